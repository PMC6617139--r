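# Shared fixtures, all generated in code.

# Straight bright ridge of given width on a dark background.
ridge_image <- function(n = 120, width = 3, value = 1) {
  m <- matrix(0, n, n)
  c0 <- (n - width) %/% 2 + 1
  m[, c0:(c0 + width - 1)] <- value
  m
}

# Rasterized semicircle skeleton of radius R.
semicircle_skeleton <- function(R = 40) {
  theta <- seq(0, pi, length.out = 50 * R)
  m <- matrix(FALSE, 2 * R + 20, 3 * R)
  m[unique(cbind(round(R + 20 - R * sin(theta)),
                 round(1.5 * R + R * cos(theta))))] <- TRUE
  m
}

# Dense vessel grid with a vessel-free central disk (ground-truth FAZ).
grid_faz_phantom <- function(n = 200, disk_r = 25) {
  mask <- matrix(FALSE, n, n)
  for (r in seq(4, n - 3, by = 7)) mask[r:(r + 2), ] <- TRUE
  for (cl in seq(4, n - 3, by = 13)) mask[, cl:(cl + 1)] <- TRUE
  ctr <- (n + 1) / 2
  d <- sqrt((row(mask) - ctr)^2 + (col(mask) - ctr)^2)
  truth <- d <= disk_r
  mask[truth] <- FALSE
  list(mask = mask, truth = truth, center = c(ctr, ctr))
}

# Regular polygon approximating a circle.
circle_polygon <- function(r = 50, n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  cbind(x = r * cos(th), y = r * sin(th))
}

# Two classes separated by a genuine margin on two features: class clusters
# are uniform boxes three reference-SDs apart, so a linear boundary with a
# wide margin exists.
separable_cohort <- function(n_per_class = 100, seed = 1) {
  withr::with_seed(seed, {
    d <- as.data.frame(matrix(stats::rnorm(2 * n_per_class * 13),
                              2 * n_per_class, 13))
    names(d) <- octa_feature_names()
    cls <- rep(c(0, 1), each = n_per_class)
    d$BVT_S <- stats::runif(2 * n_per_class) + cls * 4
    d$FAZ_A_S <- stats::runif(2 * n_per_class) + cls * 4
    d$label <- ifelse(cls == 0, "control", "severe_scr")
    d$subject_id <- sprintf("P%04d", seq_len(2 * n_per_class))
    d$eye <- "OD"
    tibble::as_tibble(d)
  })
}

# Synthetic feature cohort: `informative` features shifted by `effect` SD in
# the disease groups, everything else pure noise.
synthetic_cohort <- function(n_per_class = 60, effect = 2,
                             informative = c("BVT_S", "FAZ_A_S"),
                             labels = c("control", "severe_scr"),
                             seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(seq_along(labels), function(i) {
      d <- as.data.frame(matrix(stats::rnorm(n_per_class * 13), n_per_class, 13))
      names(d) <- octa_feature_names()
      if (i > 1) for (f in informative) d[[f]] <- d[[f]] + effect
      d$label <- labels[i]
      d$subject_id <- sprintf("%s%03d", substr(labels[i], 1, 2), seq_len(n_per_class))
      d$eye <- "OD"
      d
    })
    tibble::as_tibble(dplyr::bind_rows(rows))
  })
}

# Mann-Whitney AUC oracle: P(score+ > score-) with ties counting one half.
auc_mann_whitney <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
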