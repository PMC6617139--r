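#' @importFrom stats coef cor lm median predict quantile rnorm runif sd setNames
#' @importFrom rlang .data
NULL

# Shift a matrix by (dr, dc), padding the vacated rows/cols with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr
  cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# Replicate-pad a matrix by r rows/cols on every side.
pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci]
}

# 2-D convolution with replicate boundary handling. EBImage::filter2 requires
# the kernel to fit inside the image, hence the explicit padding.
conv2 <- function(m, kernel) {
  r <- (dim(kernel)[1] - 1L) %/% 2L
  p <- pad_replicate(m, r)
  out <- EBImage::filter2(p, kernel, boundary = "circular")
  out <- as.matrix(out)
  out[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m)), drop = FALSE]
}

gaussian_kernel_1d <- function(sigma, order = 0, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
    "0" = g,
    "1" = -x / sigma^2 * g,
    "2" = (x^2 - sigma^2) / sigma^4 * g,
    stop("unsupported derivative order")
  )
}

# Separable Gaussian (derivative) filtering built as an outer-product kernel.
gaussian_filter <- function(m, sigma, order = c(0, 0)) {
  radius <- ceiling(3 * sigma)
  kr <- gaussian_kernel_1d(sigma, order[1], radius)  # along rows (y)
  kc <- gaussian_kernel_1d(sigma, order[2], radius)  # along cols (x)
  conv2(m, outer(kr, kc))
}

# Heavy low-pass for bias-field estimation: three iterated box filters
# approximate a Gaussian of arbitrary width without kernel-size limits.
box_blur <- function(m, width) {
  w <- max(3L, as.integer(width))
  if (w %% 2L == 0L) w <- w + 1L
  r <- (w - 1L) %/% 2L
  pass <- function(x) {
    p <- pad_replicate(x, r)
    cs <- apply(p, 2, cumsum)
    v <- (cs[(2 * r + 1):nrow(p), , drop = FALSE] -
            rbind(0, cs[seq_len(nrow(p) - 2 * r - 1), , drop = FALSE])) / w
    cs2 <- t(apply(v, 1, cumsum))
    (cs2[, (2 * r + 1):ncol(p), drop = FALSE] -
       cbind(0, cs2[, seq_len(ncol(p) - 2 * r - 1), drop = FALSE])) / w
  }
  out <- m
  for (i in 1:3) out <- pass(out)
  out
}

# Number of 8-neighbours that are TRUE, per pixel.
neighbour_count8 <- function(mask) {
  m <- mask * 1
  shift_mat(m, 1, 0) + shift_mat(m, -1, 0) + shift_mat(m, 0, 1) + shift_mat(m, 0, -1) +
    shift_mat(m, 1, 1) + shift_mat(m, 1, -1) + shift_mat(m, -1, 1) + shift_mat(m, -1, -1)
}

# 8-connected labelling: 4-connected pass (EBImage::bwlabel), then union-find
# merge of labels touching diagonally.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  a1 <- lab[-nrow(lab), -ncol(lab)]; b1 <- lab[-1, -1]          # down-right
  a2 <- lab[-nrow(lab), -1]; b2 <- lab[-1, -ncol(lab)]          # down-left
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

# Remove connected components smaller than min_px (8-connectivity).
remove_small_objects <- function(mask, min_px) {
  if (!any(mask)) return(mask)
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Fill holes (background components not touching the border) smaller than max_px.
fill_small_holes <- function(mask, max_px) {
  bg <- !mask
  if (!any(bg)) return(mask)
  lab <- EBImage::bwlabel(bg * 1)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0])
  fill <- setdiff(which(sizes <= max_px), border_labels)
  if (length(fill)) mask[matrix(lab %in% fill, nrow(mask), ncol(mask))] <- TRUE
  mask
}

# Keep only the connected component containing the seed (4-connectivity).
seed_component <- function(mask, seed) {
  if (!mask[seed[1], seed[2]]) return(matrix(FALSE, nrow(mask), ncol(mask)))
  filled <- EBImage::floodFill(mask * 1, matrix(c(seed[1], seed[2]), 1), col = 2)
  matrix(as.matrix(filled) == 2, nrow(mask), ncol(mask))
}

# Shoelace area of a closed polygon given as a matrix with columns x, y.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

polygon_perimeter <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  if (x[1] != x[n] || y[1] != y[n]) { x <- c(x, x[1]); y <- c(y, y[1]) }
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# Disk-shaped structuring element / raster mask of given radius.
disk_mask <- function(radius) {
  r <- ceiling(radius)
  x <- seq(-r, r)
  d <- outer(x, x, function(a, b) sqrt(a^2 + b^2))
  (d <= radius) * 1
}
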