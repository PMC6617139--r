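#' Multi-scale Frangi vesselness
#'
#' Hessian-eigenvalue ridge enhancement for bright curvilinear structures.
#' At each scale the image is filtered with scale-normalized Gaussian second
#' derivatives; the eigenvalues \eqn{|\lambda_1| \le |\lambda_2|} of the
#' Hessian give the blobness ratio \eqn{R_b = \lambda_1/\lambda_2} and the
#' second-order structureness \eqn{S = \sqrt{\lambda_1^2 + \lambda_2^2}}. The
#' vesselness response
#' \deqn{V = \exp(-R_b^2 / 2\beta^2)\,(1 - \exp(-S^2 / 2c^2))}
#' is suppressed where \eqn{\lambda_2 > 0} (dark ridges) and maximized over
#' scales. The result is rescaled to `[0, 1]`.
#'
#' @param img An [angiogram] (or plain numeric matrix) with intensities in
#'   `[0, 1]`.
#' @param scales_px Gaussian scales (ridge half-widths) in pixels; the default
#'   `c(1, 2, 4, 8)` spans capillaries to large vessels.
#' @param beta Blobness sensitivity (default 0.5).
#' @param c_factor Structureness sensitivity as a fraction of the per-scale
#'   maximum of `S` (default 0.5).
#'
#' @return Numeric matrix of vesselness scores in `[0, 1]`.
#' @export
frangi_vesselness <- function(img, scales_px = c(1, 2, 4, 8), beta = 0.5,
                              c_factor = 0.5) {
  m <- if (inherits(img, "angiogram")) img$pixels else as.matrix(img)
  if (length(scales_px) == 0) stop("scales_px must be a nonempty list of positive scales")
  if (any(scales_px <= 0)) stop("all scales_px must be positive")
  best <- matrix(0, nrow(m), ncol(m))
  if (max(m) == min(m)) return(best)  # no structure at all
  for (s in scales_px) {
    dxx <- s^2 * gaussian_filter(m, s, c(0, 2))
    dyy <- s^2 * gaussian_filter(m, s, c(2, 0))
    dxy <- s^2 * gaussian_filter(m, s, c(1, 1))
    tmp <- sqrt(((dxx - dyy) / 2)^2 + dxy^2)
    mu <- (dxx + dyy) / 2
    e1 <- mu + tmp
    e2 <- mu - tmp
    # order by magnitude: lambda1 small, lambda2 large
    swap <- abs(e1) > abs(e2)
    lam1 <- ifelse(swap, e2, e1)
    lam2 <- ifelse(swap, e1, e2)
    s2 <- lam1^2 + lam2^2
    cc <- c_factor * sqrt(max(s2))
    if (cc == 0) next
    rb2 <- (lam1 / ifelse(lam2 == 0, .Machine$double.eps, lam2))^2
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cc^2)))
    v[lam2 > 0] <- 0  # bright ridges have strongly negative lambda2
    best <- pmax(best, matrix(v, nrow(m), ncol(m)))
  }
  best
}

#' Flow-gated vesselness map
#'
#' Multi-scale vesselness multiplied by the window-normalized image
#' intensity. Coarse Hessian scales respond in a halo around thin vessels;
#' gating by the flow signal suppresses that halo (the background carries no
#' flow) while leaving genuine vessel pixels bright. This is the map the
#' segmentation chain thresholds.
#'
#' @inheritParams frangi_vesselness
#' @return Numeric matrix in `[0, 1]`.
#' @export
vesselness_map <- function(img, scales_px = c(1, 2, 4, 8), beta = 0.5,
                           c_factor = 0.5) {
  m <- if (inherits(img, "angiogram")) img$pixels else as.matrix(img)
  v <- frangi_vesselness(m, scales_px, beta, c_factor)
  rng <- range(m)
  gate <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  out <- v * gate
  hi <- max(out)
  if (hi > 0) out / hi else out
}
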