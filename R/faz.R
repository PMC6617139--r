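#' Foveal avascular zone result
#'
#' Container for a FAZ segmentation: the enclosed pixel mask, the closed
#' sub-pixel contour polygon, the area (pixel count times physical pixel
#' area), and the contour perimeter.
#'
#' @param mask Logical matrix of enclosed pixels.
#' @param contour Closed polygon, an n x 2 matrix of (x, y) vertices in pixel
#'   coordinates (first row equals last row).
#' @param mm_per_pixel Physical pixel pitch in mm.
#' @param layer `"SCP"` or `"DCP"`.
#' @param converged Logical; did the contour evolution converge.
#'
#' @return An object of class `faz_result` with fields `mask`, `contour`,
#'   `area_um2`, `contour_perimeter_um`, `layer`, `converged`.
#' @export
faz_result <- function(mask, contour, mm_per_pixel, layer = "SCP",
                       converged = TRUE) {
  contour <- as.matrix(contour)
  if (nrow(contour) >= 2 &&
      any(contour[1, ] != contour[nrow(contour), ])) {
    contour <- rbind(contour, contour[1, ])
  }
  um_per_px <- mm_per_pixel * 1000
  structure(
    list(
      mask = mask,
      contour = contour,
      area_um2 = sum(mask) * um_per_px^2,
      contour_perimeter_um = polygon_perimeter(contour) * um_per_px,
      layer = layer,
      converged = converged
    ),
    class = "faz_result"
  )
}

#' @export
print.faz_result <- function(x, ...) {
  cat(sprintf("<faz_result> %s layer: area %.0f um^2, perimeter %.0f um%s\n",
              x$layer, x$area_um2, x$contour_perimeter_um,
              if (!x$converged) " (non-converged)" else ""))
  invisible(x)
}

# Sub-pixel closed contour of a binary mask: marching squares on a lightly
# smoothed indicator, so the polygon is not dominated by pixel staircase.
mask_contour <- function(mask, smooth_sigma = 1.5) {
  ind <- gaussian_filter(mask * 1, smooth_sigma)
  cl <- if (diff(range(ind)) > 1e-12) {
    grDevices::contourLines(x = seq_len(nrow(ind)), y = seq_len(ncol(ind)),
                            z = ind, levels = 0.5)
  } else list()
  if (!length(cl)) {
    # mask nearly fills or nearly misses the grid; fall back to pixel bounds
    idx <- which(mask, arr.ind = TRUE)
    if (!nrow(idx)) return(matrix(numeric(0), 0, 2))
    r <- range(idx[, 1]); c <- range(idx[, 2])
    return(cbind(x = c(c[1], c[2], c[2], c[1], c[1]),
                 y = c(r[1], r[1], r[2], r[2], r[1])))
  }
  lens <- vapply(cl, function(p) length(p$x), numeric(1))
  best <- cl[[which.max(lens)]]
  # contourLines x follows the first matrix index (rows); report as (x, y) =
  # (column, row) pixel coordinates
  poly <- cbind(x = best$y, y = best$x)
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  poly
}

#' Segment the foveal avascular zone with a region-based active contour
#'
#' Evolves a closed region from a small disk at the seed point with a
#' morphological Chan-Vese (edge-free) scheme on a smoothed vessel-density
#' image: at each iteration pixels move inside/outside according to which
#' region mean they are closer to, followed by morphological regularization,
#' and the region is constrained to stay connected to the seed. Capillary
#' dropout gives OCTA weak edges, which is why a region-based rather than
#' gradient-based evolution is used.
#'
#' @param img An [angiogram] (used for scale metadata, and as the evolution
#'   image when `on = "image"`).
#' @param vessel_mask Logical matrix from [binarize_vessels()].
#' @param seed Pixel (row, col) to grow from; defaults to the image centre
#'   (scans are macula-centred).
#' @param on Evolve on the smoothed binary vessel mask (default) or on the raw
#'   image.
#' @param smooth_sigma Gaussian sigma (px) for the vessel-density smoothing.
#' @param max_iter Iteration cap (default 500).
#' @param init_radius_px Radius of the initial disk (default 5).
#' @param max_radius_mm Foveal search radius: the contour may not move farther
#'   than this from the seed (default 1.5 mm, generous for any plausible FAZ).
#'   `Inf` disables the constraint.
#'
#' @return A [faz_result]. If the evolution hits `max_iter` the last contour
#'   is returned with `converged = FALSE`; a contour touching the image border
#'   triggers a warning (implausible FAZ).
#' @export
segment_faz <- function(img, vessel_mask, seed = NULL,
                        on = c("mask", "image"), smooth_sigma = 2,
                        max_iter = 500, init_radius_px = 5,
                        max_radius_mm = 1.5) {
  stopifnot(inherits(img, "angiogram"))
  on <- match.arg(on)
  nr <- img$height_px; nc <- img$width_px
  if (is.null(seed)) seed <- c((nr + 1) %/% 2, (nc + 1) %/% 2)
  u <- if (on == "mask") gaussian_filter(vessel_mask * 1, smooth_sigma)
       else gaussian_filter(img$pixels, smooth_sigma)
  # initial disk at the seed
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- (rows - seed[1])^2 + (cols - seed[2])^2
  mask <- d2 <= init_radius_px^2
  brush <- disk_mask(2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    inside <- u[mask]
    outside <- u[!mask]
    if (!length(outside)) break
    c1 <- mean(inside); c2 <- mean(outside)
    if (!is.finite(c1) || !is.finite(c2) || abs(c1 - c2) < 1e-9) {
      # degenerate contrast: nothing to lock onto, the avascular region is
      # unbounded
      mask[] <- TRUE
      break
    }
    cand <- (u - c1)^2 < (u - c2)^2
    if (is.finite(max_radius_mm)) {
      cand <- cand & (d2 <= (max_radius_mm / img$mm_per_pixel)^2)
    }
    cand <- cand | (d2 <= init_radius_px^2)  # never lose the seed
    new_mask <- seed_component(cand, seed)
    new_mask <- fill_small_holes(new_mask, max_px = Inf)
    new_mask <- matrix(as.matrix(EBImage::opening(new_mask * 1, brush)) > 0.5, nr, nc)
    new_mask <- seed_component(new_mask | (d2 <= init_radius_px^2), seed)
    if (identical(new_mask, mask)) { converged <- TRUE; break }
    mask <- new_mask
  }
  if (any(mask[1, ]) || any(mask[nr, ]) || any(mask[, 1]) || any(mask[, nc])) {
    warning("FAZ contour touches the image border (implausible FAZ)")
  }
  contour <- mask_contour(mask)
  faz_result(mask, contour, img$mm_per_pixel, layer = img$layer,
             converged = converged)
}

#' All derived vessel maps for one angiogram
#'
#' Convenience wrapper running vesselness, binarization, skeletonization,
#' perimeter extraction, and the local fractal-dimension map.
#'
#' @param img A preprocessed [angiogram].
#' @param config Parameter list from [octa_config()].
#' @param with_skeleton Compute the skeleton and perimeter maps (default
#'   `TRUE`); layers whose features need neither can skip the thinning.
#' @return An object of class `vessel_map_set` with fields `vessel_mask`,
#'   `skeleton_mask`, `perimeter_mask`, `fd_map`, `vessel_area_fraction`,
#'   `skeleton_area_fraction`.
#' @export
vessel_map_set <- function(img, config = octa_config(), with_skeleton = TRUE) {
  v <- vesselness_map(img, scales_px = config$frangi_scales,
                      beta = config$frangi_beta, c_factor = config$frangi_c)
  vessel <- binarize_vessels(v, window_px = config$thresh_window_px,
                             offset = config$thresh_offset,
                             min_object_px = config$min_object_px,
                             max_hole_px = config$max_hole_px,
                             min_response = config$min_response)
  # ridge enhancement misses confluent plexus (no tube contrast); union with
  # an adaptive threshold of the flow intensity itself recovers those areas
  rng <- range(img$pixels)
  gate <- if (rng[2] > rng[1]) (img$pixels - rng[1]) / (rng[2] - rng[1])
          else img$pixels * 0
  ivessel <- binarize_vessels(gate, window_px = config$thresh_window_px,
                              offset = config$thresh_offset,
                              min_object_px = config$min_object_px,
                              max_hole_px = config$max_hole_px,
                              min_response = config$intensity_floor)
  vessel <- fill_small_holes(vessel | ivessel, config$max_hole_px)
  skel <- if (with_skeleton) skeletonize_vessels(vessel)
  peri <- if (with_skeleton) perimeter_map(vessel)
  fd <- local_fd_map(vessel, window_px = config$fd_window_px)
  structure(
    list(
      vessel_mask = vessel,
      skeleton_mask = skel,
      perimeter_mask = peri,
      fd_map = fd,
      vessel_area_fraction = mean(vessel),
      skeleton_area_fraction = if (with_skeleton) mean(skel) else NA_real_
    ),
    class = "vessel_map_set"
  )
}

#' @export
print.vessel_map_set <- function(x, ...) {
  cat(sprintf("<vessel_map_set> vessel %.1f%%, skeleton %.1f%% of image area\n",
              100 * x$vessel_area_fraction, 100 * x$skeleton_area_fraction))
  invisible(x)
}
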