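#' Pipeline configuration defaults
#'
#' All tunable parameters of the extraction/selection/classification chain in
#' one list. Defaults follow the acquisition geometry (6 mm field of view,
#' 2/4/6 mm diameter rings), the fractal-dimension vessel cutoff of 0.7, the
#' selection thresholds (0.15 univariate, 0.10 multivariate, 0.05 final), and
#' 5-fold cross-validation.
#'
#' @param ... Named overrides of any default.
#' @return A named list of parameters.
#' @export
octa_config <- function(...) {
  cfg <- list(
    fov_mm = 6.0,
    background_scale_mm = 1.5,
    bias_correct = FALSE,
    clahe = FALSE,
    frangi_scales = c(1, 2, 4, 8),
    frangi_beta = 0.5,
    frangi_c = 0.5,
    thresh_window_px = 31,
    thresh_offset = -0.02,
    min_object_px = 20,
    max_hole_px = 10,
    min_response = 0.05,
    intensity_floor = 0.4,
    min_branch_px = 5,
    fd_window_px = 16,
    fd_threshold = 0.7,
    region_diameters_mm = c(2, 4, 6),
    nested_regions = FALSE,
    faz_smooth_sigma = 2,
    faz_max_iter = 500,
    faz_max_radius_mm = 1.5,
    length_weighted_bvt = FALSE,
    p_enter = 0.15,
    p_remove = 0.10,
    p_final = 0.05,
    folds = 5,
    svm_kernel = "linear",
    svm_cost = 1,
    group_by_subject = TRUE
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config parameters: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Blood vessel tortuosity
#'
#' Mean over skeleton branches of the geodesic-to-Euclidean length ratio. A
#' straight branch scores exactly 1; curvier branches score higher. Closed
#' loops (coincident endpoints, zero Euclidean length) are excluded and
#' counted via a message.
#'
#' @param branches List of branches from [extract_branches()].
#' @param length_weighted Weight branch ratios by geodesic length instead of
#'   the plain mean (default `FALSE`).
#' @param max_ratio Validity cap: branches whose ratio exceeds this are
#'   treated as segmentation artifacts (medial axes doubling back through
#'   tangential vessel merges) and excluded with a message. A semicircular
#'   vessel course scores pi/2, so the default 2 never touches plausible
#'   anatomy.
#' @return Mean tortuosity ratio (>= 1 up to discretization).
#' @export
compute_bvt <- function(branches, length_weighted = FALSE, max_ratio = 2) {
  if (!length(branches)) stop("undefined feature: BVT needs at least one branch")
  eu <- vapply(branches, function(b) b$euclidean_length, numeric(1))
  ge <- vapply(branches, function(b) b$geodesic_length, numeric(1))
  loops <- eu == 0
  if (any(loops)) {
    message(sprintf("BVT: excluded %d closed-loop branch(es)", sum(loops)))
    eu <- eu[!loops]; ge <- ge[!loops]
  }
  if (!length(eu)) stop("undefined feature: all branches are closed loops")
  ratios <- ge / eu
  bad <- ratios > max_ratio
  if (any(bad)) {
    message(sprintf("BVT: excluded %d implausible branch(es) with ratio > %g",
                    sum(bad), max_ratio))
    ratios <- ratios[!bad]; ge <- ge[!bad]
  }
  if (!length(ratios)) stop("undefined feature: no valid branches")
  if (length_weighted) sum(ratios * ge) / sum(ge) else mean(ratios)
}

#' Blood vascular caliber
#'
#' Ratio of vascular area (vessel-map pixel count times physical pixel area)
#' to vascular length (8-connected skeleton path length times pixel pitch),
#' in micrometres. For a bar of constant width the result is the bar width.
#'
#' @param vessel_mask,skeleton_mask Logical matrices.
#' @param mm_per_pixel Pixel pitch in mm.
#' @return Mean caliber in micrometres.
#' @export
compute_bvc <- function(vessel_mask, skeleton_mask, mm_per_pixel) {
  if (!any(skeleton_mask)) stop("undefined feature: BVC needs a nonempty skeleton")
  um_per_px <- mm_per_pixel * 1000
  area_um2 <- sum(vessel_mask) * um_per_px^2
  len_um <- skeleton_length_px(skeleton_mask) * um_per_px
  area_um2 / len_um
}

# Total 8-connected skeleton path length in pixel units. Each connected
# curve of n pixels traversed with orthogonal steps measures n (the pixel
# count), diagonal steps add sqrt(2) - 1 each.
skeleton_length_px <- function(skeleton_mask) {
  br <- extract_branches(skeleton_mask, min_length_px = 0)
  if (!length(br)) return(0)
  sum(vapply(br, function(b) b$geodesic_length + 1, numeric(1)))
}

#' Vessel perimeter index
#'
#' Fraction of image pixels lying on the vessel perimeter.
#'
#' @param perimeter_mask Logical matrix from [perimeter_map()].
#' @return Ratio in `[0, 1]`.
#' @export
compute_vpi <- function(perimeter_mask) {
  mean(perimeter_mask)
}

#' Circular measurement regions around the fovea
#'
#' Defines the three rings used for regional vessel density: diameters 2, 4,
#' and 6 mm around the foveal centre (disjoint annuli C1 = 0-1 mm, C2 = 1-2
#' mm, C3 = 2-3 mm radius by default, or nested disks when `nested = TRUE`),
#' with an exclusion mask (the segmented FAZ) removed from every region.
#'
#' @param center Pixel (row, col) of the foveal centre.
#' @param mm_per_pixel Pixel pitch in mm.
#' @param dim_px Image dimensions (rows, cols).
#' @param diameters_mm Ring diameters in mm (default `c(2, 4, 6)`).
#' @param exclusion_mask Optional logical matrix excluded from all regions.
#' @param nested Use nested disks instead of disjoint annuli.
#'
#' @return An object of class `region_spec`: a list of logical region masks
#'   named `C1`, `C2`, `C3`, plus the centre.
#' @export
region_spec <- function(center, mm_per_pixel, dim_px,
                        diameters_mm = c(2, 4, 6), exclusion_mask = NULL,
                        nested = FALSE) {
  radii_px <- (diameters_mm / 2) / mm_per_pixel
  rows <- matrix(seq_len(dim_px[1]), dim_px[1], dim_px[2])
  cols <- matrix(seq_len(dim_px[2]), dim_px[1], dim_px[2], byrow = TRUE)
  d <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  regions <- vector("list", length(radii_px))
  inner <- 0
  for (i in seq_along(radii_px)) {
    m <- if (nested) d <= radii_px[i] else d <= radii_px[i] & d > inner
    if (!is.null(exclusion_mask)) m <- m & !exclusion_mask
    regions[[i]] <- m
    inner <- radii_px[i]
  }
  names(regions) <- paste0("C", seq_along(regions))
  structure(list(regions = regions, center = center), class = "region_spec")
}

#' Regional blood vessel density from the fractal-dimension map
#'
#' Per region, the fraction of (in-region, non-excluded) pixels whose local
#' fractal dimension is at least `fd_threshold` — i.e. pixels classified as
#' vessel. The denominator is the region under measurement.
#'
#' @param fd_map Numeric matrix from [local_fd_map()].
#' @param region A [region_spec()].
#' @param fd_threshold Vessel cutoff on the fractal dimension (default 0.7).
#' @return Named numeric vector of densities in `[0, 1]`, one per region.
#' @export
compute_bvd <- function(fd_map, region, fd_threshold = 0.7) {
  stopifnot(inherits(region, "region_spec"),
            fd_threshold > 0, fd_threshold < 1)
  vapply(region$regions, function(m) {
    n <- sum(m)
    if (n == 0) stop("undefined feature: BVD region entirely excluded")
    sum(fd_map[m] >= fd_threshold) / n
  }, numeric(1))
}

#' FAZ area
#'
#' Number of pixels in the segmented fovea times the physical area of one
#' pixel, in square micrometres.
#'
#' @param faz A [faz_result].
#' @param mm_per_pixel Pixel pitch in mm.
#' @return Area in square micrometres.
#' @export
compute_faz_area <- function(faz, mm_per_pixel) {
  stopifnot(inherits(faz, "faz_result"))
  if (!any(faz$mask)) stop("undefined feature: empty FAZ mask")
  sum(faz$mask) * (mm_per_pixel * 1000)^2
}

#' FAZ contour irregularity
#'
#' Perimeter of the FAZ contour divided by the perimeter of the circle with
#' equivalent area. Both perimeter and area are computed from the same
#' sub-pixel contour polygon (shoelace area), so the index is not inflated by
#' pixel staircase; a circle scores 1, any other shape more.
#'
#' @param faz A [faz_result] (or anything with a closed `contour` polygon).
#' @return Irregularity ratio (>= 1 up to discretization).
#' @export
compute_faz_ci <- function(faz) {
  poly <- if (inherits(faz, "faz_result")) faz$contour else as.matrix(faz)
  if (nrow(poly) < 4) stop("undefined feature: FAZ contour too short")
  a <- polygon_area(poly)
  if (a <= 0) stop("undefined feature: FAZ contour encloses no area")
  if (is_self_intersecting(poly)) {
    warning("FAZ contour is self-intersecting; computing on the polygon as-is")
  }
  polygon_perimeter(poly) / (2 * sqrt(pi * a))
}

# Conservative O(n^2) segment-intersection check on decimated vertices.
is_self_intersecting <- function(poly) {
  n <- nrow(poly)
  if (poly[1, 1] == poly[n, 1] && poly[1, 2] == poly[n, 2]) poly <- poly[-n, , drop = FALSE]
  n <- nrow(poly)
  if (n > 200) { poly <- poly[round(seq(1, n, length.out = 200)), ]; n <- nrow(poly) }
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    if (!length(js)) next
    d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[js, 1], seg[js, 2]) *
          cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[js, 3], seg[js, 4])
    d2 <- cross(seg[js, 1], seg[js, 2], seg[js, 3], seg[js, 4], seg[i, 1], seg[i, 2]) *
          cross(seg[js, 1], seg[js, 2], seg[js, 3], seg[js, 4], seg[i, 3], seg[i, 4])
    if (any(d1 < 0 & d2 < 0)) return(TRUE)
  }
  FALSE
}
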