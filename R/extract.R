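#' Extract the full 13-scalar feature vector for one eye
#'
#' Runs the complete chain (preprocess, vesselness, binarization,
#' skeletonization, branch decomposition, fractal-dimension map, FAZ active
#' contour) on the superficial (SCP) and deep (DCP) plexus images of one eye
#' and computes the quantitative features: tortuosity (BVT), caliber (BVC),
#' and perimeter index (VPI) from the SCP; regional vessel density (BVD, rings
#' C1-C3), FAZ area, and FAZ contour irregularity from both layers. The BVD
#' rings are centred on the FAZ centroid when FAZ segmentation succeeded
#' (image centre otherwise) and exclude the segmented FAZ.
#'
#' @param scp,dcp [angiogram] objects for the two plexuses. `dcp` may be
#'   `NULL`, yielding an SCP-only partial vector flagged incomplete.
#' @param config Parameter list from [octa_config()].
#' @param subject_id,eye,label Identifiers copied into the output row.
#' @param keep_maps Keep intermediate maps as an attribute `"maps"`.
#'
#' @return A one-row [tibble::tibble] with columns `subject_id`, `eye`,
#'   `label`, `BVT_S`, `BVC_S`, `VPI_S`, `BVD_SC1`, `BVD_SC2`, `BVD_SC3`,
#'   `BVD_DC1`, `BVD_DC2`, `BVD_DC3`, `FAZ_A_S`, `FAZ_A_D`, `FAZ_CI_S`,
#'   `FAZ_CI_D`, and logical `complete`.
#' @export
extract_all_features <- function(scp, dcp = NULL, config = octa_config(),
                                 subject_id = NA_character_,
                                 eye = NA_character_, label = NA_character_,
                                 keep_maps = FALSE) {
  stopifnot(inherits(scp, "angiogram"))
  s <- layer_measurements(scp, config, with_vascular = TRUE)
  d <- if (!is.null(dcp)) layer_measurements(dcp, config, with_vascular = FALSE)
  out <- tibble::tibble(
    subject_id = subject_id, eye = eye, label = label,
    BVT_S = s$bvt, BVC_S = s$bvc, VPI_S = s$vpi,
    BVD_SC1 = s$bvd[1], BVD_SC2 = s$bvd[2], BVD_SC3 = s$bvd[3],
    BVD_DC1 = if (is.null(d)) NA_real_ else d$bvd[1],
    BVD_DC2 = if (is.null(d)) NA_real_ else d$bvd[2],
    BVD_DC3 = if (is.null(d)) NA_real_ else d$bvd[3],
    FAZ_A_S = s$faz_a, FAZ_A_D = if (is.null(d)) NA_real_ else d$faz_a,
    FAZ_CI_S = s$faz_ci, FAZ_CI_D = if (is.null(d)) NA_real_ else d$faz_ci,
    complete = !is.null(d)
  )
  if (keep_maps) attr(out, "maps") <- list(scp = s$maps, dcp = d$maps)
  out
}

# Per-layer measurements. The SCP additionally carries the branch-based
# vascular features (BVT, BVC, VPI).
layer_measurements <- function(img, config, with_vascular) {
  pre <- preprocess_angiogram(img, config$background_scale_mm,
                              config$bias_correct, config$clahe)
  maps <- vessel_map_set(pre, config, with_skeleton = with_vascular)
  faz <- segment_faz(pre, maps$vessel_mask, smooth_sigma = config$faz_smooth_sigma,
                     max_iter = config$faz_max_iter,
                     max_radius_mm = config$faz_max_radius_mm)
  center <- if (any(faz$mask)) {
    idx <- which(faz$mask, arr.ind = TRUE)
    c(mean(idx[, 1]), mean(idx[, 2]))
  } else {
    c((img$height_px + 1) / 2, (img$width_px + 1) / 2)
  }
  reg <- region_spec(center, img$mm_per_pixel,
                     c(img$height_px, img$width_px),
                     diameters_mm = config$region_diameters_mm,
                     exclusion_mask = faz$mask, nested = config$nested_regions)
  res <- list(
    bvd = unname(compute_bvd(maps$fd_map, reg, config$fd_threshold)),
    faz_a = compute_faz_area(faz, img$mm_per_pixel),
    faz_ci = compute_faz_ci(faz),
    maps = maps, faz = faz
  )
  if (with_vascular) {
    # one decomposition serves both tortuosity (length-filtered) and caliber
    branches <- extract_branches(maps$skeleton_mask, min_length_px = 0)
    long <- branches[vapply(branches, function(b)
      b$geodesic_length >= config$min_branch_px, logical(1))]
    res$bvt <- compute_bvt(long, config$length_weighted_bvt)
    len_um <- sum(vapply(branches, function(b) b$geodesic_length + 1,
                         numeric(1))) * img$mm_per_pixel * 1000
    area_um2 <- sum(maps$vessel_mask) * (img$mm_per_pixel * 1000)^2
    res$bvc <- area_um2 / len_um
    res$vpi <- compute_vpi(maps$perimeter_mask)
  }
  res
}

#' Feature column names
#'
#' The 13 quantitative feature columns, in canonical order. Superscript S/D
#' in the names denotes the superficial/deep plexus; C1-C3 the three rings.
#'
#' @return Character vector of 13 column names.
#' @export
octa_feature_names <- function() {
  c("BVT_S", "BVC_S", "VPI_S",
    "BVD_SC1", "BVD_SC2", "BVD_SC3", "BVD_DC1", "BVD_DC2", "BVD_DC3",
    "FAZ_A_S", "FAZ_A_D", "FAZ_CI_S", "FAZ_CI_D")
}
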