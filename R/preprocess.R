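#' En-face angiogram container
#'
#' Bundles a 2-D grid of nonnegative flow intensities with its physical scale.
#' Scans are assumed square and macula-centered; the pixel pitch is derived
#' from the field of view as `fov_mm / width_px`.
#'
#' @param pixels Numeric matrix of nonnegative intensities (rows = y, cols = x).
#' @param layer Plexus the image samples: `"SCP"` (superficial) or `"DCP"` (deep).
#' @param fov_mm Physical width of the field of view in mm (default 6).
#'
#' @return An object of class `angiogram` with fields `pixels`, `width_px`,
#'   `height_px`, `fov_mm`, `layer`, and `mm_per_pixel`.
#' @export
angiogram <- function(pixels, layer = c("SCP", "DCP"), fov_mm = 6.0) {
  layer <- match.arg(layer)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels)) {
    stop(sprintf("angiogram must be square; got %d x %d pixels",
                 nrow(pixels), ncol(pixels)))
  }
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stop("angiogram intensities must be finite and nonnegative")
  }
  if (fov_mm <= 0) stop("fov_mm must be positive")
  structure(
    list(
      pixels = pixels,
      width_px = ncol(pixels),
      height_px = nrow(pixels),
      fov_mm = fov_mm,
      layer = layer,
      mm_per_pixel = fov_mm / ncol(pixels)
    ),
    class = "angiogram"
  )
}

#' @export
print.angiogram <- function(x, ...) {
  cat(sprintf("<angiogram> %s layer, %d x %d px, %.1f mm FOV (%.4f mm/px)\n",
              x$layer, x$width_px, x$height_px, x$fov_mm, x$mm_per_pixel))
  cat(sprintf("  intensity range [%.3f, %.3f]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Load an en-face angiogram from a PNG or TIFF file
#'
#' Reads a single-channel (or collapsible-to-gray) image, converts integer
#' intensities to floating point in `[0, 1]` and records layer and scale.
#' Multi-channel images are collapsed to luminance.
#'
#' @param path Path to an 8- or 16-bit grayscale PNG or TIFF file.
#' @inheritParams angiogram
#'
#' @return An [angiogram].
#' @export
load_angiogram <- function(path, layer = c("SCP", "DCP"), fov_mm = 6.0) {
  if (!file.exists(path)) stop("cannot read angiogram: no such file: ", path)
  img <- EBImage::readImage(path)
  if (EBImage::colorMode(img) != EBImage::Grayscale) {
    img <- EBImage::channel(img, "gray")
  }
  d <- dim(img)
  if (length(d) > 2) img <- EBImage::getFrame(img, 1)
  # EBImage stores [x, y]; transpose to row-major [y, x]
  m <- t(as.matrix(EBImage::imageData(img)))
  angiogram(m, layer = layer, fov_mm = fov_mm)
}

#' Window-normalize an angiogram to [0, 1]
#'
#' Linearly rescales intensities to a standard window based on the minimum and
#' maximum values, preserving intensity order. A constant image has no
#' contrast and maps to all zeros with a warning.
#'
#' @param img An [angiogram].
#' @return An [angiogram] with intensities in `[0, 1]`.
#' @export
normalize_window <- function(img) {
  stopifnot(inherits(img, "angiogram"))
  p <- img$pixels
  lo <- min(p); hi <- max(p)
  if (hi == lo) {
    warning("constant image: degenerate contrast, returning all-zero image")
    img$pixels <- matrix(0, nrow(p), ncol(p))
    return(img)
  }
  img$pixels <- (p - lo) / (hi - lo)
  img
}

#' Correct a slowly varying illumination bias
#'
#' Estimates a smooth multiplicative background by heavy low-pass filtering at
#' the scale `background_scale_mm` (much wider than any vessel) and divides it
#' out, then re-windows the result to `[0, 1]`. A spatially flat image is
#' returned unchanged up to a constant factor. Background estimates that reach
#' zero are floored at a small positive epsilon and the number of floored
#' pixels is reported via a message.
#'
#' @param img An [angiogram].
#' @param background_scale_mm Width of the background smoothing kernel in mm
#'   (default 1.5).
#' @return An [angiogram] with bias-corrected intensities in `[0, 1]`.
#' @export
correct_bias_field <- function(img, background_scale_mm = 1.5) {
  stopifnot(inherits(img, "angiogram"))
  p <- img$pixels
  width_px <- background_scale_mm / img$mm_per_pixel
  # estimate illumination from the background floor: light smoothing (so
  # speckle minima do not drag the floor to zero), grayscale opening wide
  # enough to remove vessels (a plain local mean would track vessel density
  # instead of illumination), then heavy smoothing
  open_r <- max(3, round(width_px / 5))
  smooth <- box_blur(p, 7)
  # replicate-pad before the grayscale opening: EBImage treats the outside as
  # zero, which would drag the floor to zero along the borders
  padded <- pad_replicate(smooth, open_r + 1)
  op <- as.matrix(EBImage::opening(padded, disk_mask(open_r)))
  floor_img <- op[(open_r + 2):(open_r + 1 + nrow(p)),
                  (open_r + 2):(open_r + 1 + ncol(p)), drop = FALSE]
  bg <- box_blur(floor_img, width_px)
  med <- median(bg)
  if (med < 0.01 * max(p)) {
    # no measurable background floor: illumination treated as flat
    message("background floor too weak to estimate a bias field; image returned unchanged")
    return(img)
  }
  if (max(bg) / med > 2.5) {
    # illumination varies smoothly and modestly across a field of view; a
    # field this steep means confluent foreground leaked into the floor
    # estimate, so correcting with it would do more harm than good
    message("bias-field estimate dominated by foreground; image returned unchanged")
    return(img)
  }
  eps <- 0.2 * med
  n_floored <- sum(bg < eps)
  if (n_floored > 0) {
    message(sprintf("bias field floored at epsilon for %d pixels", n_floored))
    bg[bg < eps] <- eps
  }
  out <- p / bg
  # robust re-window: a single bright speckle pixel over a low floor must not
  # set the scale for the whole image
  lo <- min(out); hi <- quantile(out, 0.995)
  if (hi - lo > 1e-8 * max(hi, 1)) {
    out <- pmin((out - lo) / (hi - lo), 1)
  } else if (max(out) > 0) {
    out <- out / max(out)  # numerically flat: keep it flat
  }
  img$pixels <- out
  img
}

#' Standard preprocessing chain
#'
#' Applies window normalization, optionally followed by bias-field correction
#' plus re-normalization and by contrast-limited adaptive histogram
#' equalization (both off by default). Flat-fielding assumes the vasculature
#' is sparse at the background-estimation scale; in macula-centred angiograms
#' with confluent perfusion that assumption fails and the local adaptive
#' thresholding downstream already neutralizes slowly varying illumination,
#' so the correction is opt-in.
#'
#' @inheritParams correct_bias_field
#' @param bias_correct Logical; divide out the estimated illumination field.
#' @param clahe Logical; apply contrast-limited equalization after correction.
#' @return A preprocessed [angiogram].
#' @export
preprocess_angiogram <- function(img, background_scale_mm = 1.5,
                                 bias_correct = FALSE, clahe = FALSE) {
  out <- normalize_window(img)
  if (bias_correct) {
    out <- correct_bias_field(out, background_scale_mm)
    out <- normalize_window(out)
  }
  if (clahe) {
    eq <- EBImage::clahe(t(out$pixels))
    out$pixels <- t(as.matrix(eq))
    out <- normalize_window(out)
  }
  out
}
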