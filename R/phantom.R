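#' Specification of a synthetic angiogram phantom
#'
#' Parameter set for the vascular phantom generator: bright sinusoid-perturbed
#' curvilinear vessels on a dark background, a central quasi-circular
#' avascular zone with a perturbable boundary, multiplicative speckle noise,
#' and a smooth illumination ramp. The same seed always reproduces the same
#' phantom bit for bit.
#'
#' @param image_px Image side in pixels (default 304).
#' @param fov_mm Field of view in mm (default 6).
#' @param n_vessels Number of vessel centerlines in the superficial layer.
#' @param tortuosity_amp Dimensionless sinusoid amplitude; 0 gives straight
#'   vessels. The physical perturbation amplitude is `tortuosity_amp * 20` px.
#' @param vessel_radius_px Mean vessel half-width in pixels.
#' @param faz_radius_mm Mean radius of the central avascular zone in mm.
#' @param faz_irregularity Relative amplitude of the avascular-zone boundary
#'   perturbation (low-order harmonics).
#' @param noise_sigma Speckle strength in `[0, 1)`.
#' @param bias_strength Relative amplitude of the multiplicative illumination
#'   ramp.
#' @param seed Integer seed; fully determines the output.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_px = 304, fov_mm = 6.0, n_vessels = 30,
                         tortuosity_amp = 0.25, vessel_radius_px = 2.0,
                         faz_radius_mm = 0.30, faz_irregularity = 0.08,
                         noise_sigma = 0.15, bias_strength = 0.15, seed = 1L) {
  stopifnot(image_px >= 64, fov_mm > 0, n_vessels >= 1,
            tortuosity_amp >= 0, vessel_radius_px > 0,
            faz_radius_mm >= 0, faz_irregularity >= 0,
            noise_sigma >= 0, noise_sigma < 1, bias_strength >= 0)
  if (faz_radius_mm >= fov_mm / 2) stop("faz_radius_mm must be < fov_mm / 2")
  structure(as.list(environment()), class = "phantom_spec")
}

# Evaluate the perturbed avascular-zone boundary radius (px) at angles phi,
# given harmonic coefficients drawn once per phantom.
faz_radius_at <- function(phi, faz_px, irregularity, harmonics) {
  if (faz_px <= 0) return(rep(0, length(phi)))
  pert <- rep(0, length(phi))
  if (irregularity > 0) {
    for (k in seq_len(nrow(harmonics))) {
      pert <- pert + harmonics[k, "a"] *
        cos(harmonics[k, "k"] * phi + harmonics[k, "psi"])
    }
  }
  faz_px * (1 + irregularity * pert)
}

# One rendered layer: centerline curves -> masks, truth polylines, intensity.
# Vessels follow the radial architecture of the perifoveal plexus: trunks run
# outward from the avascular-zone rim with a sinusoidal transverse wiggle,
# spawning diverging child branches, plus circumferential mesh arcs and a
# terminal capillary ring hugging the avascular-zone boundary. Radial trees
# rarely cross, so skeleton branches stay long enough to carry the
# tortuosity signal.
render_layer <- function(n_px, n_vessels, amp_px, radius_px, faz_px,
                         irregularity, harmonics, noise_sigma, bias_strength,
                         mesh = TRUE) {
  ctr <- (n_px + 1) / 2
  faz_max_px <- faz_px * (1 + irregularity)
  if (faz_max_px + radius_px + 2 >= 0.45 * n_px) {
    stop("vessels cannot avoid the avascular zone: faz radius too large")
  }
  centerlines <- list()
  pix_by_radius <- list()
  push_curve <- function(cx, cy, r_v, min_len = 30, type = "trunk") {
    inside <- cx >= 1.5 & cx <= n_px - 0.5 & cy >= 1.5 & cy <= n_px - 0.5
    if (!any(inside)) return(invisible())
    runs <- rle(inside)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (j in which(runs$values)) {
      sel <- starts[j]:ends[j]
      if (length(sel) < min_len) next
      x <- cx[sel]; y <- cy[sel]
      geo <- sum(sqrt(diff(x)^2 + diff(y)^2))
      chord <- sqrt((x[1] - x[length(x)])^2 + (y[1] - y[length(y)])^2)
      centerlines[[length(centerlines) + 1]] <<- list(
        x = x, y = y, geodesic = geo, chord = chord, radius_px = r_v,
        type = type)
      key <- sprintf("%.2f", round(r_v * 4) / 4)
      ij <- unique(cbind(round(y), round(x)))
      pix_by_radius[[key]] <<- rbind(pix_by_radius[[key]], ij)
    }
  }
  # radial trunk (or child branch) from radius rb outward
  radial_vessel <- function(theta0, rb, r_v, amp_v, type = "trunk") {
    lambda <- runif(1, 50, 90)
    phase <- runif(1, 0, 2 * pi)
    rr <- seq(rb, 0.75 * n_px, by = 0.4)
    # transverse wiggle tapers in over ~50 px so trunks leave the rim cleanly
    th <- theta0 +
      if (amp_v > 0) (amp_v * pmin(1, (rr - rb) / 50) / pmax(rr, 15)) *
        sin(2 * pi * (rr - rb) / lambda + phase) else 0
    push_curve(ctr + rr * cos(th), ctr + rr * sin(th), r_v, type = type)
  }
  # terminal capillary ring: short arcs hugging the avascular-zone boundary;
  # spans kept short so straight-vessel phantoms stay near tortuosity 1
  if (faz_px > 0) {
    r_ring <- max(1, 0.6 * radius_px)
    n_arcs <- 12
    phi0 <- runif(1, 0, 2 * pi)
    for (aidx in seq_len(n_arcs)) {
      # arcs almost close the ring but never overlap: overlapping arcs would
      # merge into long curved pseudo-branches and contaminate tortuosity
      span <- (2 * pi / n_arcs) * runif(1, 0.82, 0.95)
      a0 <- phi0 + (aidx - 1) * 2 * pi / n_arcs
      phis <- seq(a0, a0 + span, length.out = 60)
      rads <- faz_radius_at(phis, faz_px, irregularity, harmonics) + r_ring + 2
      push_curve(ctr + rads * cos(phis), ctr + rads * sin(phis), r_ring,
                 min_len = 10, type = "ring")
    }
  }
  # radial trunks with diverging children
  for (v in seq_len(n_vessels)) {
    r_v <- radius_px * runif(1, 0.75, 1.25)
    theta0 <- 2 * pi * (v - 1 + runif(1, -0.15, 0.15)) / n_vessels
    amp_v <- if (amp_px > 0) amp_px * runif(1, 0.7, 1.3) else 0
    # staggered origins: not every trunk springs from the rim, which would
    # merge into a solid annulus there
    rb <- faz_max_px + r_v + 1 + runif(1, 0, 30)
    radial_vessel(theta0, rb, r_v, amp_v)
    for (ch in seq_len(stats::rbinom(1, 2, 0.5))) {
      if (rb + 32 >= 0.45 * n_px) break  # small fields: no room for children
      rb_c <- runif(1, rb + 30, 0.45 * n_px)
      # children are straight radial rays at a small fixed angular offset,
      # so amplitude-zero phantoms stay strictly straight
      doff <- sample(c(-1, 1), 1) * runif(1, 0.05, 0.11)
      radial_vessel(theta0 + doff, rb_c, 0.75 * r_v, 0.8 * amp_v,
                    type = "child")
    }
  }
  # circumferential mesh arcs interconnecting the tree (they cross the
  # trunks, so the superficial layer, where tortuosity is measured, omits
  # them to keep skeleton branches long)
  for (a in seq_len(if (mesh) round(0.6 * n_vessels) else 0)) {
    r_a <- runif(1, faz_max_px + 12, 0.46 * n_px)
    a0 <- runif(1, 0, 2 * pi)
    span <- runif(1, 0.15, 0.35)
    phis <- seq(a0, a0 + span, length.out = 40)
    push_curve(ctr + r_a * cos(phis), ctr + r_a * sin(phis),
               0.6 * radius_px, min_len = 10, type = "mesh")
  }
  vessel_mask <- matrix(FALSE, n_px, n_px)
  for (key in names(pix_by_radius)) {
    r_v <- as.numeric(key)
    cl <- matrix(0, n_px, n_px)
    cl[pix_by_radius[[key]]] <- 1
    dist <- as.matrix(EBImage::distmap(1 - cl))
    vessel_mask <- vessel_mask | (dist <= r_v)
  }
  # avascular-zone truth mask
  rows <- matrix(seq_len(n_px), n_px, n_px)
  cols <- matrix(seq_len(n_px), n_px, n_px, byrow = TRUE)
  rr <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  phi <- atan2(rows - ctr, cols - ctr)
  faz_mask <- rr <= matrix(faz_radius_at(as.vector(phi), faz_px, irregularity,
                                         harmonics), n_px, n_px)
  # render intensities: PSF blur, background floor, speckle, illumination ramp
  img <- gaussian_filter(vessel_mask * 1, 0.7)
  img <- 0.10 + 0.80 * pmin(img, 1)
  if (noise_sigma > 0) {
    img <- img * (1 - noise_sigma + noise_sigma *
                    matrix(stats::rexp(n_px * n_px), n_px, n_px))
  }
  img <- pmin(img, 1)  # detector saturation
  if (bias_strength > 0) {
    alpha <- runif(1, 0, 2 * pi)
    ramp <- ((cols - ctr) * cos(alpha) + (rows - ctr) * sin(alpha)) / n_px + 0.5
    img <- img * (1 - bias_strength / 2 + bias_strength * ramp)
  }
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 255) / 255  # 8-bit export, as devices write
  list(image = img, vessel_mask = vessel_mask, faz_mask = faz_mask,
       centerlines = centerlines)
}

#' Generate a synthetic SCP/DCP angiogram pair with ground truth
#'
#' Draws `n_vessels` smooth curves crossing the field, each perturbed by a
#' sinusoid of amplitude `tortuosity_amp`, dilated to the vessel radius and
#' excluded from a central quasi-circular avascular zone; adds speckle noise
#' and a multiplicative illumination ramp. The deep layer is generated from an
#' independent sub-seed with denser, finer capillaries.
#'
#' @param spec A [phantom_spec()].
#' @return A list with [angiogram] elements `scp` and `dcp` and a `truth`
#'   list (class `phantom_truth`): superficial `vessel_mask` and `faz_mask`,
#'   per-vessel centerline polylines with polyline geodesic and chord lengths,
#'   deep-layer masks, and the generator parameters.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  n_px <- spec$image_px
  mm_per_px <- spec$fov_mm / n_px
  faz_px <- spec$faz_radius_mm / mm_per_px
  amp_px <- spec$tortuosity_amp * 20

  set.seed(spec$seed)
  ks <- 2:5
  a <- stats::rnorm(length(ks))
  a <- a / sum(abs(a))
  harmonics <- cbind(k = ks, a = a, psi = runif(length(ks), 0, 2 * pi))
  scp_l <- render_layer(n_px, spec$n_vessels, amp_px, spec$vessel_radius_px,
                        faz_px, spec$faz_irregularity, harmonics,
                        spec$noise_sigma, spec$bias_strength, mesh = FALSE)
  set.seed(spec$seed + 1000003L)
  dcp_l <- render_layer(n_px, round(1.6 * spec$n_vessels), amp_px * 0.8,
                        max(1, 0.55 * spec$vessel_radius_px),
                        faz_px, spec$faz_irregularity, harmonics,
                        spec$noise_sigma, spec$bias_strength)
  truth <- structure(list(
    vessel_mask = scp_l$vessel_mask,
    faz_mask = scp_l$faz_mask,
    centerlines = scp_l$centerlines,
    dcp_vessel_mask = dcp_l$vessel_mask,
    dcp_faz_mask = dcp_l$faz_mask,
    params = unclass(spec)
  ), class = "phantom_truth")
  list(
    scp = angiogram(scp_l$image, layer = "SCP", fov_mm = spec$fov_mm),
    dcp = angiogram(dcp_l$image, layer = "DCP", fov_mm = spec$fov_mm),
    truth = truth
  )
}

#' Stage-parameterized phantom profiles
#'
#' Ordinal parameter ramps for the six cohort labels. They encode the trend
#' directions expected with disease onset and progression — tortuosity,
#' caliber, and foveal metrics increase while vessel density and perimeter
#' index decrease — with the diabetic branch dominated by capillary loss and
#' foveal enlargement and the sickle-cell branch by markedly higher
#' tortuosity. They are ordinal ramps, not biophysical models.
#'
#' @return Named list (one entry per label) of [phantom_spec()] overrides.
#' @export
octa_stage_profiles <- function() {
  list(
    control       = list(n_vessels = 30, tortuosity_amp = 0.20,
                         vessel_radius_px = 2.0, faz_radius_mm = 0.30,
                         faz_irregularity = 0.08),
    mild_npdr     = list(n_vessels = 26, tortuosity_amp = 0.25,
                         vessel_radius_px = 2.2, faz_radius_mm = 0.34,
                         faz_irregularity = 0.12),
    moderate_npdr = list(n_vessels = 22, tortuosity_amp = 0.30,
                         vessel_radius_px = 2.4, faz_radius_mm = 0.38,
                         faz_irregularity = 0.16),
    severe_npdr   = list(n_vessels = 18, tortuosity_amp = 0.35,
                         vessel_radius_px = 2.6, faz_radius_mm = 0.43,
                         faz_irregularity = 0.20),
    mild_scr      = list(n_vessels = 26, tortuosity_amp = 0.50,
                         vessel_radius_px = 2.3, faz_radius_mm = 0.36,
                         faz_irregularity = 0.12),
    severe_scr    = list(n_vessels = 21, tortuosity_amp = 0.80,
                         vessel_radius_px = 2.5, faz_radius_mm = 0.42,
                         faz_irregularity = 0.18)
  )
}

#' Cohort labels
#' @return Character vector of the six cohort labels in severity order.
#' @export
octa_labels <- function() {
  c("control", "mild_npdr", "moderate_npdr", "severe_npdr",
    "mild_scr", "severe_scr")
}

#' Generate a labelled phantom cohort
#'
#' Per label, draws `n_per_group` subjects whose generator parameters jitter
#' around the group profile (within-group biological variation), and returns a
#' manifest of fully resolved per-subject [phantom_spec()]s plus, optionally,
#' the materialized images.
#'
#' @param stage_profiles Named list of parameter overrides per label
#'   (default [octa_stage_profiles()]).
#' @param n_per_group Subjects per label (minimum 2).
#' @param seed Integer seed.
#' @param base Baseline [phantom_spec()] the profiles modify.
#' @param jitter_sd Relative SD of the per-subject parameter jitter.
#' @param keep_images Materialize the images (memory-heavy); otherwise the
#'   manifest's specs regenerate them deterministically on demand.
#'
#' @return A list with `manifest` (tibble: subject_id, eye, label, spec) and,
#'   if `keep_images`, `images` (list of `generate_phantom()` outputs).
#' @export
generate_cohort <- function(stage_profiles = octa_stage_profiles(),
                            n_per_group = 10, seed = 1L,
                            base = phantom_spec(), jitter_sd = 0.06,
                            keep_images = FALSE) {
  if (n_per_group < 2) stop("n_per_group must be at least 2")
  missing_labels <- setdiff(octa_labels(), names(stage_profiles))
  if (length(missing_labels)) {
    stop("stage_profiles must cover all labels; missing: ",
         paste(missing_labels, collapse = ", "))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  rows <- list()
  images <- list()
  sid <- 0
  for (lab in names(stage_profiles)) {
    prof <- utils::modifyList(unclass(base), stage_profiles[[lab]])
    for (i in seq_len(n_per_group)) {
      sid <- sid + 1
      jit <- function(x) x * exp(stats::rnorm(1, 0, jitter_sd))
      sp <- phantom_spec(
        image_px = prof$image_px, fov_mm = prof$fov_mm,
        n_vessels = max(5L, prof$n_vessels + sample(-2:2, 1)),
        tortuosity_amp = jit(prof$tortuosity_amp),
        vessel_radius_px = jit(prof$vessel_radius_px),
        faz_radius_mm = jit(prof$faz_radius_mm),
        faz_irregularity = jit(prof$faz_irregularity),
        noise_sigma = prof$noise_sigma,
        bias_strength = prof$bias_strength,
        seed = sample.int(2^30, 1)
      )
      rows[[sid]] <- tibble::tibble(
        subject_id = sprintf("P%03d", sid), eye = "OD", label = lab,
        spec = list(sp))
      if (keep_images) images[[sid]] <- generate_phantom(sp)
    }
  }
  out <- list(manifest = dplyr::bind_rows(rows))
  if (keep_images) out$images <- images
  out
}

#' Extract features for a whole phantom cohort
#'
#' Runs [extract_all_features()] over a cohort manifest, regenerating each
#' phantom pair from its spec (no images are retained between rows).
#'
#' @param cohort Output of [generate_cohort()].
#' @param config Parameter list from [octa_config()].
#' @param progress Emit one message per subject.
#' @return A tibble with one feature row per eye (the cohort table).
#' @export
extract_cohort_features <- function(cohort, config = octa_config(),
                                    progress = FALSE) {
  man <- cohort$manifest
  if (!nrow(man)) stop("empty cohort manifest")
  rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    ph <- if (!is.null(cohort$images)) cohort$images[[i]]
          else generate_phantom(man$spec[[i]])
    rows[[i]] <- extract_all_features(
      ph$scp, ph$dcp, config = config,
      subject_id = man$subject_id[i], eye = man$eye[i], label = man$label[i])
    if (progress) message(sprintf("extracted %s (%s)", man$subject_id[i],
                                  man$label[i]))
  }
  dplyr::bind_rows(rows)
}
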