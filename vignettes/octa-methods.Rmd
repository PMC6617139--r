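---
title: "Quantitative OCTA features and hierarchical retinopathy classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative OCTA features and hierarchical retinopathy classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Optical coherence tomography angiography (OCTA) produces en-face maps of
retinal blood flow, resolved by vascular layer (superficial and deep capillary
plexus, SCP and DCP). Retinovascular disease — diabetic retinopathy (DR) and
sickle-cell retinopathy (SCR) in particular — distorts this vasculature in
quantifiable ways: capillary dropout lowers perfusion density, vessels become
more tortuous, the foveal avascular zone (FAZ) enlarges and its boundary grows
irregular. `octaclass` measures these distortions as a 13-scalar feature
vector per eye, selects the most diagnostic feature combination per screening
task by stepwise backward elimination, and evaluates a hierarchical
support-vector-machine classifier: control vs. disease, then DR vs. SCR, then
severity staging within each disease.

No clinical images ship with the package. Every stage is validated against a
synthetic vascular phantom generator with analytic ground truth, so the full
chain is testable end to end.

## The features

All images are preprocessed by min–max window normalization to `[0, 1]`.
Six quantities are measured, some per layer and per region, giving 13 scalars:

* **BVT** (blood vessel tortuosity, SCP): the skeleton is decomposed into
  branches at junction pixels; each branch contributes the ratio of its
  geodesic (along-path) length to the Euclidean distance between its
  endpoints, and BVT is the unweighted mean ratio. A straight vessel scores
  exactly 1, a semicircular course $\pi/2$.
* **BVC** (caliber, SCP, µm): vessel-map area divided by skeleton length —
  the mean vessel width.
* **VPI** (vessel perimeter index, SCP): fraction of image pixels on the
  vessel boundary (4-neighbour definition, image border counts as
  background).
* **BVD** (vessel density, both layers, rings C1–C3): each pixel gets a local
  box-counting fractal dimension in `[0, 1]` (window 16 px, dyadic box sizes,
  slope normalized by 2); pixels at or above 0.7 count as vessel. Density is
  the vessel-pixel fraction within three rings of diameter 2, 4, and 6 mm
  around the fovea (disjoint annuli by default), with the segmented FAZ
  excluded and the ring itself as the denominator.
* **FAZ-A** (both layers, µm²): FAZ pixel count times the physical pixel area
  ($\mathrm{(mm/px \cdot 1000)^2}$).
* **FAZ-CI** (both layers): FAZ contour perimeter divided by the perimeter of
  the equal-area circle, $P / 2\sqrt{\pi A}$, computed from one sub-pixel
  polygon for both $P$ and $A$ (shoelace). A circle scores 1.

## Segmentation

The vessel map is the union of two routes, both thresholded by a local
adaptive rule (31-px window mean − 0.02, plus an absolute floor) and cleaned
morphologically (components < 20 px removed, holes < 10 px filled):

1. a **flow-gated multi-scale Hessian vesselness** (scales 1, 2, 4, 8 px,
   bright-ridge polarity, β = 0.5, per-scale adaptive structureness cutoff),
   multiplied by the normalized intensity — the gating suppresses the halo
   that coarse Hessian scales paint around thin vessels;
2. the **normalized flow intensity itself** — ridge filters are blind to
   confluent perfusion (a solid sheet has no tube contrast), which the
   intensity route recovers.

The skeleton uses Guo–Hall two-subiteration thinning (it resolves the
two-pixel diagonal bands simpler schemes leave), followed by removal of
redundant staircase-corner pixels. Branch decomposition cuts at junctions
(crossing number ≥ 3; irreducible 2×2 crossing centres count as junctions)
and measures each branch's geodesic length on a lightly smoothed polyline:
the raw (1, √2) chain length overestimates smooth curves by 3–8% depending
on orientation, while the smoothed polyline is exact for straight runs and
lands a rasterized semicircle within 0.1% of $\pi R$. Branches whose
geodesic-to-Euclidean ratio exceeds 2 are excluded from BVT as segmentation
artifacts — medial axes that double back through tangential vessel merges —
since even a semicircular anatomical course only reaches $\pi/2 \approx 1.57$.

The FAZ is segmented by a region-based (edge-free) active contour of the
Chan–Vese family, evolved morphologically on a Gaussian-smoothed
vessel-density image from a small disk at the image centre (scans are
macula-centred). Region-based evolution is used because capillary dropout
gives OCTA weak gradients at the FAZ rim. The contour is constrained to a
1.5 mm foveal search radius — generous for any plausible FAZ — which
prevents leakage through peripheral avascular gaps; a contour touching the
image border still warns. The final mask's sub-pixel contour comes from
marching squares on a smoothed indicator, so FAZ-CI is not dominated by
pixel staircase (rasterized perimeters carry a systematic ≈ +27% bias).

### Bias-field correction

`correct_bias_field()` estimates a multiplicative illumination field from the
background floor (light smoothing, grayscale opening wide enough to remove
vessels, heavy smoothing) and divides it out with a robust re-window. The
estimator assumes vessels are sparse at the opening scale and that a
measurable background floor exists; both are stated preconditions, and the
function declines (with a message) when the floor is too weak or the
estimated field varies more than ~2.5-fold — such fields indicate confluent
foreground leaking into the estimate, not illumination. For the default
pipeline the correction is **off**: on dense macula-centred angiograms (and
on the phantoms) the floor estimate is contaminated by confluent perfusion,
and dividing by a contaminated field sharply degrades ground-truth vessel
recovery, while the local adaptive threshold already neutralizes the mild,
slowly varying illumination ramps such images carry. Set
`octa_config(bias_correct = TRUE)` for sparse-field images where the
assumptions hold.

## Feature selection and classification

Per task, features are first screened univariately: a one-predictor logistic
model (binomial, or multinomial for the three-class staging task) with a
likelihood-ratio test, keeping features with p < 0.15. Backward elimination
then starts from the survivors, repeatedly removing the predictor with the
largest single-term-deletion likelihood-ratio p while that p ≥ 0.10 (ties
broken by lower single-feature cross-validated accuracy), and finally reports
which retained features also meet the stricter p < 0.05. Both printed
thresholds are kept: iteration at 0.10, reporting against 0.05. Each step
logs the refitted model's cross-validated SVM accuracy; if everything is
eliminated the single best feature by accuracy is returned with a flag.
Aliased (collinear) predictors get p = 1 and leave first; a non-converging
logistic fit has its iteration cap raised and the event recorded in the
trace notes rather than silently ridge-penalized, because no available
penalized fit yields the likelihood-ratio p-values the procedure is built on.

Classification uses a support-vector machine with a linear kernel, unit cost,
and class-balanced weights — with at most a handful of features and modest
cohort sizes, the lowest-variance choice; kernel and cost are configurable.
Evaluation is stratified 5-fold cross-validation, grouped by subject so two
eyes of one subject never straddle a fold (leakage-safe default, toggleable),
with standardization fitted on training folds only. Metrics are computed on
the pooled out-of-fold predictions: sensitivity, specificity, accuracy, and
the ROC/AUC from a full threshold sweep with trapezoidal integration (ties
count one half, matching the Mann–Whitney formulation to 1e-9). Multi-class
tasks use one-vs-one voting for labels; the macro-averaged one-vs-rest AUC
scores each class by its pairwise vote count with a bounded margin
tie-breaker. Votes are piecewise in feature space, so the middle class of an
ordinal triplet can outscore both neighbours — a single linear one-vs-rest
decision value cannot do that, which structurally caps the middle class's
AUC near chance — and unlike Platt probability estimates the scores are
deterministic (libsvm's probability fit draws from a random stream outside
R's control).

The hierarchy wires four trained stages: control vs. disease; DR vs. SCR on
"disease" outputs; NPDR staging (mild/moderate/severe, 3-class) on the DR
branch and SCR staging (mild/severe) on the SCR branch. Every input receives
exactly one leaf label. Stage metrics are reported on each stage's true
sub-cohort; end-to-end routing (with error propagation) is available through
`predict()` on the assembled model.

## The phantom generator

`generate_phantom()` emulates the *image class* of macula-centred en-face
angiograms, not any particular retina: bright curvilinear vessels on a dark
background, a central avascular zone, speckle, and an illumination ramp. The
geometry is a radial tree, mirroring perifoveal architecture: trunks run
outward from the avascular-zone rim with a sinusoidal transverse wiggle
(amplitude = `tortuosity_amp` × 20 px, wavelengths 50–90 px, tapering in
over ~50 px), spawning straight child branches at small angular offsets, with
a terminal capillary ring of short arcs hugging the avascular-zone boundary.
The radial layout is deliberate: vessels laid as random chords cross each
other so densely that inter-junction skeleton branches become too short to
carry any tortuosity signal — radial trees keep branches long. The deep
layer adds circumferential mesh arcs (denser, finer capillaries) from an
independent sub-seed; the superficial layer omits them so tortuosity is
measured on uncut trunks. The avascular-zone boundary is a circle of radius
`faz_radius_mm` perturbed by low-order harmonics with relative amplitude
`faz_irregularity`. Rendering applies a small point-spread blur, a background
flow floor, multiplicative exponential speckle, detector saturation, an
illumination ramp, and 8-bit quantization, as exported device images carry.
Every curve's centerline is kept as an analytic polyline with exact geodesic
and chord lengths, so tortuosity oracles need no segmentation.

Defaults (304 × 304 px, 6 mm field, 30 vessels, amplitude 0.2, radius 2 px,
FAZ radius 0.30 mm, irregularity 0.08, speckle 0.15, ramp 0.15) give
disease-free images with vessel fractions around 0.3–0.4 and measured FAZ
areas within a few percent of truth. The cohort profiles are *ordinal
parameter ramps*, not biophysical models: with disease onset and progression
tortuosity, caliber, and foveal metrics ramp up while vessel count (hence
density and perimeter index) ramps down; the diabetic branch is dominated by
capillary loss and foveal enlargement, the sickle-cell branch by markedly
higher tortuosity. Within-group variation is log-normal jitter (6% SD) per
subject. What passing tests show is therefore that the *mechanics* — every
operator, the selector, the classifier, and their composition — behave
correctly and track known ground truth monotonically; they say nothing about
clinical effect sizes, scanner artifacts, media opacity, motion, or
projection artifacts, none of which the generator attempts.

## Numerical choices and degenerate inputs

* Constant images window-normalize to all-zero with a warning.
* An empty branch list, empty skeleton, empty FAZ mask, or a measurement
  region fully covered by the exclusion mask raise "undefined feature"
  errors naming the feature rather than returning silent zeros.
* Closed-loop branches (zero chord) are excluded from BVT and counted.
* Constant decision scores yield the degenerate two-point ROC with AUC 0.5
  and a warning.
* The active contour caps at 500 iterations and flags non-convergence;
  convergence is mask fixed-point, so results are deterministic.
* The local fractal dimension uses dyadic box sizes 1–16 anchored at each
  centred window; fully filled windows hit slope 2 (value 1) and straight
  lines slope 1 (value 0.5) exactly.
* Elimination ties on p (within 1e-12) break toward the feature with lower
  single-feature cross-validated accuracy.
* Folds shrink (with a warning) when a class has fewer members than folds.

## Problem sizes used in validation

The shipped validation suite runs entirely on synthetic data: dose-response
sweeps use 10 parameter levels × 5 replicates per feature axis (Spearman
rank correlation on per-level means, since replicates exist to average
extraction noise); selector-recovery simulations use 60 eyes per class with
2-SD effects over 50 seeds; the end-to-end screen uses 20 subjects per group
(120 eyes) plus a held-out set of 2 per group. These sizes were chosen to
match the cohort scale of a typical single-centre OCTA study while keeping
the whole suite comfortably runnable on a laptop.

## Known limitations

* The phantom's disease profiles are ordinal and synthetic; classifier
  accuracies on phantoms say nothing about clinical accuracy.
* BVT on dense plexus is measured between junctions; heavy anastomosis
  shortens branches and compresses the tortuosity scale (the dose-response
  stays monotone, which is what the validation asserts).
* The FAZ contour assumes a macula-centred scan; off-centre scans need an
  explicit seed.
* Bias-field correction requires a visible background floor and sparse
  vessels at the opening scale; it declines rather than guesses when those
  fail.
* The univariate profile applies Bonferroni across the 13 features only, not
  across tasks.
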