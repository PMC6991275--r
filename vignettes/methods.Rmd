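---
title: "Methods: wide-field OCTA microvascular quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wide-field OCTA microvascular quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octawide)
```

# Scope and model

`octawide` quantifies retinal microvascular status from wide-field en-face
OCTA maximum projections. The canonical acquisition is a 12 × 12 mm field
sampled at 500 × 500 A/B-scans, i.e. 24 µm pixels; the package works on any
grid once the physical extent is known, but several defaults are tuned to
that sampling density and this vignette flags where.

The analysis assumes: (i) perfused vasculature is bright against a darker
background (decorrelation polarity); (ii) large vessels are tubular, roughly
0.1–0.3 mm wide, and substantially brighter than the capillary texture;
(iii) where the structural OCT signal is lost, absence of flow signal is
uninterpretable and must be excluded rather than scored as nonperfusion;
(iv) the inner-retinal plexuses are *not* separated — the input is a single
projection.

## Large-vessel filter

Two complementary tubularity detectors are combined:

* **Gabor bank.** Even-phase, zero-DC Gabor kernels, σ = 0.56 λ (one-octave
  bandwidth), aspect γ = 0.5, at wavelengths {6, 10, 16} px over 12 evenly
  spaced orientations (15° apart). Negative responses are clipped (bright
  bars only) and the maximum over the bank is taken.
* **Hessian (Frangi-style) vesselness.** Scale-normalised Gaussian-derivative
  Hessians at scales {2, 4, 8} px; β = 0.5, the structureness scale c set
  adaptively to half the per-scale maximum; only λ₂ < 0 (bright ridge)
  responses count.

Each map is min–max normalised to [0, 1] before combination (default
pixelwise `max`), so neither branch dominates through its raw scale, and the
result is invariant to a global intensity gain. The wavelength/scale defaults
target vessels ~4–12 px wide, the calibre of the arcades at 24 µm pixels; at
other pixel sizes the defaults in `filterParams()` should be rescaled
accordingly. Binarisation is Otsu's threshold on the combined response (a
fixed threshold can be pinned for exact reproducibility), constrained to
pixels brighter than the image median, with connected specks below
0.01 mm² removed so capillary fragments never enter the large-vessel class —
important because the capillary threshold references this mask's mean
intensity, and because large-vessel density should reflect large vessels.

Degenerate input: a constant image produces an identically zero response
(guarded normalisation, no division by zero) and an empty mask with a
message.

## Capillary segmentation

The adaptive threshold follows the local vessel signal: windows of
3 × 3 mm slide at 1.5 mm steps; in each window the threshold is
0.35 × mean angiogram intensity over the large-vessel pixels it contains.
Design choices the procedure leaves open, and how they are resolved here:

* *Which vessel mean?* The per-window mean, since the rule is stated per
  window — but peripheral windows can be nearly vessel-free, so windows
  holding fewer than 50 vessel pixels (configurable) fall back to the global
  vessel mean.
* *Overlapping votes.* With window = 2 × step, interior pixels are covered
  by exactly four windows. Disjoint tiling produces visible seams at window
  borders; instead every covering window votes `intensity ≥ t_w` and the
  majority decides, ties counting as perfused. An `any` rule is available
  for sensitivity analysis.
* *Window membership* is decided by pixel centres against half-open mm
  intervals, making the vote count exact and deterministic; if the step does
  not divide the field, one border-flush window per axis guarantees
  coverage (for the 12/3/1.5 geometry it never fires).
* *Disjoint classes.* Large-vessel pixels are removed from the capillary
  mask, so TPD = CPD + LVD holds as an identity rather than approximately.

An empty vessel mask is a hard error: the threshold has no referent, and
silently substituting a fixed cutoff would change the metric's meaning.

## Low-signal masking

The structural image is averaged over 0.6 mm blocks; pixels whose local mean
falls in the lowest 5% of block means *and* below half the image mean are
flagged. The second condition keeps artifact-free images from losing a fixed
5% of their area — a pure quantile rule has no notion of "no artifact
present". Flagged pixels leave every downstream mask and every area
denominator.

## Nonperfusion and the dropout rule

Nonperfusion is the complement of perfusion within the valid area. Its
connected components are labelled 8-connected by default (diagonal gaps
merge visually continuous nonperfusion; 4-connectivity is available), and a
component is dropout only if its area **strictly exceeds 0.36 mm²** — at
24 µm pixels, 625 pixels is exactly 0.36 mm² and is rejected; 626 are kept.
Manual FAZ and optic-disc masks remove *whole touching components* by
default (pixel-level subtraction is available): the FAZ is physiologically
avascular, and subtracting only its pixels would leave a ring-shaped residue
of its surround counted as dropout. Exclusion happens before the area
threshold. Border-touching components are kept and flagged, since peripheral
dropout is precisely the signal of interest; an option drops them.

## Regions and metrics

Two independent region schemes cover the field: wide = central 6 × 6 mm
square + square annulus, and a 5 × 5 grid of 2.4 mm blocks. The block grid
is treated as a partition of the *full* field (a 2.4 mm grid cannot tile a
6 mm central square, so the annulus cannot literally "consist of" such
blocks; the two schemes are kept separate and both reported). Membership is
by pixel centre, so the 25 blocks partition the field exactly and
area-weighted block metrics reassemble the wide-field metric to numerical
precision. Dropout components straddling region boundaries are attributed
per pixel, preserving that additivity. Exclusions are removed from numerator
and denominator alike (a full-region denominator is available behind a
switch). A region with zero valid area yields a record flagged invalid
rather than a division by zero.

# Synthetic phantoms

`generatePhantom()` renders what the pipeline assumes: random-walk vessel
tubes entering from the border with tapering calibre (intensity ≈ 0.9), a
perfused capillary mesh (≈ 0.5) over a 0.05 background, a light 0.4 px blur,
multiplicative log-normal speckle (decorrelation angiograms are
speckle-dominated; default σ = 0.15), optional dropout disks that erase the
mesh but never the large vessels, and low-signal patches darkening both
images. Defaults — 12 × 12 mm / 500 × 500, 8 vessel trees 4–12 px wide,
55% capillary fill — sit in the range the pipeline's own output reports for
healthy wide-field scans.

Two generator details matter for correctness:

* **The mesh is cellular, not blob noise.** A single median level-set of
  smoothed noise has two elongated percolating phases, and its unperfused
  interiors can exceed 0.36 mm², poisoning the dropout baseline. The mesh is
  therefore the union of the boundary sets of *two* independent level-set
  tessellations at different scales (cell scale 0.053 mm, physical), dilated
  via the distance transform to hit the target fill fraction exactly (a
  small jitter breaks distance ties). The unperfused area then decomposes
  into compact intercapillary cells far below the cutoff, as in a real
  angiogram. This holds at the canonical sampling density; on much coarser
  grids normal cells approach the physical cutoff and the baseline dropout
  floor rises — a property of the area rule itself, so recovery experiments
  are run at 500 × 500.
* **Ground-truth dropout is rule-derived.** A dropout disk cuts the mesh,
  and the intercapillary cells along its rim join its nonperfusion
  component. The truth mask is therefore computed by applying the same
  8-connected, > 0.36 mm² rule to the *truth* perfusion masks, so designed
  and pipeline-measured CDD quantify the same geometric object and their
  difference isolates segmentation error.

Cohorts (`generateCohort()`) draw a per-subject random effect on the fill
fraction (truncated normal, SD 0.03) shared by both eyes, inducing the
intra-subject correlation the clustered bootstrap exists to handle; severity
is encoded as a nondecreasing number of dropout disks per group, optionally
eccentricity-biased (radial acceptance weight (d/d_max)^bias) to emulate
predominantly peripheral dropout.

What the phantoms do *not* emulate: physical OCT speckle statistics, motion
and projection artifacts, vessel branching morphology beyond a single side
branch, systematic large-vessel calibre differences between groups (so the
real-data rationale for CPD outperforming TPD — large vessels confounding
perfusion — is only weakly present), and fovea-centred anatomy (no FAZ is
rendered; exclusion masks are exercised with synthetic disks). Passing
recovery tests on phantoms therefore validates the algorithmic chain, not
clinical performance.

# Statistics

* **ICC**: two-way random-effects, absolute agreement, single measurement —
  the standard test-retest variant — computed from the ANOVA mean squares;
  bands poor/moderate/good/excellent at 0.50/0.75/0.90, a value exactly at
  a cutpoint falling in the lower band. Zero total variance reports an
  undefined ICC rather than 0/0.
* **Group contrasts**: each metric is z-normalised over *all* eyes in the
  table (pooled, not per comparison pair — one scale for all contrasts of a
  family), and the mean difference is bootstrapped by resampling subjects
  with replacement within each group, carrying every eye of a resampled
  subject. CIs are percentile (2.5, 97.5); the two-sided p-value uses the
  (count + 1)/(B + 1) continuity correction so finite replicates never
  produce p = 0. B defaults to 1000. Each group draws from its own RNG
  substream keyed by (seed, group name), so results are independent of the
  order groups are listed and a comparison and its reverse are exact
  mirror images.
* **Trend**: the linear orthogonal contrast of group means (−1, 0, 1 for
  three ordered groups; −3, −1, 1, 3 for four), with significance from the
  same subject-clustered bootstrap engine rather than a classical F test —
  one inferential engine throughout, and eye clustering is honoured either
  way.
* **FDR**: Benjamini–Hochberg step-up across the whole family of
  (metric × comparison) cells of a region scheme.
* **ROC/AUC**: the Mann–Whitney statistic (ties ½) with DeLong variance;
  correlated AUCs compared by the paired DeLong test on placement values.
  Score polarity is *declared* (`positiveLow`), never auto-flipped — an
  auto-oriented AUC can silently report max(AUC, 1 − AUC). Eyes are treated
  as independent observations in the DeLong computation, as the standard
  algorithm does; the known limitation that eyes cluster within subject is
  accepted there and documented rather than corrected.

# Verification problem sizes

The test suite validates each stage against independent oracles:
brute-force flood-fill labelling on 100 random 64 × 64 masks, exhaustive
concordant-pair AUC counting on fixtures up to 50 observations, an
`aov`-based mean-squares oracle for the ICC, a placement-value computation
for the DeLong variance, and a stand-alone step-up implementation for BH on
1000 random p-vectors. Recovery experiments use 20 canonical 500 × 500
phantoms across designed dropout levels (noiseless and speckled), and
bootstrap calibration uses 500 simulated cohorts of 30 subjects × 2 eyes
per group at intra-subject correlation 0.5 with B = 500 — sizes chosen to
make Monte-Carlo noise small relative to the property being checked while
keeping the default suite runnable in minutes on one CPU.

# Known limitations

* Filter scales are stated in pixels; grids far from 24 µm sampling need
  rescaled `filterParams()`.
* The 0.36 mm² rule is resolution-honest but its interaction with very
  coarse grids (pixel area comparable to normal intercapillary cells)
  inflates baseline CDD.
* No automatic image-quality gate: quality exclusion criteria in real
  studies are qualitative, so only explicit exclusion lists are honoured.
* FAZ and optic-disc delineation is manual by design; masks are inputs.
* Laterality-aware analyses (e.g. temporal-quadrant pooling across OD/OS)
  are not implemented; metrics are computed in scan coordinates.
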