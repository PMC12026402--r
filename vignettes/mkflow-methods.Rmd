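---
title: "Identifying megakaryocytes in imaging flow cytometry data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying megakaryocytes in imaging flow cytometry data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkflow)
```

## The problem

Megakaryocytes (MKs) are rare, large, polyploid bone-marrow cells; their
abnormally small counterparts, micromegakaryocytes (7–15 µm), are a
dysplasia marker in myelodysplastic neoplasms. Identifying MKs by
conventional flow cytometry is hampered by two artifacts: the largest MKs
overlap doublets and aggregates in area-based singlet gates, and platelets
adhering to CD41⁻ cells give those cells a false MK-like CD41⁺
immunophenotype. Imaging flow cytometry (IFC) captures a multichannel image
of every event, which makes both artifacts addressable: a discriminant over
image morphometrics replaces the area/aspect-ratio singlet gate, and the
*spatial pattern* of the CD41 signal — many spots distributed along the cell
perimeter for a true CD41⁺ membrane versus a few bright spots from adherent
platelets — separates true MKs from platelet-decorated false positives.

`mkflow` implements that pipeline end to end: morphometric feature
extraction, spillover compensation, a hierarchical gating cascade, a
linear-discriminant (LDA) singlet gate, a small convolutional network (CNN)
for the platelet-adhesion artifact, confusion-matrix evaluation, and a
parametric synthetic event-image generator that provides ground truth for
validating every stage.

## Data model

An `EventSet` holds one co-registered raster per channel per event, the
acquisition time, and an object id. Channels are addressed by *marker role*
(`bf`, `cd41`, `cd45`, `ssc`, `dump`, `dna`, `viability`) through a
`PanelConfig`, never by hard-coded channel id; the default layout puts
brightfield in Ch01, CD41 in Ch03, SSC in Ch06, CD45 in Ch08, the pooled
dump markers (CD3/CD19/CD15/CD64) in Ch10, the DNA dye in Ch11 and the
viability dye in Ch12, at 0.5 µm/px (a 40× objective with a 60 µm field of
view) and 12-bit dynamic range. The 12-bit default (0–4095) is the range in
which the conventional saturation cutoff of 4030 raw counts is expressed;
it remains configurable because vendor raw formats do not document the
native bit depth. Galleries are interchanged as a 16-bit multipage TIFF
plus a CSV index (`object_id, time_s, channel, file, page`) — proprietary
vendor files are deliberately not parsed — and round-trip pixel-exactly.
Feature tables export to CSV and to minimal, standards-conforming FCS 3.1
(float32, little-endian) for use in conventional cytometry software.

## Morphometric features

The vendor software's mask and feature formulas are unpublished, so the
definitions below are this package's normative ones, chosen so the
conventional thresholds (raw max pixel < 4030, gradient RMS > 55, diameters
in µm) keep their meaning. All thresholds stay configurable.

* **Default mask** — Otsu threshold on the Gaussian-smoothed (σ = 1.5 px)
  absolute deviation from the border-frame background level, hole-filled,
  largest connected component. Using the 3-px border frame rather than the
  global median as the background reference matters for the largest MKs,
  which can cover more than half the field of view and would invert a
  median-referenced mask. An empty or tiny (< 25 px) foreground flags the
  mask invalid; downstream gates treat such events as failing.
* **Morphology mask** — the default mask closed (5-px disc) and eroded by
  1 px: the tight boundary used for size features. The erosion shrinks the
  equivalent diameter of rendered test discs by a stable ≈1.4 µm; the
  offset is small against the 10.5–51.5 µm MK range and identical for all
  classes, so gates and classifiers are unaffected.
* **Area / diameter / aspect ratio** — pixel count × pixel area;
  `2·sqrt(area/π)`; minor/major axis ratio of the second-moment ellipse
  (1 for a circle, ≈0.45 for two touching equal discs).
* **Raw max pixel** — the maximum pixel of the *uncompensated* raster; by
  contract never touched by compensation.
* **Gradient RMS** — RMS over the mask pixels of the 3×3 Sobel gradient
  magnitude of the raster rescaled to [0, 100] by bit depth. Sobel (the
  smoothed 3×3 central difference) rather than the bare 2-tap central
  difference puts realistic in-focus texture at ≈70–88 on this scale and
  defocused events (σ ≥ 3 px) at ≈5–20, so the conventional focus
  threshold of 55 separates them cleanly. Constant rasters score exactly
  0, the score is invariant to adding a constant, and Gaussian blur
  strictly lowers it on textured images.
* **Intensity** — background-subtracted sum over the 3-px-dilated default
  mask (the dilation captures membrane spots sitting on the cell
  perimeter); background is the median of the pixels outside a further
  3-px dilation. The median rather than the mean makes the estimate robust
  to stray platelet spots in the background.

## Spillover compensation

A spillover matrix is estimated from single-stain controls by
zero-intercept least squares: entry (i, j) is the slope of channel-j total
intensity on channel-i total intensity over the control-i events, the
diagonal is fixed at 1, and negative slopes are clamped to 0 (spillover is
physically nonnegative and proportional). Compensation right-multiplies
per-event intensity vectors by the matrix inverse; it acts on scalar
intensities, not pixels, because every downstream gate consumes
intensities. On noiseless synthetic controls the generating matrix is
recovered exactly; under Poisson shot noise the attenuation bias of the
zero-intercept slope is negligible because per-event total intensities vary
far more across events than their shot noise.

## The gating cascade

Gates run in a fixed order, each feeding the survivors of the previous one,
with per-gate attrition recorded in a `GatingReport`:

1. **Stable flow** — auto mode bins event times
   (`clamp(n/15, 8, 40)` bins) and keeps the largest contiguous run of bins
   whose counts sit within `max(3·mad, 2·sqrt(median)+1)` of the median
   count; the Poisson floor keeps ordinary counting noise from fragmenting
   a steady acquisition. An explicit time window is also accepted.
2. **Unsaturated** — raw max pixel strictly below 4030 in every checked
   channel.
3. **Viable** and **nucleated** — viability intensity at or below, DNA
   intensity above, their thresholds (reported as two sub-gates).
4. **Lymphocyte exclusion** — removes the CD45-high/SSC-low rectangle.
5. **CD41⁺ / dump⁻** — the MK-lineage selection.
6. **Singlet** — LDA score ≥ 0 (below).
7. **Focus** — gradient RMS > 55.
8. **CNN** — CD41-membrane-positive classification (below).

Gate placement that a cytometrist would do by eye is made explicit:
every intensity threshold is a number or `"auto"`. The auto rule is an Otsu
valley on `log1p` intensities with a unimodality guard — if the two sides
of the candidate cut are separated by less than 1.5 log units the
population is treated as single and the gate keeps everything. One rule
serves every auto threshold. A fixed-percentile rule (e.g. CD45 75th
percentile) was considered and rejected: whenever the population to be
excluded exceeds the percentile's complement (say 30 % lymphocytes against
a 75th-percentile cut), the threshold lands inside the excluded cluster and
caps its removal below what the gate is for; the valley rule has no such
coupling to mixture proportions. The guard is what makes degenerate inputs
safe — an all-MK sample has unimodal viability, DNA, CD45 and CD41
distributions, and every auto gate passes it untouched.

## The LDA singlet gate

The largest MKs overlap doublets in BF area and aspect ratio, so the
singlet gate is a two-class linear discriminant over ten features — area,
aspect ratio, diameter, gradient RMS and intensity, each from the
brightfield and CD41 channels (the vendor's exact feature list is
unpublished; this list is the package's documented, configurable choice).
Features are standardized; the pooled within-class covariance is
ridge-regularized with λ = 10⁻³·trace/p; the score is shifted so the
standardized class-mean midpoint scores exactly 0, signed so singlets are
positive, and divided by the pooled within-class SD of raw scores. The
normalization makes the published "keep score ≥ 0" rule scale-free:
rescaling any raw feature by a positive constant provably leaves every
score unchanged. Historically 28 tagged singlets and 52 tagged doublets
sufficed to train this gate; the synthetic benchmark reproduces that tally.

## The CNN classifier

The CNN separates two classes from BF + CD41 crops only: `cd41_pos` (true
membrane CD41, many perimeter spots) versus `cd41_neg` (platelet-adherent,
1–4 brighter spots anywhere on the cell). Crops are the bounding box of the
BF mask padded to a square, resized to 64×64, and min-max normalized per
channel per crop — the network judges the *pattern*, while cell size is
handled by morphometry.

The architecture (no vendor reference exists) is three 3×3 convolution
blocks of 16/32/64 filters with ReLU and 2×2 max pooling, global average
pooling, and a 2-way softmax — ~23k parameters, trained with Adam
(lr 10⁻³, β₁ = 0.9, batch 32) under dihedral augmentation (flips and 90°
rotations; flow-cell orientation is physically arbitrary). Training stops
when the training and validation accuracy curves have stayed within 0.02
of each other, or validation accuracy has not improved, for 6 consecutive
epochs — both rules gated on validation accuracy having moved well off
chance, so a not-yet-learning plateau cannot trigger them — with a floor
of 10 and a cap of 30 epochs; the weights of the best validation epoch are
kept. Training is bit-deterministic given (data, spec, seed): a single
seeded generator drives initialization, shuffling and augmentation, and
the implementation is single-threaded.

Truth sets are split into train/validation/test by stratified random
partition with largest-remainder rounding per class. An exact 80/10/10 is
not achievable for arbitrary counts, so realized counts and fractions are
always reported alongside the nominal ratios (794 objects at nominal
80/10/10 realize 636/79/79 here; a 610/92/92 partition realizes
76.8/11.6/11.6 %).

## Evaluation

Two-class confusion matrices feed accuracy `100·(TP+TN)/total`, precision
`100·TP/(TP+FP)`, recall `100·TP/(TP+FN)`, and F1, the harmonic mean of
precision and recall; per-class rows are support-weighted into averages.
Percentages are rounded half-up at 1 decimal place (the table convention),
with accuracy additionally reported at 2. Metrics with zero denominators
are reported as missing, never as 0, so they cannot silently deflate a
weighted average. Row- and column-normalized matrix views (the recall and
precision views) are part of every report.

## The synthetic generator

The generator is the package's study-condition module, not a test
convenience: its defaults encode the conditions the pipeline is meant to
handle, and every stage is validated against its ground truth.

* **Geometry** — 120×120 px canvas at 0.5 µm/px (the 40× field of view);
  MK diameters log-normal (median 22.5 µm, σ_log 0.32) truncated to
  10.5–51.5 µm; micromegakaryocytes uniform 7–15 µm; lymphocytes 7–10 µm;
  doublets are two touching discs of 12–26 µm.
* **Channels** — BF is a dark textured disc on a light background (the
  texture carries the sharpness signal the focus gate measures); DNA is a
  nuclear disc (absent for anucleate events); CD41 is 8–24 membrane spots
  on the mask perimeter for MK-lineage cells, or 1–4 brighter ~2 µm spots
  anywhere on the cell for platelet-adherent events; CD45/SSC/dump/
  viability are flat in-cell amplitudes per class (lymphocytes CD45-high/
  SSC-low/dump-positive, dead cells viability-high), scaled so summed
  intensities separate on a log scale despite the 5× cell-size range. The
  real instrument's intensity units are arbitrary; these scales are free
  parameters of the generator.
* **Corruption** — Poisson shot noise plus Gaussian read noise
  (σ = 25 counts), clipped to the bit depth; a configurable fraction of
  events is rendered out of focus (scene blurred at σ = 3 px before
  noise); a fraction receives a pixel-saturating CD41 blob; a fraction is
  assigned times inside a short high-rate window near the start of
  acquisition, giving the stable-flow gate something to remove.
* **Consistency by construction** — ground truth is drawn first (classes,
  diameters, flags, times), then events are rendered; the saturation flag
  is recomputed from the final rasters, so truth and pixels cannot
  disagree. Generation is a pure function of (config, seed).

What the generator does *not* emulate: real optics (no PSF model),
fluorescence spectra, ploidy-dependent DNA content, cell-shape irregularity
beyond discs, debris, and the long tail of real staining variability.
Passing tests on synthetic data therefore demonstrate that the pipeline's
logic is correct under the stated conditions — not that the trained CNN or
the auto thresholds transfer to any particular instrument without
recalibration on real controls.

## Problem sizes and numerical choices

The test suite and the reproduction script use deliberately moderate
problem sizes — galleries of a few hundred events, the 794-crop CNN
benchmark (412 positive/382 negative, the historical truth-set tally), 500
events per noisy compensation control, 2000 truth-only draws for the
diameter-distribution check — chosen so each check has enough statistical
resolution for its tolerance while the whole suite stays comfortably
CPU-sized. Monte-Carlo assertions use fixed seeds and tolerances derived
from the checked distribution (e.g. the MK median-diameter window [21, 24]
µm covers the binomial CI of a 500-draw median). Ties in the split's
largest-remainder rounding resolve toward the earlier partition; the LDA
ridge guarantees a defined discriminant whenever the truth classes are not
literally degenerate, and literal degeneracy (duplicated events, constant
features in both classes) is a hard error rather than a silent fit.

## Known limitations

Compensation is intensity-level, not per-pixel. The CD41-channel mask used
for LDA features can collapse to a single spot for sparse membrane
patterns; the discriminant carries this as one weak feature among ten. The
CNN's determinism guarantee is per build environment (BLAS and compiler
fixed); across different BLAS builds, final weights may differ in the last
float. The cascade's auto thresholds are calibrated on synthetic data only
and should be re-derived from controls for real acquisitions.
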