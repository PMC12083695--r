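---
title: "Methods: ISOI ratio imaging, WFR scoring and TTC volumetry in isoistroke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ISOI ratio imaging, WFR scoring and TTC volumetry in isoistroke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoistroke)
```

## The measurement problem

Widefield intrinsic signal optical imaging (ISOI) records cortical
reflectance under red light; whisker stimulation evokes a triphasic
fractional-change (dR/R) response in barrel cortex — an *initial dip*
(deoxyhemoglobin rise, dark relative to baseline), an *overshoot*
(blood-flow influx, bright) and a late *undershoot*. In the rat
permanent-MCAo model, topical lidocaine delivered through a small
skull-dura slit blocks neuronal activity in the imaged territory; the
scientific questions are (a) whether the whisker functional
representation (WFR) recovers by 24 h, quantified as thresholded areal
extent and peak amplitude of each signal phase, and (b) whether the
blocked territory proceeds to infarct, quantified from TTC-stained
coronal slices with edema correction.

`isoistroke` implements that measurement chain end to end, plus a
seedable generator that emulates the five-group study design so every
stage can be validated against known ground truth.

## Ratio imaging

Raw trials are 100 ms frame stacks. Analysis proceeds as:

1. **Frame summation** (`sum_to_analysis_frames()`): groups of five raw
   frames are summed into 500 ms analysis frames (SNR improvement);
   a trailing remainder is dropped with a warning.
2. **Ratio series** (`compute_ratio_series()`): each frame from stimulus
   onset onwards is divided by the single 500 ms frame immediately
   preceding onset, minus one. We use `ratio - 1` so thresholds
   "away from zero" and phase polarities are meaningful in dR/R units.
   The reference is deliberately a single frame, not a pre-stimulus
   average, and is recorded in the output provenance. Frame `k` spans
   `[0.5 k, 0.5 (k + 1))` s from onset (half-open intervals); reported
   times are frame mid-times. Zero-valued reference pixels abort with
   the offending pixel named; pixels at the 16-bit saturation level are
   flagged and excluded (`NA`).
3. **Trial averaging** (`average_trials()`): pixelwise mean across the
   block; shapes, timing and calibration must agree exactly.
4. **Smoothing** (`smooth_frame()`): separable Gaussian convolution.
   The kernel is parameterized by its half-width at half-maximum
   (default 5 px, i.e. sigma = 5 / sqrt(2 ln 2) ~ 4.25 px); "half
   width" is not defined more precisely in common usage, so the
   parameter is configurable and carried in the output rows. Boundaries
   use symmetric reflection so constants are preserved.

## Phase scoring

`phase_spec()` fixes the conventions per phase:

| phase          | polarity | threshold (dR/R) | frame selection |
|----------------|----------|------------------|-----------------|
| initial dip    | negative | 1.75e-4          | max areal extent in 0-7 s |
| overshoot      | positive | 3.5e-4           | max areal extent in 0-7 s |
| condensed dip  | negative | 2.5e-4           | fixed 0.5-1.0 s frame |

Sparse-protocol scoring searches the first 7 s of acquisition for the
frame with the largest suprathreshold pixel count inside the analysis
ROI (ties go to the earliest frame, for reproducibility); the condensed
protocol always scores the 0.5–1.0 s frame. A series with no
suprathreshold pixel anywhere returns `NA` with a warning rather than a
silent index; quantification then reads amplitudes at the frame nearest
the expected phase peak.

**Areal extent** counts ROI pixels with polarity-signed dR/R at or above
threshold; area is reported in both px and mm^2
(`area_mm2 = area_px * mm_per_pixel^2`, default calibration 7 mm / field
width). **Peak amplitude** is the polarity-extremal pixel within the
intersection of the extent mask and the slit mask; if that intersection
is empty (an abolished representation) the extremum over the slit mask
alone is returned with a `fallback` flag, so 24 h comparisons stay
numerically defined and an abolished WFR yields a near-noise amplitude
instead of a missing value. Condensed amplitudes are read at the
baseline peak pixel in both sessions so the pair is compared at the
same cortical location. Exact ties at the extremum resolve to the
lowest (row, col) in raster order.

ROIs are supplied as masks (PNG, nonzero in-mask) or generated around
the slit; in the original workflow they are drawn from surface
vasculature landmarks, which cannot be automated faithfully, so the ROI
is an explicit input here.

## TTC volumetry

`segment_slice()` separates tissue from background with an Otsu cut on
luminance, then classifies infarct (unstained) pixels as tissue whose
red-channel dominance `R - (G + B) / 2` falls below a margin (default
0.1) *and* whose lightness exceeds an Otsu cut within the tissue;
healthy TTC-stained tissue is strongly red-dominant. The original
analysis used manual ImageJ thresholding with no stated values, so this
two-criterion rule is the package's own, with the margin configurable.
An exclusion mask (surgical-site damage) is subtracted from the
infarct. The midline is taken from the slice annotation when present,
otherwise from the tissue centroid column.

`infarct_volume()` multiplies per-slice infarct areas by slice
thickness (2 mm) and sums; edema correction multiplies the raw volume
by the contralateral/ipsilateral hemispheric volume ratio. The ratio
convention is one reading of "normalizing to the contralateral
hemisphere"; the Swanson-style indirect formula
`V_contra - (V_ipsi - V_raw)` is available via `method = "indirect"`.
Equal hemispheres leave the volume unchanged; appending empty slices
never changes infarct volume but does change hemisphere volumes (both
properties are tested).

`slit_regression()` is OLS of corrected volume on dura-slit area
(mm^3 per mm^2), fitted per group, with slope CI, R^2 and the two-sided
slope p-value; the returned object supports `coef`, `predict`,
`summary`, `residuals` and `plot`.

## Statistics

The study's primary model is a mixed-design repeated-measures ANOVA
(`rm_anova()`): group (5 levels, between subjects) x time (baseline vs
24 h, within subjects), fitted by `stats::aov` with an `Error(animal)`
stratum. With two within-subject levels sphericity holds automatically
(noted in the result). Post hoc per-group paired contrasts
(`posthoc_time_contrasts()`) report both Bonferroni (`min(1, p k)`) and
Sidak (`1 - (1 - p)^k`) corrections; since the source protocol says
only "Bonferroni/Sidak", both are computed and the default decision
column uses Sidak, the less conservative. `baseline_equality_check()`
is the one-way ANOVA across the five groups at baseline with pairwise
Bonferroni contrasts. `infarct_group_tests()` uses Welch t-tests by
default (a robust choice where the protocol does not specify pooled
variances; `var_equal = TRUE` restores the pooled test) plus a one-way
ANOVA with eta^2. Peak amplitudes are analysed as signed values with
the phase polarity conventions above. Animals missing a timepoint are
excluded listwise with a warning and logged counts.

## The synthetic-data generator

The generator emulates the *statistical structure* of the measurements,
not the physiology:

* **Baseline reflectance**: a smooth low-frequency field around 10^4
  counts (16-bit scale) with static dark vessel streaks. Streaks are
  static within an animal, so they cancel in ratio images — as the
  white/black vessel artifacts do in real ratio frames.
* **Temporal kernel**: raised-cosine lobes. Sparse defaults: dip
  -7e-4 peaking 2.5 s post-onset (half-width 2 s), overshoot +1e-3 at
  5 s (2.5 s), undershoot -4e-4 at 9 s (2.5 s) — phase order and the
  0–7 s analysis window respected. Condensed trials carry a single
  growing dip (default -1.4e-3, peak 1.5 s, half-width 1.5 s) so the
  scored 0.5–1.0 s frame is suprathreshold at baseline; its magnitude
  exceeds the sparse dip because no overshoot truncates it.
* **Spatial profile**: 2-D Gaussian, default sigma 0.55 mm (a
  single-whisker representation a couple of mm^2 in extent at the dip
  threshold).
* **Noise**: multiplicative Gaussian per pixel per 100 ms frame,
  default s.d. 3e-3 of the local baseline — after 500 ms summation,
  4-trial averaging and smoothing this leaves ~6e-5 dR/R of correlated
  noise, a realistic fraction of the 1.75e-4 threshold.
* **Drug block**: the 24 h signal is multiplied by `block_gain` inside
  a diffusion disc that covers the suprathreshold blob (the drug
  spreads beyond the slit footprint; the slit mask is always contained
  in the disc). Groups 3–4 use gain 0; structurally protected group-5
  animals use gain 0.5 — they escape infarct but, having received no
  stimulation, recover only partially; unprotected group-5 animals use
  gain 0 and draw a large infarct (~N(70, 10) mm^3) extending beyond
  the barrel field. The protected fraction defaults to 0.5
  ("almost binomial" spread).
* **Infarct rule**: groups 3–4 volumes follow
  `5 + 3 x slit + N(0, 0.5)` mm^3, with per-animal slit areas uniform
  on 0.5–2.5 mm^2 (group 3) and 1–6 mm^2 (group 4) — the two groups'
  slit ranges deliberately differ in scale. Slit size is expressed in
  mm^2 of dura opening.
* **TTC slices**: eight 2 mm coronal slices at 0.1 mm/px; hemispheres
  are half-ellipses, the ipsilateral one dilated so its area is
  `edema_factor` (default 1.08) times the contralateral, and the drawn
  infarct pixel area inflated by the same factor — so the
  edema-corrected pipeline volume recovers the intended edema-free
  volume. Occluded animals carry a small excluded surgical-site lesion.
  The drawn per-slice pixel counts are retained as ground truth.

What the generator does **not** emulate: collateral blood-flow
dynamics, LFP synchronization, anesthesia effects, vessel jitter
between sessions, camera shot-noise statistics, nonrigid misalignment
between baseline and 24 h sessions, or the irregular outline of real
brain slices. Passing tests therefore demonstrate that the analysis
chain is correct and calibrated on data with this structure — not that
it is robust to every artifact of real recordings.

## Simulation sizes and numerical choices

Simulated studies default to a 64 px field (the calibration stays
7 mm across the field, so mm-scale quantities are unchanged) and 4
trials per block; single-stack examples use 128 px. These sizes were
chosen so a full 40-animal study — 160 image blocks plus 320 TTC
slices — generates and quantifies in well under a minute while leaving
every effect of interest many standard errors from zero. The nominal
acquisition block sizes (64 sparse / 40 condensed trials) remain in the
protocol metadata and can be requested explicitly. Raw stacks are kept
as float count arrays in memory and quantized to 16-bit only on TIFF
export; sub-count quantization would otherwise dominate the 1e-6-level
recovery checks. `make_study()` is lazy: it fixes all ground truth and
per-animal seeds up front and materializes image blocks one animal at a
time (`simulate_animal()`), so a full study never holds gigabytes of
frames. Inter-trial intervals are metadata only; no dead-time frames
are generated because the analysis never uses them.

A sparse trial is nominally quoted as 15 s although its components sum
to 16 s; the generator uses the component durations (160 frames) and
records the nominal figure in the stack metadata.

## Known limitations

* ROI placement is synthetic (disc around the slit); real analyses
  draw ROIs from vasculature landmarks, and results are sensitive to
  that choice.
* The white-pixel rule assumes a dark background and red-dominant
  viable tissue; slides photographed on light backgrounds need the
  margin re-tuned.
* Areal-extent estimates at 64 px carry a positive noise bias (the
  max-over-frames selection); group contrasts are unaffected but
  absolute retention percentages slightly exceed 100% in control
  groups.
* `rm_anova()` targets the balanced two-timepoint design; unbalanced
  data are handled by listwise deletion, not by mixed models.
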