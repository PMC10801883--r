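---
title: "Methods: gaze morphing and fixation-pattern statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze morphing and fixation-pattern statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazemorph)
```

## The analysis problem

When a primate free-views a face it concentrates fixations on the eyes, nose
and mouth — the classic T-shaped pattern. Comparing such gaze patterns across
many different face photographs is awkward because every face has its own
geometry. `gazemorph` implements the standard solution: annotate each face
with 26 corresponding landmarks, average the landmark coordinates into a
*mean shape*, triangulate the mean shape, and warp every trial's gaze
positions into the mean-face frame with per-triangle affine maps. Dwell-time
statistics (e.g., time on each eye), heatmap comparisons and permutation
inference are then computed in that common frame.

The package targets experiments with trial structure like: 1 s of central
fixation, then a 28° × 21° image shown for 10 s of free viewing, gaze sampled
at 1,000 Hz. A unilateral-inactivation design is built in: injection
conditions carry a site (face patch or control region), hemisphere and volume
(5 or 10 µL), and the headline statistic is the extra time spent on the eye
*ipsilateral* to the injected hemisphere, normalized by the animal's baseline
left/right bias.

All geometry is in screen-centered degrees of visual angle (dva), x
rightward, y upward, with the image center at the origin; time is integer
milliseconds with 0 at image onset. Pixels appear only inside heatmaps.

## Trial inclusion and blink handling

A trial is kept when its cumulative on-image viewing time strictly exceeds
7 s (`filter_trials()`). Interruptions — gaze leaving the image or tracker
dropout — shorter than 500 ms are *bridged* (`bridge_gaps()`): they count as
continuous viewing, which tolerates natural blinks. Bridged samples are only
annotated; missing gaze is never interpolated, because fabricated positions
would bias heatmaps. Only interior gaps (flanked by on-image viewing) are
bridged; leading or trailing off-image time never counts as viewing. Whether
bridged time should count toward the 7-s criterion is a genuinely open
reading; this package counts it, which is the permissive reading of
"breaks ... were ignored".

## Saccade detection and the main sequence

Speed is the Euclidean norm of the central-difference derivative of position
after a 5-ms moving average (`velocity_profile()`); the estimator is a
package choice, as mild smoothing is standard at 1 kHz. Thresholds are
estimated per trial from the pre-stimulus fixation window: with `m` and `s`
the median and SD of fixation speed, a saccade candidate is a maximal run of
samples with speed above `m + 6 s`, extended on both sides to the nearest
samples below `m + 2 s` (`detect_saccades()`). Overlapping or near-adjacent
(≤ 10 ms) extensions merge and events shorter than 8 ms are discarded —
microsaccade-scale guards chosen as defaults, both configurable. If the
fixation window is degenerate (zero SD, e.g., a constant synthetic trace)
detection falls back to absolute floor thresholds with a warning. Events
containing data gaps are flagged and excluded from main-sequence fitting,
since their amplitude and peak velocity are unreliable.

The main sequence is fit through the origin, `PV = βA`, with the closed-form
least-squares slope `β = Σ(A·PV) / Σ(A²)` (`fit_main_sequence()`). R² is
computed about the mean of PV, not about zero: the zero-reference convention
inflates R² for through-origin models, and the conservative choice matches
the magnitude such analyses usually report. Group differences in β are
tested by permuting saccades between groups (`compare_main_sequences()`).

## Heatmaps

`build_fixation_heatmap()` removes samples inside detected saccades larger
than 1 dva, accumulates the remaining on-image samples one count per 1-ms
sample (so mass ≈ dwell time in ms), and smooths with an isotropic Gaussian
of SD 0.25 dva (unit-sum kernel, zero-padded borders; mass is conserved for
interior sources). The display resolution defaults to 20 px/deg, a package
choice. `resample_for_analysis()` then produces the analysis recipe:
mass-preserving down-sampling to 5 px/deg — exactly 140 × 105 pixels for the
standard image — followed by a Gaussian of SD 2.5 px. Heatmap comparison
uses the plain Euclidean distance over flattened grids.

Averaging uses raw dwell mass by default; `normalize_heatmap()` provides the
unit-mass alternative. The pipeline normalizes per-trial heatmaps before
pattern-change analysis, because with raw mass the Euclidean distance is
dominated by per-trial viewing-time differences rather than pattern.

## Morphing

The mean shape is the pointwise arithmetic mean of the corresponding
landmarks (`compute_mean_shape()`). The Delaunay triangulation is computed
once, on the mean shape, and its vertex-index topology is transferred to
every face (`triangulate()`, via deldir): per-face triangulations could
disagree in topology, and correspondence of triangles is what the morph
requires. Each triangle's affine map solves the six-unknown homogeneous
system sending the three source vertices exactly onto the three destination
vertices (`triangle_affine()`); a point is assigned to the containing
source triangle — ties on shared edges go deterministically to the lowest
triangle index — and mapped with that triangle's transform
(`warp_points()`). Points outside the source convex hull have no defined
map; they are flagged `out_of_mesh` and returned unwarped, never
extrapolated. Warping preserves timestamps, so in-mesh dwell time is
conserved (`warp_trial_gaze()`).

Heatmaps in the mean-face frame are built by *warp-then-bin* (warp the
samples, then accumulate), not by warping binned heatmaps, which would
require Jacobian corrections to conserve mass. On faces whose transferred
triangles overlap slightly (strong shape differences), the lowest-index rule
keeps the map deterministic; warps remain exact at all 26 landmarks
regardless.

## ROI statistics and inference

Eye ROIs default to squares centered on the mean-shape eye-center landmarks
with side 1.6 × the inner-to-outer eye-corner distance — a "rectangular
area around each eye" needs a concrete size, and this scale
covers the eye region without overlapping the nose line. Dwell time sums one
nominal sampling period per retained in-mesh sample inside the closed
rectangle (`roi_dwell_time()`), consistent with heatmap mass; attributing
the full gap to the last pre-saccade sample instead would leak saccade
durations into whichever ROI a saccade happened to leave from.

"Ipsilateral eye" is observer-referenced: a right-hemisphere injection makes
the observer-right eye ipsilateral. Injection-session biases are normalized
by subtracting the mean observer-referenced baseline bias from baseline
sessions dated within ±31 days (`baseline_normalize()`), then re-signed to
ipsi-minus-contra.

Permutation tests are two-sided with the add-one rule
`p = (1 + #{|null| ≥ |obs|}) / (1 + n)`, which cannot return 0; when the
number of distinct reassignments is small the null is enumerated
exhaustively and the exact fraction is reported instead. The two-sample test
pools and re-splits trials (the exchangeability unit); the one-sample test
flips signs of per-trial differences. Confidence intervals are nonparametric
bootstrap percentiles over trials. Families of looking-time comparisons are
corrected with Benjamini–Hochberg (`bh_adjust()`, backed by
`stats::p.adjust`); note that BH re-adjustment is only a no-op on tied
families such as the reference case — the procedure is not idempotent in
general.

The pattern change index for trial *i* is
`(d(hᵢ, H̿) − d(hᵢ, h̄)) / d(hᵢ, H̿)`, where `h̄` averages the same-stimulus
trials of the trial's injection condition and `H̿` additionally pools the
baseline trials of that stimulus. It is 1 when the trial sits exactly on its
condition mean away from the grand mean, 0 when equidistant, negative when
farther from its condition mean, and undefined (NA, trial excluded) when the
trial equals the grand mean. The expected natural variation is estimated by
a random split-half of baseline trials per stimulus
(`baseline_pattern_variation()`).

## The synthetic-data generator

`generator_spec()` fixes the study conditions the generator emulates:
10-s trials at 1,000 Hz with a 1-s pre-stimulus fixation on a 28 × 21 dva
screen; 62-image-style sets with left-right mirrored twins (26-point
landmark template plus per-image jitter, SD 0.25 dva); Yarbus-T dwell
concentration with saliency weights (eyes 0.45, nose 0.25, mouth 0.20,
off-face 0.10); an observer-right-eye baseline bias defaulting to 1.1 s; an
injection-condition grid shaped like the published session counts, with
default ipsi effects of 1.4 s (face patch, 10 µL), 0.1 s (control, 10 µL)
and 0 (5 µL); main-sequence slope β = 30 dva/s per dva with 10%
multiplicative peak-velocity noise; log-normal fixation durations
(median 300 ms, σ_log 0.4); blink gaps of 100–400 ms at 0.15 Hz; and
0.02 dva white gaze noise. Fixation-duration shape and all noise levels are
generator conventions, not claims about real data.

Scanpaths alternate fixations and saccades. Targets are drawn from the
saliency weights with Gaussian scatter around ROI centers (SD = a quarter of
the eye-ROI side); repeated draws of the same ROI extend the current
fixation rather than emitting a zero-length saccade, so every ground-truth
saccade is a genuine inter-ROI movement of at least 2 dva — small enough
movements would sit below any velocity criterion and make exact event-count
recovery ill-posed. Saccades follow a raised-cosine speed profile scaled so
the peak equals `βA` times the noise factor (duration `2A/PV`), integrated
to position; a saccade that cannot finish before the 10-s cutoff is replaced
by holding the current fixation.

The seconds-scale bias/effect parameters are calibrated analytically so that
the *measured* ipsi-minus-contra dwell difference is unbiased: the eye-weight
tilt is `Δw = target · ΣW / (q · T_fix)`, with `q` the probability that a
scattered fixation lands inside its eye ROI (per-axis Gaussian capture,
squared) and `T_fix` the expected per-trial fixation time after discounting
saccade time, merge probability and blink time. Cross-contamination between
the two eye ROIs from nose/mouth fixations is left/right symmetric and
cancels in the difference.

Ground truth (per-ms ROI attribution, saccade events, true β) is recorded
exactly as rendered, so generator-truth tests are exact by construction.
Everything derives from one experiment seed through fixed integer mixing —
no time-based seeding — so a seed reproduces an experiment byte for byte.

## What passing tests do and do not show

The generator produces cleaner data than a real rig: stationary noise, no
drift or calibration error, no smooth pursuit, no microsaccades, fixations
exactly at rest. Consequently the main-sequence R² on synthetic data
(≈ 0.95) is far above the 0.56–0.72 range typical of real recordings, and
saccade-count recovery near 100% should not be read as a claim about real
traces. Effect-recovery tests validate the *estimator chain* (detection →
morph → ROI dwell → normalization → inference), not tracker physics.

The generator implements the inactivation effect purely as an eye-dwell
redistribution. That is enough to power the looking-time statistics at the
published magnitudes, but it barely moves the pattern change index at
desk-scale trial counts: per-trial heatmap variability (a 10-s scanpath is
~25 sparse blobs) sets a variance floor that a ±1.4 s eye swap does not
clear, so pipeline-level injection indices sit near the baseline band. The
index machinery itself is validated against hand oracles and a
controlled-shift simulation in the unit tests.

## Problem sizes and numerical choices

Test and acceptance runs use reduced but representative sizes chosen as
package defaults: 2–4 unique images (each with a mirror), 20–25 trials per
session, 100-trial injection conditions for effect recovery, 200 replicate
null experiments (20 vs 20 trials, 400 resamples) for calibration, and
10,000-resample tests in the full pipeline configuration. Barycentric
containment uses a 1e-9 tolerance with lowest-index tie-breaks; affine
solves reject triangles with |det| < 1e-12; permutation counts switch to
exhaustive enumeration below 20,000 splits (4,096 sign patterns); heatmap
kernels truncate at 4 SD. The >7-s rule is a strict inequality. Degenerate
inputs (all-missing traces, zero-area triangles, empty ROIs, zero-mass
heatmaps, p-values outside [0, 1]) raise errors naming the offending object
rather than propagating NaN.
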