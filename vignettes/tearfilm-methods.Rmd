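---
title: "Methods: video-based TFBUT estimation and dry eye diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: video-based TFBUT estimation and dry eye diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and the diagnostic rule

Tear-film breakup time (TFBUT) is the number of seconds between an eye
opening after a blink and the first appearance of a dry spot on the cornea.
Under fluorescein staining and ~488 nm blue light the tear film fluoresces
green; where it ruptures, the dye layer thins and the rupture appears as a
black spot. Clinically the examiner times the first spot after each of
three blinks and averages the three measurements.

`tearfilm` reproduces this measurement from video:

1. **preprocess** -- slice the video onto a 200-ms grid, drop unusable
   frames (defocus, blink closure, occluders such as eyelashes), detect the
   corneal disc, and standardize each frame to a 384 x 384 corneal crop;
2. **classify** -- decide per frame whether at least one dark breakup spot
   is present, with a confidence in [0, 1];
3. **tfbut** -- segment the label stream at blinks, time the first
   persistent positive frame per segment, and average the first three
   uncensored segments;
4. **diagnose** -- apply the revised Asia Dry Eye Society (ADES) criteria:
   dry eye disease (DED) iff TFBUT <= 5 s *and* OSDI symptom score > 13.
   The boundaries are exact: a TFBUT of exactly 5 s is short, an OSDI of
   exactly 13 is not symptomatic;
5. **evaluate** -- frame-level accuracy / F1 / ROC-AUC and case-level
   sensitivity / specificity / PPV / NPV / AUC with 95% intervals, plus the
   Spearman correlation between estimated and reference TFBUT.

Because the clinical videos behind the original study are not deposited
anywhere, the package ships a **simulator** that generates blue-light
fluorescein videos with complete ground truth; every claim the test suite
makes is made against that ground truth.

## The simulator

A scene is a bright corneal disc (radius `corneal_radius_frac` x the short
image side, default 0.35 x 720 = 252 px) with a mild radial vignette and a
~2 px smooth rim, on a dark background. Videos default to 720 x 1280 at
30 frames/s (the supported device range is 720 x 1280 to 1080 x 1920 at 30
or 60 fps) and 56.1 s, the mean clinical video length; test fixtures use
much shorter, explicitly-sized videos.

* **Blinks.** `n_blinks >= 3` full closures (a valid measurement video must
  contain at least three blinks), evenly spaced with seeded jitter, or
  placed exactly via `segment_lengths_s`. During a closure the disc is
  absent. Partial lid closure is not modeled: a frame is either fully open
  or fully closed, which gives the timing logic an unambiguous eye-opening
  signal.
* **Breakup spots.** Each measurement segment may break up at a configured
  time after its opening. A spot is a circular darkening (fractional depth
  `spot_depth`, default 0.6) whose radius grows linearly at
  `spot_growth_rate` px/s from an initial `spot_min_radius` (default 7 px).
  The nonzero initial radius makes "positive at and after the breakup
  time" literally true at frame resolution: a rupture appears as a finite
  crack, not a point. One spot per segment by default
  (`spots_per_segment`).
* **Noise.** Additive Gaussian intensity noise (sd 0.05), generated inside
  the C++ render kernel by the polar method from R's uniform stream:
  bit-reproducible under a seed at a fraction of the cost of R's inversion
  sampler at ~1 Mpx per frame.
* **Artifacts.** With probability `artifact_rate` (default 0.03) per
  open-eye frame: either a defocused capture (emulated by down/up-sampling
  the recorded frame by `artifact_blur_factor`, default 12 -- applied after
  noise, as defocus and compression smear the recorded frame) or an
  eyelash occluder (an opaque dark stroke crossing the corneal rim).
* **Determinism.** Every frame draws from its own RNG substream derived
  from the seed and frame index, so a frame rendered alone is bit-identical
  to the same frame inside a full render, and rendering only the frames on
  the 0.2-s slicing grid is exactly equivalent to rendering everything and
  slicing afterwards.

Frames are stored as the fluorescein (green) channel matrix; the full RGB
rendering (`render_frame(..., channels = "rgb")`, fixed channel gains) is
materialized on demand. Every analysis step consumes the green channel, so
the two representations give identical results.

What the simulator does **not** emulate: tear-film interference color
patterns, partial blinks, camera motion, specular light reflexes, uneven
fluorescein instillation, iris texture, or breakup morphologies other than
circular spots (streaks, amoeboid pools). Passing tests therefore
demonstrate that the measurement logic is correct when its imaging
assumptions hold; they do not certify performance on clinical video.

## Preprocessing choices

* **Slicing** keeps tick 0 and selects the source frame nearest each
  0.2-s tick; at 30 fps every 6th and at 60 fps every 12th frame. The
  published frame count for the clinical dataset (22,172 frames from
  4,434 s) does not match any single whole-video slicing convention
  exactly (4,434 / 0.2 = 22,170), so the convention here is documented as
  this package's own, not asserted as the original one.
* **Quality rules**, in order: `no_cornea` when the bright-pixel fraction
  of a 4x-downsample falls below `tau_area = 0.04` (an open disc covers
  ~22% of the frame; a blink ~0%); `no_focus` when the variance of a
  Laplacian response on the downsample falls below `tau_focus = 2e-3`
  (clean frames score ~0.05 with noise and ~6e-3 noiseless; defocused
  frames ~6e-4); `noise` when more than `tau_occ = 2%` of the limbal ring
  (0.80-0.93 of the disc radius) is dark -- an eyelash stroke must cross
  the rim, while breakup spots live well inside the disc and at the
  simulator's growth rates never reach it. The disc-absent check runs
  first so that a flat eyelid frame is always `no_cornea`, whatever its
  sharpness. Thresholds were calibrated once on simulator fixtures so that
  100% of clean renders (noisy or noiseless) pass.
* **Corneal ROI**: the largest bright connected component on the
  4x-downsampled threshold mask (`EBImage::bwlabel`), refined at full
  resolution by the row/column extents of bright runs (>= 3 px, which
  discards isolated supra-threshold noise pixels). On simulated scenes the
  recovered center is within ~1 px and the radius within ~1% of truth.
  The enclosing-circle-of-bbox shortcut is exact for a circular disc; it
  would bias the radius for strongly elliptical regions.
* **Standardization** crops the ROI square plus a 10% margin (clipped at
  the image border) and resizes to 384 x 384 with bilinear interpolation
  (half-pixel-aligned, so a same-size crop is the identity and
  standardizing an already-standardized frame is exact). In standardized
  coordinates the disc is centered with radius 384 / 2.2 = 174.5 px.
* **Coordinates** are R conventions throughout: 1-based, `y` = row,
  `x` = column, pixel centers at integer indices.
* Quality-failed frames keep their row and timestamp: a gap in the
  timeline, never a time shift.

## Frame classification

The default classifier is the annotation criterion made executable. Spots
are connected components of pixels darker than `depth_frac = 0.55` x the
local fluorescein background (the median inside the corneal mask eroded by
8 px), of at least `min_area = 20` px. At the simulator's contrast
(`spot_depth = 0.6`, so spot pixels sit at 0.4 x background) this threshold
is ~5 noise standard deviations below the background, which makes false
dark pixels rare and false components (>= 20 connected) essentially
impossible; the minimum-area rule also keeps isolated noise pixels out.
Confidence is `1 - exp(-k * sum(area x mean_depth))`: zero evidence gives
exactly 0, more or deeper spot area never lowers it, and `k = 0.06` is
anchored so one minimum-area spot at full depth scores ~0.7. The label is
positive iff confidence >= `decision_threshold` (default 0.5; the ROC
sweep in `evaluate` explores all other operating points).

The **trainable surrogate** is a ridge-regularized logistic regression
(selected on validation deviance over an extended lambda path) on
intensity quantiles of the corneal interior of the normalized frame.
Pooled-pixel grids were evaluated as features and rejected: in
leave-one-video-out checks they memorize per-video spot positions (held-out
accuracy dropped to 0.80-0.95), while the quantile descriptor -- which
collapses at the low end as soon as any dark region exists, wherever it is
-- held 1.00. The development set splits 8:2 into train and validation,
grouped by source video so no video straddles the split; the
flip/transpose/normalize augmentation recipe is applied to training frames
only. Training fixtures disable artifacts: artifact frames are
quality-excluded upstream and would only shrink the usable set.

**Attribution maps** are model-agnostic occlusion: slide a 48-px patch
(stride 24), flatten it to its own median, and record the confidence drop.
The drop is credited to the pixels the occlusion actually erased (those
darker than the patch median), combined across patches by maximum. Filling
with the patch's own median rather than a global constant keeps the
occluded frame inside the training distribution; with a global fill the
largest "drops" appeared at the dark frame corners. For the rule-based
classifier the map is analytic: the per-pixel fractional depth inside
detected spots. In both cases values are confidence units in [0, 1] and
are deliberately not re-normalized, so a negative frame's map stays near
zero instead of amplifying noise.

## Timing and censoring

A blink is a maximal run of `no_cornea` frames; each measurement segment
starts at the first passing frame after a run and ends at the next blink
onset (or video end). The pre-first-blink interval is not a measurement
segment -- clinically, timing starts at a blink opening -- and the
simulator accordingly never places a rupture there. The segment's breakup
time is the timestamp of the first positive passing frame (persistence
`k_persist = 1` by default, taking "first dry spot" literally;
`k_persist > 1` hardens against classifier flicker at the price of a
detection delay). TFBUT is the mean of the first three uncensored
segments. If a segment ends before any positive frame it is censored at
its length: a lower bound. Censored values never enter the average; for
the 5-s decision a censored segment counts only as evidence *against* a
short TFBUT (a bound >= 5 s means "not short"; a bound < 5 s is simply
uninformative, and an eye with no observed rupture is classified non-DED).

On the 0.2-s grid both the opening and the onset snap to the next tick, so
a single segment's error lies in (-0.2, 0.2) s and the quantization bound
`max |error| <= 0.2 s` holds video-wide with oracle labels. The
parameter-recovery suite (50 videos, true TFBUT uniform on [1, 10] s) runs
its oracle arm with `artifact_rate = 0`: an artifact frame landing exactly
on the onset tick would push the first *usable* positive one tick later
and the bound would no longer be a theorem. The rendered-detector arm
keeps the default artifact rate and is scored by Spearman correlation.

## Evaluation statistics

* Proportions (accuracy, sensitivity, specificity, PPV, NPV) carry exact
  binomial (Clopper-Pearson) intervals via `stats::binom.test`; undefined
  ratios (zero margins) are flagged `NA`, never silently 0.
* F1 carries a seeded multinomial bootstrap over the table cells
  (equivalent to resampling items), 2000 replicates, percentile limits.
* AUC is the rank statistic (midrank ties = half credit); the ROC curve
  sweeps every observed threshold, and its trapezoid area equals the rank
  AUC to 1e-10 (verified against exhaustive pair counting at small n and
  against an independent library implementation). Its interval is a
  seeded stratified bootstrap.
* Spearman's r is the Pearson correlation of midranks with a Fisher-z
  interval, SE = 1 / sqrt(n - 3) -- a documented large-sample
  approximation.
* The case-level ROC uses the estimated TFBUT as the continuous score with
  the symptom criterion held fixed: eyes with OSDI <= 13 can never be
  called DED, so they score `-Inf`; otherwise the score is `-tfbut_s`.

The published study's clinical operating figures (frame accuracy 0.789,
frame AUC 0.877, case sensitivity 0.778 / specificity 0.857, Spearman
r = 0.791 against medical-record TFBUT) come from a private 79-patient
video dataset and are context, not reproduction targets: without those
videos no pipeline can re-derive them. What this package verifies instead
is (a) the arithmetic consistency of the published dataset bookkeeping,
(b) exact-to-tolerance agreement of every statistic with independent
oracles, including that the unique minimal 2 x 2 table consistent with all
four published case-level point estimates (tp = 14, fn = 4, fp = 2,
tn = 12) reproduces them simultaneously, and (c) full-pipeline parameter
recovery on synthetic ground truth.

## The synthetic cohort

`simulate_cohort()` builds a 40-eye cohort: half dry-eye (true TFBUT
uniform on [2, 4.4] s, symptomatic OSDI), the rest split among symptomatic
eyes with stable film (TFBUT on [5.7, 9] s), symptomatic eyes whose film
never ruptures (fully censored videos), and asymptomatic eyes with short
or long TFBUT. OSDI item responses are drawn per case and re-drawn until
the group's symptom criterion is met, then scored by the standard formula
(sum x 100 / (4 x items answered)). True TFBUT keeps >= 0.5 s away from
the 5-s boundary so that grid quantization (<= 0.2 s per segment) cannot
flip a diagnosis -- eyes within one measurement tick of the boundary are
clinically ambiguous by construction and are out of scope for a
correctness suite. The reference diagnosis applies the ADES rule to the
true values; the pipeline's diagnosis uses the estimated TFBUT, via either
oracle labels or the rendered dark-spot pathway.

## Problem sizes and determinism

The shipped suites use 16-s fixtures for single-video checks, 50 videos
for parameter recovery, ~500 frames over 10 videos for the surrogate, and
the 40-eye cohort end to end; rendering happens directly on the 0.2-s
analysis grid (identical to full-rate rendering plus slicing, see above).
All randomness -- scene geometry, noise, artifacts, splits, bootstraps --
derives from explicit integer seeds, and per-frame substreams keep results
independent of rendering order.

## Known limitations

* The simulator's visual realism is deliberately minimal (see above); the
  spot contrast and size are free parameters, not calibrated to clinical
  imagery, because the source study published no quantitative description
  of either.
* The quality thresholds are calibrated to the simulator's contrast; real
  video would need re-calibration on annotated frames.
* Video containers are not read directly: the interfaces accept a
  directory of frames with a manifest (any standard extractor produces
  one), and `write_video_frames()` emits the same layout plus a
  ground-truth JSON sidecar.
* Censored TFBUT handling (lower-bound semantics) is this package's
  policy; the original description does not state what its system reports
  when no breakup is observed.
* The 8:2 development split is grouped by video here; whether the original
  splits were frame- or video-level is ambiguous in the source, and
  frame-level splits of video data leak near-duplicate frames across the
  boundary.
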