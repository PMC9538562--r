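---
title: "Sweet-period discovery and vision/sEMG fusion: methods"
author: "sweetfuse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sweet-period discovery and vision/sEMG fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweetfuse)
```

## The problem

A myoelectric prosthetic hand decodes surface electromyography (sEMG) into
an intended grasp gesture. sEMG decoding alone plateaus well below the
reliability a daily-life prosthesis needs, but during a natural
reach-and-grasp the user's own first-person view carries complementary
evidence: before the hand occludes the object, an egocentric camera can see
*what* is about to be grasped and hence predict *how*. sweetfuse implements
the temporal analysis behind this idea:

1. For each video frame of a trial, a frame is **valid** when the target
   object is visible and detectable; the cohort-level **valid-frame
   proportion curve** describes when vision has anything to say.
2. The **vision sweet period** is the anchored time window `[0, e)` whose
   mean valid proportion is highest, subject to a minimum length — the early
   window in which vision-based classification is most dependable.
3. Within each modality's sweet period, a **plurality vote** over that
   modality's per-frame (or per-time-point) gesture decisions yields a label
   and a **confidence** (winning votes / votes cast).
4. **Max-confidence fusion** takes, per trial, the label of the more
   confident modality, with sEMG as the fallback.
5. A **leave-one-repetition-out** (LORO) harness scores sEMG-only,
   vision-only and integrated classification.

The package operates on *decision streams* — time-stamped classifier
outputs — never on video, images or raw sEMG. Everything upstream (object
detection, grasp classification networks, sEMG decoding) is outside its
scope; a calibrated synthetic generator stands in for those classifiers so
the pipeline is testable end to end.

## Timeline and cohort structure

A trial is 4,480 ms of 25 Hz video: 112 frames of 40 ms, frame *k* starting
at 40·*k* ms. Every interval in the package — windows, phases, sweet
periods — is half-open `[start, end)`; this convention is forced by the
frame arithmetic (the 0–320 ms window holds exactly 8 frames, 0–160 ms
exactly 4). The grasp process splits into reaching `[0, 1020)` ms, early
grasping `[1020, 1604)` ms and firm grasping `[1604, 4480)` ms.

The cohort design crosses 30 subjects with a taxonomy of 10 grasp gestures
acting on 18 objects (30 gesture-object pairs: the medium wrap has four
objects, the prismatic four-finger grasp two, the rest three) and 4
repetitions: 3,600 trials, 120 per subject. The taxonomy ships as a packaged
CSV so the generator and the scorer share one label universe.

## The synthetic generator

`generator_params()` / `generate_cohort()` emulate the statistical structure
of real classifier outputs.

**Frame validity.** The probability that a frame is valid follows a
continuous piecewise-linear curve: baseline 0.41 at 0 ms (the subject
fixates the object before moving, so it is often in view), peak 0.63 at
160 ms, a linear decline to the floor 0.08 by 1,020 ms (the reaching hand
progressively occludes the object), then constant below 10% through firm
grasping. A per-trial uniform ±120 ms jitter shifts the curve in time,
modelling subjects touching the object at different moments; phase
boundaries in the timeline are cohort averages. Given the (jittered) curve,
frame validities are drawn independently; an optional first-order
persistence knob exists but defaults off, because only marginal proportions
are identifiable from cohort-level curves anyway.

Because of the jitter, the *population* per-frame validity is the
jitter-average of the curve, which `expected_validity_curve()` computes by
quadrature; it is the oracle the recovery tests compare against and reduces
to `validity_probability()` at zero jitter. The defaults were calibrated
once, analytically, so that the mean valid proportion over `[0, 320)` is
approximately 53% (0.534 in population) and `[0, 320)` is the best anchored
window of at least 5 frames — the regime the pipeline is designed for.

**Vision predictions.** Among valid frames, the gesture prediction is
correct with probability 0.92 and the object prediction with 0.97
(independent draws; errors uniform over the other 9 gestures / 17 objects,
or per an optional confusion table). The real upstream classifier couples
object and gesture predictions, but no joint error statistics are
identifiable from per-source accuracy curves, so independence is the
deliberate default.

**sEMG decisions.** A per-point iid accuracy cannot reproduce the observed
sEMG regime: plurality voting over 7 iid decisions with accuracy *p* pushes
trial-level accuracy far above *p*, yet real sEMG classification sits near
85.5% at trial level *with* vote confidences typically above 75% — because
a classifier that errs within a trial errs consistently (same muscles, same
signal). The generator therefore draws one **dominant label** per trial
(correct with probability `emg_accuracy` = 0.855, else a uniform wrong
gesture) and repeats it at each 40 ms decision point with probability
`emg_consistency` = 0.93. The resulting vote confidence is ≈ 0.93 and the
trial-level sEMG accuracy ≈ 0.855. Setting `emg_consistency = 1` recovers
a deterministic per-trial decision; an iid stream is the special case
`emg_accuracy = 1` with the noise carried by `1 - emg_consistency`.

**Reproducibility.** Each trial's random stream is derived from the master
seed and the trial key (subject, taxonomy pair, repetition) through a fixed
integer map, so cohorts are identical across runs and generation orders,
and any single trial can be regenerated in isolation.

**What the generator does not emulate.** Temporal correlation of validity
(defaults off), object/gesture error coupling, per-subject or per-object
difficulty differences, and any drift of accuracy over the trial (the real
per-timepoint accuracy curves fluctuate in a 91–97% band; the synthetic
ones are flat at their configured levels). Consequently, passing tests show
the *pipeline* is correct and the *qualitative* fusion behaviour holds under
the study's regime — not that real-data accuracies are reproduced. In
particular, with iid frame errors the vision-only plurality accuracy
(≈ 99% on synthetic cohorts) exceeds the ≈ 92% a real, within-trial
correlated classifier attains; only the per-frame accuracy (0.92) is
matched, by design.

## Window search

`find_sweet_period()` scores every anchored window `[0, e)` — `e` a frame
boundary — by the mean of the valid-proportion curve over its frames and
returns the best window with at least `min_window_frames` frames, ties
broken toward the shorter window. The default minimum of 5 frames encodes
the reliability argument for rejecting 4-frame windows: with at most 4
votes and at least one error, plurality confidence is capped at
`max_vision_confidence_bound(8, 4, 1)` = 75%, exactly the level at which
sEMG (typically > 75% confident) takes over, so such a window adds little.
All candidate scores are retained in the returned object for audit.

Only anchored (start = 0) windows are searched: the sweet period must sit
as early as possible so classification finishes before the hand reaches the
object. The sEMG sweet period, 1,100–1,400 ms in the early grasping phase,
comes from prior myoelectric work and is a configuration constant here, not
a search result. Measured end-to-start, the two sweet periods are 780 ms
apart, enough to compute the vision vote before the sEMG window opens.

Curve points with empty denominators (e.g. object-accuracy points in the
firm-grasp region where almost no frame is valid) are carried as `NA` —
undefined, never imputed or zeroed — and the anchored-window search refuses
curves containing them rather than guessing.

## Fusion rules and tie-breaks

- Plurality ties inside a vote go to the lowest gesture ID: deterministic
  and seed-free. The convention is ours (no rule is identifiable from
  cohort-level accuracies); it is exposed in `plurality_vote()`'s contract.
- An empty vote (no valid frame in the window) is an *absent* decision with
  confidence 0, never a guess.
- Fusion picks vision only when present and **strictly** more confident;
  exact ties go to sEMG, the always-available default modality. This
  mirrors the design argument that sEMG should dominate whenever vision
  confidence sinks to the 75% bound.
- sEMG decisions are never absent by construction; a trial with no sEMG
  record in the window is malformed input and raises an error.

## Evaluation harness

`loro_folds()` makes one fold per repetition; fold *r* tests on every trial
with repetition *r* (900 trials at full scale). No networks are trained
here, but the train/test separation is preserved: by default the vision
sweet period is re-selected on each fold's *training* trials only
(`sweet_period_scope: train`), so the window choice never sees the test
fold. `vision_only` accuracy is reported among trials with a present vision
decision, with the all-trials variant (`vision_only_all`, absents counted
wrong) alongside, since either denominator is defensible. Pooled accuracy
is the trial-weighted aggregate over folds; each trial is tested exactly
once.

## Numerical and test design choices

- All window membership uses exact integer frame arithmetic (times are
  multiples of the frame period); no floating-point window edges.
- The jitter quadrature in `expected_validity_curve()` uses 481 uniform
  nodes over ±120 ms; the curve is piecewise linear, so the quadrature
  error is far below sampling noise at any tested cohort size.
- Parameter-recovery tests compare roughly 450 per-frame binomial
  proportions against their oracles simultaneously. A literal
  every-frame-within-3-SE rule would false-alarm on most seeds (expected
  number of chance 3-SE exceedances ≈ 1.2), so the suite asserts the
  calibrated simultaneous version: per curve, at least 99% of frames within
  3 SE and every frame within 4.5 SE (family-wise false-alarm ≈ 0.003).
- Scale: unit tests run on 1–5-subject cohorts (120–600 trials); the
  acceptance suite uses one full 3,600-trial cohort for recovery and ten
  independent full-scale cohorts for the fusion-ordering check.

## Known limitations

- The generator's flat accuracy curves and iid vision errors make
  vision-only voting optimistic (see above); comparisons against real
  printed accuracies are out of scope by design.
- The LORO harness has no training phase to cross-validate; it preserves
  the fold structure so the same code runs unchanged on exported real
  classifier outputs.
- The sweet-period search metric is the valid-frame proportion. Where a
  narrative instead ranks windows by "accuracy", the two can disagree; this
  package scores by valid proportion, which is what the anchored-window
  argument actually uses, and reports every candidate's score so any other
  ranking can be recomputed from the output.
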