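---
title: "Methods: tracking and statistics for Drosophila magnetosensitivity assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking and statistics for Drosophila magnetosensitivity assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`flymag` implements the computational backbone of behavioural screens that
test whether *Drosophila* responds to static magnetic fields: automated
video tracking of group negative-geotaxis (climbing) assays, the climbing
statistics built on the tracks, the T-maze binary-choice statistics, and an
effect-size/power framework that makes explicit how easily small,
pseudoreplicated designs produce false positives. A synthetic-data module
generates choice counts and rendered climbing videos with known ground
truth, so every stage of the pipeline can be validated without any raw
video.

## The video-tracking algorithm

Recordings show backlit tubes with flies as dark silhouettes on a bright
field (nominally 1,280 x 1,024 px at 10 frames per second). The pipeline
is:

1. **Contrast enhancement** (`preprocess_frames()`): gamma correction with
   exponent 0.45 on intensities normalised to [0, 1], then an unsharp mask
   with Gaussian radius 1.0 px and weight 0.93. Both values are the
   standard high-contrast preset for this kind of backlit footage.
2. **Two-pass background estimation** (`estimate_background()`): the
   per-pixel arithmetic mean of all frames, then a refined mean using only
   frames whose intensity does not fall short of the first-pass mean by
   more than 20% — frames in which a fly covered the pixel fail this test
   because the silhouette is far darker than the scene. Pixels that lost
   any frame (configurable via `min_reliable_fraction`) are filled from
   reliable neighbours by an iterated moving average over a 10-px window,
   and the result is smoothed with a 1-px Gaussian.
   A consequence of the per-pixel exclusion rule worth knowing: a pixel
   occluded in *every* frame can never be flagged, because the maximum of
   any sample always exceeds 80% of its own mean. The rule is designed for
   pixels that flies cross, not squat on; the group assay knocks all flies
   down repeatedly, so permanent occlusion does not arise in practice.
3. **Per-frame intensity scaling** (`scale_to_background()`): each frame is
   linearly mapped (`a * frame + b`) to match the background over
   calibration regions between the tubes that flies cannot reach. The fit
   regresses the frame on the (noise-free) background and inverts the
   coefficients, which avoids the attenuation bias that regressing on a
   noisy image would introduce. This step absorbs global illumination
   flicker; it requires some spatial structure in the calibration regions
   (a perfectly flat background makes the fit degenerate, and the function
   says so).
4. **Detection** (`detect_flies()`): difference `background - frame` (flies
   become bright), grayscale morphological opening with a disk of radius
   2 px, binarisation, connected components (4-connectivity), and geometry
   gates. Regions are kept only if the ellipse-equivalent major axis lies
   in [4, 20] px, the minor axis in [3, 20] px and the area in
   [8, 200] px^2; axes follow the regionprops convention (normalised second
   central moments with the 1/12 pixel-variance correction), under which a
   fly-sized ellipse with semi-axes 5 x 2.5 px measures about 10 x 5 px
   with area ~39 px^2. The minimum-area gate also serves as the removal of
   small spurious components.
5. **Thresholding**: Otsu's method on the opened difference image, with a
   floor of 8 grey levels so that a fly-free frame does not binarise its
   own noise; a fixed threshold can be configured instead. The original
   analysis only ever said "a suitable threshold", so this is the package's
   own choice, exposed in `segmentation_params()`.
6. **Assembly** (`track_stack()`): the background is estimated once per
   recording; detections are assigned to tubes by ROI, converted to height
   in cm above the calibrated tube base (20-cm tubes by default), and
   annotated with trial and within-trial time. Detections outside every ROI
   are kept but flagged, never silently dropped.

Validity filters (`apply_validity_filters()`) mirror assay practice: in the
group ("gravity") assay, any frame yielding more than 10 detections in a
tube is excluded as containing false positives; in the single-fly
("flyvac") assay a fly is discarded entirely if a vacuum pulse failed to
bring it to the bottom (post-pulse height above 1 cm, configurable — the
original cutoff is not quantified anywhere) or if it never moved in any of
its five trials.

## Climbing statistics

The binary climber criterion is reaching 15 cm within 15 s of knockdown
(inclusive). Group-mode tracking has no per-fly identity, so
`climber_proportion()` counts detections at or above the height line per
frame and takes the running maximum over frames within the time bound; the
"reaching" timecourse in `proportion_timecourse()` is the same running
maximum at every time point, which makes the curve non-decreasing and
exactly consistent with the scalar criterion at 15 s. Confidence bands use
the Wilson score interval on pooled counts. `mean_height_timecourse()`
averages detected heights per tube per frame (missing frames stay missing,
they are never imputed as zero), then reports mean and s.d. across
replicates.

Exposure tests:

* `test_exposure_ratio(method = "rm_anova")` — repeated-measures ANOVA of
  per-replicate climber ratios, trials as the repeated measure within
  replicate, Exposure tested against the between-replicate stratum. Which
  factor is "repeated" is an assumption (trials within replicate); the
  source analyses do not spell it out.
* `test_exposure_ratio(method = "binomial_glmm")` — binomial GLMM of
  above-line counts per frame,
  `cbind(n, N - n) ~ Exposure + (1|id) + (1|trial/frame)`, type-III Wald
  chi-square for Exposure.
* `test_exposure_height()` — LME of per-frame tube-average height,
  `Ycm ~ Exposure * condition + (1|id) + (1|trial/frame)`, type-III
  Satterthwaite F tests for Exposure, condition and their interaction.
  With a single trial the trial stratum degenerates and the model keeps
  only the frame term.

Per-frame fits at 10 fps x 30 s x 5 trials are statistically redundant;
`subsample_frames()` thins to every 5th frame by default (every 10th-30th
in the simulation studies below), and climber proportions are provably
invariant to any subsampling finer than the crossing resolution.

### Calibration, and a caveat about the count GLMM

Under null simulations from the synthetic generator (500 replicates,
10 tubes per group, five 30-s trials of 10 flies), the per-set
quasi-binomial GLM, the repeated-measures ANOVA and the height LME all
hold their nominal 5% type-I error (the package's acceptance suite
re-measures the GLM and the LME on every run). The binomial GLMM of
per-frame counts is a more delicate instrument: its calibration depends
strongly on how densely frames enter the fit. At dense frame grids its
rejection rate under the null is far above nominal (about 0.26 at 3-s
frame spacing with 15 tubes per group, and about 0.54 at 3-s spacing with
10 tubes per group), because a tube's count trajectory is a smooth,
strongly autocorrelated curve while the model allows only a constant tube
intercept plus frame effects shared across tubes, and a binomial family
has no overdispersion parameter to soak up the remainder. Thinned to 5-s
spacing (seven frames per 30-s trial, the setting used in the acceptance
suite) the residual dependence is weak enough that the test falls back
inside the nominal band. Simulating data from the model's own assumptions
recovers the nominal level at any density, confirming the implementation;
the sensitivity is a property of the model under realistic climbing
dynamics. Practical consequence: per-frame counts should be thinned
aggressively before a binomial GLMM (the subsampling interval is an
exposed parameter precisely for this), its p-values should not be
trusted at dense grids, and conclusions about exposure effects are better
rested on the height LME and the repeated-measures ANOVA, whose
calibration does not show this sensitivity.

## T-maze statistics

Each maze run tests a set of ~100 flies; the preference index is
`PI = 2 * P_M - 1` with `P_M` the proportion choosing the magnetic arm.
The statistically sound unit of replication is the set:
`glm_group_test()` models per-set counts on the group factor with
quasi-binomial dispersion by default (a beta-binomial likelihood via
glmmTMB is available; note that on data with no overdispersion its
dispersion parameter diverges and the fit is flagged). The deliberately
wrong analysis — every fly treated as an independent replicate — is
provided as `pseudoreplicated_test()` (per-fly Welch t-test on 0/1
choices, or a pooled two-proportion chi-square without continuity
correction), labelled "for comparison only".

`type1_error_study()` quantifies the damage: with within-set correlation
generated as beta-binomial (per-set choice probability drawn from a Beta
with mean `p` and variance `icc * p * (1-p)`, reducing exactly to binomial
at `icc = 0`), the per-fly test's type-I error rises steeply with the
intraclass correlation (empirically ~0.24 at icc = 0.02 and ~0.46 at
icc = 0.05 with 10 sets of 100 flies per group) while the per-set GLM
stays at the nominal level. Even a tiny social interaction between flies
sharing a maze is enough to manufacture "highly significant" effects.

Effect size and power use Cohen's h, `2*asin(sqrt(p2)) - 2*asin(sqrt(p1))`,
with the standard two-sample arcsine normal approximation:
`power = Phi(lambda - z) + Phi(-lambda - z)`,
`lambda = |h| * sqrt(n1*n2/(n1+n2))`. At `h = 0` the power equals alpha
exactly. For the largest group-assay effect ever reported (44.5% vs 58.5%)
with 10 and 12 sets per group, the power is ~10% — an experiment that
would miss a true effect of that size nine times out of ten.
`sample_size_for_power()` inverts the formula by integer search so the
returned n is minimal. The analytic formula is validated against
Monte-Carlo simulation of the arcsine z-test; agreement to +/-0.01
requires group sizes in the hundreds, because at n ~ 10 the discreteness
of binomial counts moves the exact size of the test by one to three
percentage points. The three validation settings in the acceptance suite
use group sizes 120-250 for that reason.

## The synthetic-data generators

**Choice counts** (`simulate_tmaze_experiment()`): beta-binomial with a
marginal choice probability and an intraclass correlation, as above. The
generator is the null and alternative world for all T-maze statistics.

**Climbing trajectories** (`simulate_climb_trajectories()`): each fly gets
a base climbing speed drawn once from `Normal(speed_mean * effect,
speed_sd)` (clipped at zero); each frame it pauses with probability
`pause_prob` or advances by a per-step speed drawn around its base. All
flies reset to height 0 at every trial start and heights are clipped to
the tube length. The per-fly component is what produces a graded,
unimodal spread of distances climbed — observed assays show no clean
bimodal climber/non-climber split, and a purely per-step model would
average out over 150 frames into an all-or-none proportion. Defaults
(speed 1.3 +/- 0.5 cm/s, 20% pause, 10 flies, five 30-s trials at 10 fps,
20-cm tube) put the 15-cm/15-s climber fraction near 55%, a typical value
for healthy flies under blue light, and leave room for both slower and
faster groups. No published speed distribution exists to match, so these
are the package's own calibration, fixed once.

**Video rendering** (`render_video()`): flies are filled ellipses
(semi-axes 5 x 2.5 px, major axis vertical) at the true positions, over a
background with a smooth illumination gradient (+/-12 grey levels);
each frame gets a multiplicative gain flicker (s.d. 1%) and Gaussian
sensor noise, then 8-bit quantisation. The gradient and flicker are not
decoration: the per-frame linear intensity matching step is only
identifiable if the calibration regions contain spatial structure, and
only useful if frames actually vary in gain — a perfectly flat, constant
video would make that stage degenerate, which the synthetic world would
otherwise hide. What the renderer does *not* emulate: reflections of
flies on tube walls, occlusion by condensation, lens distortion,
fly-on-fly occlusion geometry beyond simple overlap, and photorealistic
texture. Tracking metrics on synthetic video are therefore an upper bound
on real-data performance; the package's tests demonstrate correctness of
the algorithm, not field performance of any particular rig.

## Blinding and reproducibility

`blind_labels()` replaces treatment labels by opaque random codes; the
code-to-label key is written to a separate JSON file protected by a salted
hash (`write_blinding_key()`), and `unblind_labels()` refuses a tampered
key. Because group labels are opaque to every statistic, blinded and
unblinded analyses of the same data return identical test results — this
is asserted in the test suite. `run_pipeline()` executes
simulate/render/track/filter/analyse per mode, writes CSV tables, a
summary JSON embedding the seed and a hash of the analysis-relevant
configuration, and a JSON-lines log of every parameter including
defaults; reruns with the same configuration and seed are byte-identical.
All randomness flows from explicit seeds; no function touches the global
RNG state without restoring it.

## Numerical choices and problem sizes

* Morphology uses an exact digital disc (offsets with
  `dx^2 + dy^2 <= r^2`) with replicated borders; connected components are
  4-connected.
* Wilson intervals are used for all proportion bands.
* The Otsu threshold floor is 8 grey levels; opening radius 2 px;
  both configurable.
* Simulation studies in the test suite use: 500 null replicates for
  calibration (10 tubes per group; LME frames thinned to 2.5-s spacing,
  GLMM counts to 5-s spacing), 500 replicates per intraclass-correlation
  point for the pseudoreplication study, 200 replicates at 15 tubes per
  group for the 30% speed-reduction power check, and 1e5 Monte-Carlo
  draws for the power-formula validation. The tracking benchmark uses a
  1,000-frame, 10-fly, noise s.d. 4 rendering on a 180 x 240 px frame —
  geometrically scaled down from full resolution but with fly-sized blobs
  at the native scale, so all detection gates operate on realistic
  geometry.

## Known limitations

* No per-fly identity in group mode (by design — positions are averaged);
  no multi-object tracking or Kalman filtering.
* The count GLMM's anticonservatism at dense frame grids, above.
* The background model assumes flies move; a fly parked on the same pixels
  for an entire recording becomes part of the background.
* Synthetic video omits reflections and other artefacts of real rigs, so
  real recordings may need a tuned threshold or opening radius.
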