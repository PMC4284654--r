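---
title: "Decoding working-memory dynamics and inducing the plasticity curve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding working-memory dynamics and inducing the plasticity curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

The non-monotonic plasticity hypothesis (NMPH) holds that the fate of a
memory depends non-monotonically on how strongly it is activated: moderate
activation — the regime of close competition with another memory — weakens
it, while strong activation strengthens it. `pcitr` implements a complete
analysis pipeline for testing this idea with a retro-cue working-memory
paradigm: participants hold a scene and a face in mind, a switch cue
occasionally redirects attention from the scene to the face, multivoxel
pattern analysis (MVPA) of ventral-temporal fMRI data tracks the
competitive balance between the two representations ("scene − face"
classifier evidence), and a surprise recognition test afterwards measures
what happened to the scene memory. The pipeline estimates the *plasticity
curve* — the function relating evidence during the two learning windows of
each switch trial to later graded recognition — with a Bayesian
importance-sampling procedure (P-CIT) and scores the NMPH by a log Bayes
factor over curve shapes.

Because no public dataset accompanies the design, the package includes a
first-class synthetic-study generator with known ground truth. Every
downstream stage (decoding, curve induction, permutation, bootstrap) is
exercised and validated against it; the P-CIT stage equally accepts
externally decoded per-trial evidence tables.

## Experiment structure as data

`experiment_design()` encodes the session: TR = 2 s; four 20-trial
phase 1 blocks (even face/scene split; trials are 1 s target + 7 s delay +
2 s probe + 6 s blank = 16 s); six 18-trial phase 2 blocks (12 stay trials
of 20 s, 6 switch trials of 28 s, ratio 2:1); 20 s of dummy pulses before
every block. These give 340 s phase 1 blocks, 428 s phase 2 blocks and a
3928 s session, all recomputed rather than hard-coded. Analysis windows
are half-open `[a, b)` intervals on the TR grid — the 4–12 s pre-switch
window therefore contains exactly the four scans at 4, 6, 8 and 10 s,
which is the only reading under which the window arithmetic is exact.

Classifier training exemplars are the scans from the final 6 s of each
phase 1 delay (3 scans/trial after the 6-s hemodynamic label shift), with
rest scans subsampled per block from the shifted intertrial intervals so
all three classes contribute 120 scans across the four blocks. The
subsampling is seeded, making "randomly sampled" reproducible.

## The synthetic generator

`ground_truth_config()` fixes the study conditions. Defaults: 21
participants × 36 switch trials (756 pooled items), 200 ROI voxels of
which 50 carry signal, unit-norm random face/scene templates, Gaussian
voxel noise SD 0.2, and per-trial amplitude mixtures — scene-dominant
before the switch cue (scene ~ N(1, 0.25), face ~ N(0.3, 0.25), truncated
at 0) and the mirror image after it. Trial-level variability enters through
these amplitude distributions rather than through voxel noise so that the
evidence axis is well sampled; without that, no curve-induction method can
resolve curve shape. Small per-participant offsets on the mixture means
(SD 0.1) give the participant bootstrap real between-subject variance.

Hemodynamics are modeled as a pure onset shift of the signal boxcar, with
an optional canonical double-gamma convolution behind the `hrf` flag. The
shift is per phase: 6 s in phase 1, matching the 6-s training label shift
exactly (so training labels align with signal scans), and 4 s in phase 2,
matching how the analysis windows are constructed (the post-switch window
begins 4 s after the switch cue precisely to catch the lagged post-cue
response). A single 6-s lag in phase 2 would place the 16–20 s window
astride the pre/post signal boundary and contradict the switch-trial
dynamics the generator is meant to emulate.

Behavior follows the ground-truth plasticity curve `f*` (default U-shaped,
knots at x = −0.2, 0.2, heights 0.8/−0.8/−0.8/0.8): each item's two
learning events (rescaled pre- and post-switch latent scene−face values)
pass through `f*` and sum, `p = plogis(0.5 + f*(e_pre) + f*(e_post))`; a
latent strength `p + N(0, 0.15)` is binned at fixed thresholds
0.25/0.5/0.75 into the four graded responses (sure new … sure old). The
binning construction is simple, monotone in `p`, and produces all four
response types; it replaces an unmodeled two-stage old/new + confidence
choice. Working-memory probe accuracy is Bernoulli in the probe-window
face evidence, `plogis(1.5 + 2 · e_face)`, giving accuracies in the
observed ~80% regime; novel lures for the recognition test sit at
`plogis(−1)` strength. Phase 2 timeseries contain switch trials only — the
brain–behavior analyses use nothing else — while the design module retains
the full 12-stay/6-switch block arithmetic.

What the generator does *not* emulate: scanner drift, motion and
physiological noise, spatial autocorrelation, HRF variability across
voxels, stay-trial behavior. Passing tests therefore demonstrate that the
*analysis machinery* is correct and well calibrated under the assumed
signal model, not that real fMRI data will behave this way.

## Decoding

Feature selection is a one-way ANOVA (face/scene/rest) per voxel at
p < 0.05, computed on training scans only; inside cross-validation it is
re-run within each fold's training blocks, a deliberate strictness that
removes selection leakage from the accuracy estimate (the final phase 2
model selects on all phase 1 data). Detectors are three independent
one-vs-other L2-penalized logistic regressions with λ = 50 applied as
`−loglik + λ/2‖w‖²` (intercept unpenalized), fitted by BFGS with analytic
gradients; a brute-force gradient-descent oracle verifies the optimum in
the tests. Evidence is each detector's raw logistic output in [0, 1] — the
three detectors are not softmax-coupled, so their outputs need not sum
to 1. Accuracy uses the argmax over the three evidences with ties broken
in fixed class order (face, scene, rest). No scan-wise normalization is
applied by default.

## Curve induction (P-CIT)

The hypothesis object is a three-segment piecewise-linear curve on the
rescaled evidence axis [−1, 1]: interior knot positions are order
statistics of two Uniform(−1, 1) draws, heights are i.i.d. Uniform(−1, 1).
Under this prior exactly half the mass is *theory-consistent* — the curve
drops strictly below its starting height and later rises strictly above
its minimum — because the label reduces to "the minimum height falls on an
interior knot". ("Rises above its minimum" was chosen over the stricter
"returns above its start"; the labeling is validated against a segment-walk
oracle.)

Evidence is rescaled once per analysis by the affine map sending the
pooled minimum/maximum over all values entering that analysis (both event
columns of the combined analysis pooled together) to −1/1. Each curve's
importance weight is its maximized likelihood: the two learning events
pass through the curve and sum, a logistic link with a profiled intercept
β₀ (1-D Newton ascent on the concave profile, bounds ±10, tolerance 1e-9)
maps the sum to a response probability, and graded outcomes enter through
the fractional-Bernoulli form `y log p + (1 − y) log(1 − p)` with exact
thirds for the graded levels and probabilities clamped at 1e-12. No free
slope multiplies the summed effect: a slope would trade off exactly
against curve amplitude, which is already bounded by the height prior.
The posterior summary is the weighted pointwise mean on a 101-point grid
with a weighted 5th–95th percentile band; the log Bayes factor is the
posterior-vs-prior odds of theory consistency (prior odds estimated from
the same sample's unweighted labels), capped at ±10 with a flag when one
class holds zero mass. Overall predictive fit is a likelihood-ratio
statistic against the intercept-only model, referred to χ² with df = 1
(the curve's net effect treated as one induced predictor), floored at 0.

Numerical choices worth knowing:

* The inner kernels (curve evaluation, intercept profiling) are compiled;
  `approx()` and `optimize()` re-derive them in the tests.
* `n_samples` defaults to 1e5; 5000 is the desk-scale setting used
  throughout the tests and the acceptance script. With 756 informative
  items the weights are highly concentrated (effective sample sizes of
  tens at 5000 draws); the fit carries a split-sample Monte-Carlo standard
  error of the log Bayes factor and warns below an ESS floor of 100.
* The χ² test is *conservative* under the null: with outcomes independent
  of evidence the posterior-mean curve shrinks toward flat, so the
  statistic piles up near 0 and p near 1. Tests assert type-I control
  rather than exact uniformity.
* Degenerate inputs error early and specifically: constant evidence
  cannot be rescaled, outcomes outside [0, 1] are rejected, and
  `partial_out()` of a variable on itself surfaces the constant-residual
  error rather than returning nonsense.

### A known limitation: monotone ground truth

With a U-shaped ground truth the pipeline is decisive (log Bayes factors
of +3 to +7 at 756 items). With a *monotone-increasing* ground truth the
log Bayes factor converges to only weakly negative values (−1 to 0,
dataset-dependent) rather than strongly negative ones. The reason is a
degeneracy of the curve family: when the first interior knot sits near
−1, the starting height controls a region containing almost no data, so
"U-shaped" curves whose dip is squeezed into that sparse left edge fit
monotone data essentially as well as truly monotone curves, and retain
close to their prior share of posterior mass. Conclusions of the form
"the curve is U-shaped" (positive log BF) are therefore well powered,
while "the curve is monotone" (negative log BF) is intrinsically
low-contrast at these sample sizes — worth remembering when interpreting
near-zero log Bayes factors.

## Resampling inference

All participants' items pool into one supersubject table (per-participant
data are too sparse for individual curve fits). The permutation test
shuffles the outcome column across the whole pool (within-participant
shuffling is available via `scope`), keeps the evidence — and hence its
rescaling — fixed, and reports the fraction of 200 null log Bayes factors
that match or exceed the observed one (`>=` convention). The participant
bootstrap redraws 21 participants with replacement, pools their items
(duplicated participants contribute duplicated items), recomputes the
rescaling on each replicate's pool, and reports the fraction of 200
replicates with positive log Bayes factor. Both procedures derive one RNG
substream per replicate from `(seed, replicate)`, are invariant to item
row order, and reuse the prior curve sample drawn once per analysis:
curves are prior draws independent of the data, so reuse changes only the
shared Monte-Carlo error, not validity, and makes 200-replicate defaults
interactive.

## Behavior module

Graded strengths are exact thirds internally (1, 2/3, 1/3, 0); 0.667 and
0.333 are display roundings. Recognition sensitivity is the Mann-Whitney
AUC (ties 1/2). The working-memory regression is a maximum-likelihood
logistic fit of single-trial probe accuracy on one evidence score with a
seeded percentile bootstrap 95% CI over trials (1000 resamples; percentile
rather than BCa, as nothing stronger is warranted); complete separation is
flagged and the slope capped at ±30 instead of erroring.

## Problem sizes used in the validation suite

The test suite and acceptance script size the simulations for a desktop
run: curve-direction recovery uses the canonical 756 items with 5000 curve
samples over 20 seeded replicates per ground truth; permutation
calibration uses 50 replicates of 120 null items with 500 samples and 99
permutations; oracle-equivalence checks use ≤ 20 items against a 9375-curve
enumeration grid; decoding checks run 2 participants at canonical signal
settings. The acceptance script runs the full canonical study once
(permutation and bootstrap at 200 replicates each for the combined
analysis).
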