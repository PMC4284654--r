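# pcitr

Neural-evidence decoding and Bayesian plasticity-curve induction for
subsequent-memory analysis.

## What this package is for

When two memories compete in working memory — say a scene and a face held
simultaneously, with attention switched from one to the other mid-trial —
what happens to the deprioritized memory afterwards? The non-monotonic
plasticity hypothesis (NMPH) predicts a U-shaped answer: *moderate*
activation of a memory (close competition) weakens it, while low or high
activation leaves it intact or strengthens it.

`pcitr` implements the full analysis chain for testing this prediction
with fMRI:

1. **MVPA decoding** — three one-vs-other L2-penalized logistic detectors
   (face / scene / rest, penalty λ = 50) trained on region-of-interest
   voxel patterns with ANOVA feature selection (p < 0.05), 6-s
   hemodynamic label shift, and leave-one-block-out cross-validation.
   Per-trial evidence is averaged over the pre-switch (4–12 s),
   post-switch (16–20 s) and probe (20–24 s) windows; the index of
   competitive balance is scene − face evidence.
2. **P-CIT curve induction** — the plasticity curve linking evidence to
   graded recognition strength (sure old = 1, unsure old = 2/3, unsure
   new = 1/3, sure new = 0) is estimated by importance sampling over
   three-segment piecewise-linear curves f on the rescaled evidence axis
   [−1, 1]. The pre- and post-switch measurements of each item are
   separate learning events whose effects sum:

   p(remember item i) = logistic( β₀ + f(e_pre,i) + f(e_post,i) ),

   with β₀ profiled out per curve. Curves are labeled *theory-consistent*
   if they are U-shaped (drop strictly below their start, then rise
   strictly above their minimum); the headline statistic is the log Bayes
   factor log[posterior odds / prior odds] of consistency — positive
   values favor the NMPH. A likelihood-ratio χ² tests whether the induced
   curve explains the outcomes at all.
3. **Inference** — permutation of the evidence→outcome mapping across the
   pooled "supersubject" (200 permutations, fraction of null log BFs ≥
   observed), bootstrap over participants (200 replicates, fraction with
   log BF > 0), partialing analyses (pre residualized on post and vice
   versa), and a bootstrap-CI logistic regression of working-memory probe
   accuracy on evidence.
4. **Synthetic studies** — a generator with known ground truth (category
   templates in ROI voxel timeseries, scene-dominant pre-switch and
   face-dominant post-switch amplitude mixtures, a true plasticity curve
   driving graded recognition) so the whole pipeline is testable without
   any data download. The canonical configuration is 21 participants × 36
   switch trials = 756 items.

## Worked example

```r
library(pcitr)

cfg   <- ground_truth_config(n_participants = 4, seed = 1)  # U-shaped truth
study <- generate_dataset(cfg)
study
#> <synthetic_study> 4 participants, 144 switch trials, 200 voxels (50 informative), noise sd 0.2

items <- decode_study(study)   # feature selection -> detectors -> windows
fit <- pcit(items, events = c("pre_switch_smf", "post_switch_smf"),
            outcome = "strength", n_samples = 5000, seed = 2)
fit
#> P-CIT curve induction
#>   items: 144 (2 learning events each); curve samples: 5000
#>   log Bayes factor (non-monotonic hypothesis): 3.866
#>   predictive fit: chi^2(1) = 15.77, p = 7.16e-05
#>   effective sample size: 161

pm <- permutation_test(items, c("pre_switch_smf", "post_switch_smf"),
                       "strength", n_samples = 5000, n_perm = 200, seed = 3)
pm
#> P-CIT permutation test (200 permutations, scope: pool)
#>   observed log BF: 3.626
#>   fraction of null log BFs >= observed: 0.000
```

The positive log Bayes factor says the posterior over curves puts ~48×
more odds on U-shaped (theory-consistent) curves than the prior does —
the generator's U-shaped ground truth is recovered from the decoded
evidence. The χ² says the induced curve explains real outcome variance,
and the permutation test says no outcome shuffle among 200 reached the
observed log BF. `tidy(fit)` returns the posterior mean curve with its
90% credible band as a tibble, `glance(fit)` the one-row summary, and
`autoplot(fit)` the ribbon plot. `run_study()` orchestrates all five
analysis variants (combined / pre-only / post-only / both partialing
directions) plus the working-memory regressions from one seeded
configuration.

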