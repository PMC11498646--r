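---
title: "Models and methods for simulated hue ensemble experiments"
author: "enshue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for simulated hue ensemble experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enshue)
```

## The scientific problem

Observers can extract the mean hue of a set of colored elements (an
"ensemble") and compare it across briefly presented displays. When a
task-irrelevant distractor set of a different hue is spatially intermixed
with the target set, two things can happen: the distractor elements leak
into the target estimate (a *mixing* failure of segmentation), which biases
the perceived target mean toward the distractor hue, and the added hue
variance raises the discrimination threshold. `enshue` provides the full
machinery to simulate and analyse two-interval forced-choice (2IFC)
experiments of this kind on the CIELUV LCh hue circle (lightness and chroma
fixed at 70), together with the categorical-observer model used to locate
color category boundaries on the same circle.

Everything is parametric and seedable: the same configuration and seed
reproduce every schedule, response and fit bit for bit.

## The 2IFC design

Two experiment geometries are built in, exposed through
`design_constants()` and the schedule builders.

* **Experiment 1**: target mean at 340° (pink group) or 130° (green group);
  element hues drawn from a 30°-wide uniform distribution; four conditions
  — no distractor (baseline), distractor 180° away, and distractors 60°
  toward yellow (60Y) or blue (60B). Hue angle increases counterclockwise,
  so "toward yellow" is +60° for the pink target and −60° for the green
  target. Eight blocks (4 conditions × 2) of 110 trials: 11 comparison
  levels × 10 repetitions, i.e. 880 trials. Comparison steps are 4°
  (baseline), 5° (180) and 6° (60Y/60B); trial jitter is uniform within
  ±7.5°.
* **Experiment 2**: target mean 22.5° from the observer's green–blue
  boundary (green side for the green group, blue side for the blue group);
  25°-wide element distributions; distractors 45° across or within the
  category; ±5° jitter; steps 4° (baseline) and 7° (distractor conditions).
  Nine blocks (3 conditions × 3) of 88 analysed trials preceded by 11
  dummy trials each: 792 analysed trials and 99 flagged dummies.

Practice schedules use only the three most distant comparison magnitudes on
each side (6 of the 11 levels, never the zero offset), 3 repetitions each,
with baseline first and the 180° block second.

Two design points were genuinely open and are settled here:

* **Offset anchoring.** Comparison offsets are applied relative to the
  *jittered* target mean of each trial. Anchoring to the nominal mean would
  add the jitter (SD ≈ 4.3° in experiment 1) to every psychometric level
  and inflate baseline thresholds far beyond what small-threshold data can
  show; the schedule logs both the jitter and the offset so the alternative
  analysis remains recoverable.
* **Dummy trials** are generated for every block (including baseline) with
  one shuffled pass through the 11 levels, flagged `is_dummy`, and excluded
  from every analysis. Their only purpose downstream is bookkeeping parity
  with real logs. The 180° practice block of experiment 2 reuses the 5°
  step of experiment 1's 180 condition, which is otherwise absent from the
  experiment-2 step table.

## The synthetic observer

`observer_params()` defines a generative observer with five parameters:

* `distractor_weight` *w* — per-element weight of distractor elements
  relative to target elements (weight 1). The test-interval estimate is the
  weighted circular mean of all 36 elements.
* `internal_noise_sd` — wrapped-normal noise in degrees added independently
  to each interval's estimate. Because the decision variable is the
  difference of two noisy estimates, the fitted cumulative-Gaussian SD is
  approximately `sqrt(2) * internal_noise_sd` plus the element-sampling
  variance of the 18-element means. The default 4° puts baseline thresholds
  in the few-degree range typical of hue ensemble data.
* `ctb_weight` — central-tendency pull: linear shrinkage of the
  test-interval estimate toward the across-trials grand mean, which in
  these designs equals the nominal target mean. Default 0 (the pure sensory
  observer); the parameter exists because a central-tendency account makes
  different predictions from sensory mixing and is worth simulating.
* `lapse_rate` — probability of a uniform random response.
* `subsample_size` — optional attention-limited subsampling (elements drawn
  without replacement before averaging). Disabled by default; weighting and
  subsampling accounts are not distinguishable from bias alone, and the
  weighting form is the one implemented throughout.

For equal element counts and a target–distractor separation *s*, the
expected position of the weighted circular mean sits at

> bias(w) = atan2(w · sin s, 1 + w · cos s)

degrees from the target mean toward the distractor. `mixing_bias()`
computes this forward map and `mixing_weight_for_fraction()` inverts it on
the bias-fraction scale (bias divided by the full-integration midpoint
prediction `s/2`). Note that the relation is *not* linear averaging: at
`s = 60°`, `w = 1/3` produces a bias fraction of about 0.46, not 1/4, and
`w = 1` produces exactly the midpoint (fraction 1). An observer producing a
quarter of full integration at 60° separation — the mixing level typical of
reported hue-ensemble data — corresponds to `w ≈ 0.165`:

```{r mixing}
w <- mixing_weight_for_fraction(0.25, 60)
w
mixing_bias(w, 60)        # expected bias in degrees (full integration = 30)
```

An undefined circular mean (exact antipodal cancellation, possible only in
the 180° geometry with `w = 1`) is resolved by a fair coin between the two
opposing directions, mirroring the fact that opposing hues admit no
meaningful average.

## Psychometric analysis

`fit_pmf()` fits `P(choose higher hue) = pnorm((offset - mu) / sigma)` by
Bernoulli maximum likelihood with `mu` in [−90, 90]° and `sigma` in
[0.1, 500]° — bounds far outside plausible data, present purely for
numerical stability. The optimizer is deterministic: a probit-regression
start plus a fixed grid of restarts, so the same data always give the same
fit. No lapse parameter is estimated (two-parameter fits, as is standard
for this design); a fixed lapse can be supplied. A fit is flagged invalid
when the fitted curve fails to reach 0.25 and 0.75 within the tested
comparison range, the conventional exclusion rule for unreliable fits;
degenerate (all-0/all-1 or flat) data hit the parameter bounds and the
invalid flag rather than raising errors.

The PSE `mu` is converted to a signed bias by `bias_toward_distractor()`:
positive always means *toward the distractor*. A distractor at lower hue
angle pulls the perceived test mean down and the PSE negative, so the bias
is the PSE multiplied by the sign of the shortest arc from target to
distractor. The bias fraction divides by the full-integration prediction
(`s/2`); it is undefined for baseline (no distractor) and for the 180°
condition (no meaningful average of opposing hues). The "ground truth"
against which baseline bias is reported is the zero comparison offset.

## The categorical observer and its estimation

The categorization model (`category_model()`) assumes a von Mises
measurement of the stimulus hue (shared concentration κ across categories —
a single noise process for the observer) and fixed boundaries that
partition the hue circle; the response probability of a category is the von
Mises mass of its arc. `fit_boundary_model()` maximises the likelihood of
observed stimulus × category counts over κ and the boundaries, each
boundary box-constrained between its two adjacent category centroids
(response-weighted circular means). Optimization uses `L-BFGS-B` on
log-κ and per-boundary gap fractions, from the interval midpoints plus two
deterministic jittered restarts; non-convergence is flagged on the returned
object, never silent. In the noiseless limit the likelihood plateaus in κ
(any sufficiently large value fits perfectly), so the optimizer may stop on
the plateau with a line-search warning while the boundaries are already
identified to within one stimulus step.

Before fitting, `clean_category_data()` applies two exclusion passes:
categories with fewer than 4 responses are dropped, and responses 20° or
more from the category's main response group are removed, where groups are
runs of adjacent occupied stimulus values terminated by three consecutive
empty 5° steps and the main group is the largest in hue steps. Cleaning is
idempotent and reports what it removed.

Pilot recovery runs at the design size (72 stimuli × 4 repetitions, two
categories, κ = 10) give a median boundary error of about 2.2° and a median
relative κ error of about 29%; κ is weakly identified at this size because
only stimuli near a boundary carry information about it. The test suite
asserts the boundary criterion (median error < 3°); κ accuracy is reported
but not asserted beyond sanity.

### von Mises machinery

Arc probabilities are computed from the Fourier series of the von Mises
CDF, with Bessel-function ratios `I_j(kappa)/I_0(kappa)` obtained by
Miller's backward recurrence (base R's `besselI` at thousands of orders
costs O(order²), the recurrence is linear). Truncation keeps the error
below 1e−12 for κ up to 2×10⁴; beyond that (angular SD < 0.4°) the
wrapped-normal limit takes over, whose O(1/κ) error is far below anything
the likelihood can resolve while keeping the objective smooth. κ = 0 is the
exact uniform limit. Sampling uses the Best–Fisher rejection algorithm.

## The interleaved staircase

`run_staircase()` implements four interleaved 1-up/1-down staircases in
strict round-robin (the interleaving scheme is not otherwise constrained),
two starting 20° below and two 20° above the initial guess. A green
response raises the stimulus hue, blue lowers it; the step starts at 4° and
is "decreased by one fourth" at each reversal, read multiplicatively
(× 0.75) — an additive −1° reading would reach zero after four reversals
and stall the procedure — with a 0.25° floor. Reversal points are the
stimulus values at which the response direction changed (recorded before
the shrunken step is applied). After 25 trials per staircase the boundary
estimate is the circular mean of the last two reversal points of each
staircase; staircases with fewer than two reversals are dropped with a
warning rather than contributing their starting transient. With a
symmetric responder the estimate is unbiased to within ±0.5° on average
at κ = 20.

## Condition-level statistics

`paired_t()` (observer-matched, two-sided), `bonferroni()` (explicit family
size, since the family is an analysis choice), and `correlate()` (Pearson,
within condition, across observers, over the measure pairs among bias,
threshold and the two flanking category boundaries) mirror the standard
analysis of such cohorts. Degenerate inputs — zero-variance differences or
columns — are flagged, not fatal. Linear mixed models are deliberately out
of scope: `export_long()` hands the fit table to external LMM software in
long format.

## What the simulations do and do not show

The generator reproduces the *structure* of real data — trial counts,
uniform hue scatter, jitter, interval randomization, binomial response
variability, categorization confusions near boundaries — under an observer
whose only failures are mixing, internal noise, central tendency and
lapses. It does not emulate sequential dependencies, learning or fatigue
across blocks, observer-specific color-space inhomogeneities, or
response-strategy changes (e.g. deliberate compensation for a suspected
bias), all of which shape real cohorts. Passing recovery tests therefore
demonstrates that the analysis chain is unbiased and well calibrated for
observers of the assumed class, not that human data must follow the mixing
model.

Problem sizes used in the test suite were chosen to make Monte Carlo error
comfortably smaller than each tolerance: ~10⁴ trials for psychometric
recovery (PSE standard error ≈ 0.1°), 50 replicates for boundary-model
recovery, 200 seeds for staircase unbiasedness.

## Reproducing the headline simulation

`scripts/acceptance.R` regenerates the package's headline number from
scratch: a mixing observer at the quarter-integration weight in the
experiment 1 60° geometry, 10,010 trials, PMF fit, bias reported as a
percentage of full integration. See the README for the command line.
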