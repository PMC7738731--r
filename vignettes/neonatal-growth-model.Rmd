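---
title: "Modelling neonatal puppy growth with pupgrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling neonatal puppy growth with pupgrowth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupgrowth)
```

## The growth law

During the neonatal period (birth to about three weeks), while puppies
are exclusively milk fed, weight follows a log-quadratic law remarkably
well across breeds from toy to giant size:

$$P(x) = P_0 \exp(b_1 x - b_2 x^2),$$

where $P$ is weight in grams on day $x$ and $P_0$ is the weight on day
0. The reference coefficients are $b_1 = 0.13084\ \mathrm{d^{-1}}$ and
$b_2 = 0.001616\ \mathrm{d^{-2}}$, stored as
`growth_coefficients()`. Three consequences drive everything else in
the package:

* the *relative* daily gain, $(dP/dx)/P = b_1 - 2 b_2 x$, does not
  depend on the puppy's weight — it declines linearly from 13.1%/day at
  birth to 6.3%/day at day 21, averaging about 10%/day;
* curves for different $P_0$ are parallel on the log scale, so a
  population of puppies shares the slope coefficients and differs only
  in intercepts;
* the law describes *maximum* growth: puppies leave their curve only
  downwards ("falls" to a curve with smaller $P_0$), never upwards.

```{r}
relative_daily_gain(c(0, 21))      # 13.1% -> 6.3% per day
time_to_multiple(2)                # days to double birth weight
setback_adjusted_p0(0.8, 2)        # curve offset after a 20% loss by day 2
```

The quadratic exponent has a vertex near day 40; that is an artifact of
the functional form, not a biological plateau, so predictions past day
28 trigger a warning and the fitting window defaults to days 0–28
(validation-stage operations use days 0–21).

## Fitting the shared slopes

`fit_shared_slope_model()` estimates the global coefficients by
ordinary least squares of $\ln y$ on one indicator column per puppy
(its intercept $a_i = \ln P_{0i}$) plus shared polynomial age columns
— a fixed-effects ("shared slope") design with no global constant,
since the indicator block spans it. `select_order()` fits orders 1–4
and keeps, among the orders whose every slope coefficient has a 95%
t-based confidence interval excluding zero, the one with the highest
adjusted $R^2$; on data generated by the law itself this retains the
quadratic, and on purely exponential data it degrades to the linear
model. $R^2$ is computed about the response mean and the adjusted
version charges $n_{\text{puppies}} + \text{order}$ parameters; both
conventions are fixed and documented here because the design has no
global intercept.

Two diagnostics accompany the fit: per-sex residual means with a
one-sample t test (the model should be unbiased for both sexes — no
sexual dimorphism is detectable in the first three weeks), and
per-puppy lag-1 residual autocorrelation flagged beyond the
approximate 95% bound $1.96/\sqrt{m}$. `compare_sex_growth_rates()`
compares mean observed relative daily gains between sexes with a
pooled-variance Student t test (Welch available via `pooled = FALSE`).

Note that the shared-slope regression assumes each puppy follows a
*single* curve. Real populations, where most puppies fall across
curves, are not suitable input for coefficient estimation — this
mirrors how the law was originally derived from litters that happened
to sustain maximum growth throughout.

## Per-puppy trajectories

With the coefficients fixed, each record carries an implied log curve
offset $c_i = \ln w_i - (b_1 x_i - b_2 x_i^2)$, and a puppy's series
becomes a step pattern in $c$: runs of constant offset (curves),
separated by one or two descending off-curve transition days, with the
offsets strictly decreasing — a puppy never rejoins a higher curve.
`segment_trajectory()` mechanizes what was originally done by eye, in
two stages:

1. **Greedy forward pass.** The current curve's $P_0$ is re-estimated
   (closed-form linear least squares, `estimate_p0()`) as records
   accrue; a fall is confirmed when the log residual stays below
   `-drop_threshold` (default 0.03, chosen above the ~2% measurement
   noise floor implied by validation error and the 5-g scale) for
   `min_run` (default 2) consecutive records, after which the next
   segment opens on the longest consistent run with strictly lower
   $P_0$.
2. **Global refinement.** A penalized least-squares partition of the
   offset series, solved exactly by dynamic programming, settles the
   boundaries. Each record is either a segment member (cost: squared
   residual over the scatter), an off-curve transition day (at most two
   per fall, small fixed cost), part of a bounded initial descent (the
   pre-curve loss path), or a gross outlier. Opening an additional
   curve costs $1.5\ln n$. The scatter scale is estimated robustly from
   first differences of the offsets (35th-percentile fallback for clean
   series whose differences are mostly structural) and floored near
   zero so noise-free series are segmented exactly. Adjacent curves
   whose $P_0$ gap is within what the scatter supports are merged, so
   the output invariably satisfies the strictly-decreasing-$P_0$
   constraint.

The forward pass alone resolves clean series perfectly but, at the
default threshold, makes marginal split/merge calls under realistic
noise; the refinement stage is what lifts segment-count recovery to
the documented rates (below). Design choices worth knowing: records
above `+drop_threshold` never open a higher curve (falls are
irreversible by assumption); a transition day absorbed into a segment
is expelled by an outlier trim so clean-series $P_0$ estimates stay
exact; and `gained_from_day0` is true when the day-0 record lies on
the first curve *or* the first curve's $P_0$ matches the day-0 weight
within the threshold (a setback curve sits at least ~12% lower, so the
two conditions cannot both misfire).

`population_summary()` aggregates pattern fractions (single curve,
three or more curves, gained from day 0, joined a curve within three
days of a drop) across trajectories.

## Validation metrics

`mare()` is the mean absolute relative error with the *predicted*
value in the denominator — the convention used for growth-curve
validation here; the more common observed-denominator reading is
available via an argument and the output records which was used.
`rmse()` is in grams. `origin_regression()` fits predicted on observed
through the origin with the uncentered $r^2$ (the centered convention
is undefined without an intercept). `per_breed_metrics()` evaluates
fitted trajectories record by record, excluding off-curve transition
days (the curves only claim to describe on-curve growth) and reporting
the excluded count.

## The synthetic population

Because the original breeder-recorded weight series are private, the
package ships a calibrated generator (`simulate_population()`) that
reproduces the *statistical structure* of such data rather than any
individual dataset:

* nineteen breeds with birth-weight ranges from 70 to 1,000 g, litter
  counts and litter-size ranges as tabulated in
  `default_breed_table()`; birth weights uniform within the breed
  range, sexes Bernoulli(0.5);
* 48% of puppies gain from day 0; 33% lose up to 20% of birth weight
  over the first 1–2 days; the rest stagnate briefly; all join a curve
  within 3 days (configurable cap), consistent with the observation
  that over 95% do;
* 10% follow a single curve, two-thirds follow three or more; of the
  three-plus class, a quarter follow four (the 22-day window rarely
  accommodates more) — an internal choice, as no distribution over
  "three or more" is documented;
* falls are uniform in time subject to a minimum separation (default 3
  days) and leave at least two on-curve records per segment and three
  after the last fall; magnitudes are uniform on 5–15% of the current
  $P_0$; each fall passes through 1–2 log-interpolated transition
  days. Uniform distributions are used because fall timing and
  magnitude show no pattern beyond randomness;
* multiplicative measurement noise with ln-scale SD 0.026, calibrated
  so the pipeline's empirical MARE ($\sigma\sqrt{2/\pi} \approx 2.1\%$)
  lands near the validation value reported for real data, then
  quantization to the 5-g divisions of the reference scale;
* a hook (`sex_effect_b1`) injects a sex effect for power studies; by
  default there is none, matching observation.

Every simulated puppy carries its ground truth (curve $P_0$s, fall
days, off-curve days, initial-loss path), so recovery tests never
re-infer generative parameters. What the generator does *not* emulate:
missed weighing days, recording errors, litter-level correlation of
fall timing (falls are independent across littermates even though a
real cause — say, a dam leaving the nest — would synchronize them),
and any breed-specific deviation from the common law. Passing tests on
synthetic data therefore show the pipeline is correct and calibrated,
not that real kennel data are this clean.

## Measured behaviour and problem sizes

The test suite and the reproduction script use these problem sizes,
chosen to exercise each claim at full strength while staying quick:
coefficient recovery uses 5 puppies at days 0–21 (110 observations);
segmentation recovery uses 100 seeded trajectories per condition with
birth weights uniform on 250–500 g (the model-development breed's
range) and falls separated by at least 4 days; the calibration check
simulates the full 19-breed population (~350 puppies) plus a
single-breed population of exactly 400 for binomial checks of the
pattern proportions. Under those conditions the segmentation recovers
the exact segment count and every $P_0$ within 1% on noise-free
series, and the segment count in at least 90 of 100 series at the
calibrated noise with falls of 8% or more; a pure forward pass
plateaus several points lower, which is why the refinement stage
exists.

## Known limitations

* The law is descriptive of maximum growth up to three weeks; it says
  nothing about what deviation warrants supplementary feeding, and the
  package deliberately only reports deviations.
* Percentile-style population charts are intentionally absent: with
  falls occurring at random times, a population average reflects the
  sample, not any actual growth pattern of an individual.
* Trajectory segmentation needs at least 3 records and at least 2 per
  curve; curves closer than the scatter threshold (3% by default) are
  indistinguishable by design.
* Fit quality for coefficients assumes single-curve series; feeding a
  general population to `fit_shared_slope_model()` yields biased,
  high-order fits and is the wrong tool — fix the published
  coefficients and use trajectories instead.
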