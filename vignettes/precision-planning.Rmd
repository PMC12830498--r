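---
title: "Planning sample sizes for well-measured items"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning sample sizes for well-measured items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itemprecision)
```

## The estimand and the procedure

Multi-item studies deliver one estimate per item — a mean rating, a mean
latency — and the scientific value of the dataset rests on how precisely
each of those is measured. `itemprecision` plans the per-item sample size
so that a target share of items reaches a precision criterion, combining
accuracy-in-parameter-estimation thinking (target a narrow uncertainty
window, not a detectable effect) with Monte Carlo resampling of pilot data.

The precision quantity is the item standard error `SE_i = SD_i / sqrt(n_i)`
with the sample (n−1) standard deviation. The criterion is relative to the
study's own items: the cutoff is the empirical 4th decile of the pilot SEs.
A relative cutoff adapts automatically to the scale of the instrument
(a 1–7 rating and a millisecond latency need no separate configuration) and
deliberately "overpowers" the typical item: at the final N, most items are
measured better than the pilot's 40th-percentile item was.

From there the pipeline is: bootstrap each item's pilot scores at every
candidate size on a grid; per size, average over replicates the fraction of
items with simulated SE strictly below the cutoff; take the first size at
which the averaged curve reaches each target level (80/85/90/95%); correct
that projection (next section); inflate for expected data loss; and report
a minimum N, the stopping-rule SE, and a maximum N.

The only distributional assumption is that item scores come from a stable
distribution with finite mean and variance — the procedure manipulates
empirical SEs, not model parameters, which is why ceiling-skewed and even
bimodal items are handled by the same machinery.

## Why projections need correcting

A bootstrap projection inherits the pilot's size: a larger pilot pins down
the item SDs better, and — because the cutoff is a quantile of SEs *at the
pilot's n* — the raw projected N grows roughly linearly with the pilot
size. Power-style curves should instead level off. Two corrections are
provided:

* **Decay correction** (`decay_factor()`, `apply_decay()`):
  `1 − sqrt((N_pilot − n_min)/N_pilot)^log2(N_pilot)`, where `n_min` is the
  smallest simulated size. The factor is exactly 1 when the pilot equals
  the grid start (small pilots are not shrunk) and decreases smoothly in
  the pilot size. The harness treats the decayed projection as its ground
  truth when comparing conditions.
* **Regression correction** (`regression_correction()`): a nine-term linear
  model — intercept plus projected N, pilot N, percent of items below the
  cutoff ("power", in percent units: 80, not 0.80), and the proportion of
  possible variance, each raw and log2-transformed — with published
  coefficients. `correction_coefficients("fourth_decile")` is the default
  set, fit for the recommended 4th-decile cutoff;
  `"all_deciles"` pools every decile and suits non-default cutoffs. The
  coefficients are used as printed constants; re-estimating them would
  require the original full-scale simulation and is out of scope.

The heterogeneity input to the regression is the **proportion of possible
variance**: the SD of the per-item SDs divided by half the scale range.
Dividing by half the range makes the summary scale-free, so a 1–7 and a
0–3000 instrument are comparable. Note the numerator is the SD of item
*standard deviations*, not of their standard errors: the worked numbers
(0.28 on a 1–5 scale giving 0.14) pin down that reading.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `decile` | 0.4 | Cutoff quantile of pilot SEs. Lower deciles are much stricter and can push N beyond feasibility; higher ones under-measure items. |
| `sample_grid(start, stop, step)` | 20–300 by 5 | Candidate per-item sizes. `start` also anchors the decay correction; 20 is the smallest size worth simulating. |
| `nsim` | 500 | Bootstrap replicates per size; 500–1000 stabilises the curve. |
| `power_levels` | 80, 85, 90, 95 | Conventional target percents; the smallest is the natural minimum N, the largest the maximum. |
| `retention` | 1 | Proportion of usable trials; final N is `ceiling(N / retention)`. |
| `nominal_power` | `FALSE` | The regression uses the percent actually achieved at the first crossing (e.g., 82.0); set `TRUE` to force the nominal levels. |

Pilot size itself matters: below ~30 participants per item the pilot's SE
and cutoff estimates are visibly biased (see the harness results below),
which is why `plan` warns when the pilot n is under 30.

## What the generator emulates

`population_preset()` reproduces a three-scale benchmark: Likert 1–7
(item means ~ Normal(4, 0.25), SDs ~ Normal(2, σσ) with σσ ∈
{0.2, 0.4, 0.8}), percent 0–100 (means 50 ± 10, SDs 25 with σσ ∈
{4, 8, 16}), and milliseconds 0–3000 (means 1000 ± 150, SDs 400 with σσ ∈
{50, 100, 200}). Ceiling variants move the mean to 6, 85, and 2500; floor
variants mirror those about the midpoint (2, 15, 500 — the mirror rule is a
package choice, since only ceiling means are conventionally quoted).
Populations default to 30 items × 1000 scores. All scores are rounded to
whole numbers and then clamped to the scale endpoints, in that order; skew
arises purely from this boundary pile-up, not from skewed primitive
distributions. Bimodal items concatenate half a ceiling and half a floor
component (the extra score goes to the ceiling half when n is odd).

What the generator does *not* emulate: participant-level dependence (each
item's scores are drawn independently, so there is no shared participant
variance across items), ordinal response processes (scores are rounded
normals, not threshold models), and drop-out structure. Passing tests on
these populations therefore says nothing about designs where
participant-level covariance dominates item precision.

Numerical details worth knowing:

* Item SDs are drawn from Normal(σ, σσ) and redrawn while below 0.01σ;
  configurations where that truncation would discard more than 40% of the
  distribution's mass are refused outright rather than silently distorting
  the requested moments. The benchmark presets sit far from this guard
  (σ ≥ 2.5σσ everywhere).
* Rounding is half-away-from-zero, not banker's rounding.
* One integer seed drives a hierarchical stream (population → pilot →
  bootstrap), so sub-steps are independently reproducible and
  `bimodal_sweep(fraction = 0)` replays the corresponding unmixed
  `run_condition()` exactly.

## Numerical and design choices

* **Quantile convention.** `decile_cutoff()` interpolates linearly between
  order statistics at `h = (k − 1)q + 1` (R's type-7 default). Other
  conventions differ by at most one order-statistic gap; with ~30 items
  this is well inside the Monte Carlo noise of the rest of the pipeline.
* **Strict inequality.** "Below the cutoff" is `SE < cutoff`. Ties have
  measure zero for continuous scores; for heavily discretised data the
  choice can matter at exactly the cutoff and is documented rather than
  configurable.
* **First crossing.** The projected N is the first grid size whose
  *replicate-averaged* percent reaches the level, even if the curve later
  dips (sampling noise can make it locally non-monotone).
* **Representative pilot n.** With unequal per-item n the pilot n entering
  the correction is the ceiling of the mean per-item n (28.52 → 29).
* **Extrapolation floor.** Regression outputs below the grid start are
  floored there with a warning; the published model was never meant to
  extrapolate below the simulated range.
* **Degenerate inputs.** An all-constant pilot has cutoff 0; the harness
  reports the grid start at every level (any size suffices), while the
  regression correction is undefined there (log2 of a zero proportion of
  variance) and returns `NA` with the decay value still available.
* **Reconstruction from summaries.** `reconstruct_pilot()` regenerates
  pilot-like data from per-item means/SDs by normal resampling. It is a
  convenience approximation: the true response distribution, rounding, and
  clamping are unrecoverable from two moments.

## What the harness shows

`evaluate_pilot_sizes()` draws many simulated researchers from one
population and reports, per condition × pilot size: the SD across
researchers of the decay-corrected recommendation, the mean relative SE
bias `(est SE − true SE)/true SE` (true SE = population item SD at the same
pilot n), and the relative cutoff bias against the population-level decile
cutoff. At the default reduced scale (20 researchers, grid 20–300 by 20,
50 replicates — chosen so a full factorial sweep completes in minutes;
the full-scale design of 100 researchers and a 20–2000 grid is reachable
through the same arguments) the bias statistics behave as expected:
both shrink toward zero from pilot 20 to pilot 40, and are essentially flat
beyond ~30 — the basis for the ~30-participant pilot recommendation.

One stability result deserves a caveat: the researcher-to-researcher SD of
the *decay-corrected* recommendation does not decrease for larger pilots in
our harness — it grows slightly (e.g., ~14 at pilot 20 vs ~19 at pilot 40
in the millisecond/large-heterogeneity condition), because the decay factor
is exactly 1 at the grid start while the raw projection's spread grows with
pilot size. Users comparing pilot sizes should therefore lean on the bias
statistics, which do favour larger pilots, rather than the SD column alone.

`bimodal_sweep()` reproduces the expected rise-then-fall: recommendations
climb as the first ~40% of items turn bimodal (those items' larger SEs
widen the SE spread) and fall again past 50% (an all-bimodal set is
homogeneous once more — precisely measured, even if the bimodal mean is not
the quantity a researcher wanted).

## Problem sizes used by the test suite

The packaged tests run the sweeps at deliberately modest sizes — 20 paired
replicates for the heterogeneity ordering, 10 for the pilot-size
flattening check, 5 per fraction for the bimodal sweep, bootstrap grids of
20–300 by 20 with 50 replicates, and 50 population replicates per condition
for the scale-ordering summary — sizes at which the trends asserted are
stable across seeds while the whole suite stays under a minute. These
checks establish trends and orderings, not figure-exact values.

## Known limitations

* The correction coefficients are constants from one benchmark simulation;
  instruments far outside the three benchmark scales (e.g., unbounded
  counts) rely on the scale-free proportion-of-variance input carrying
  over, which is untested territory.
* One score stream per item: no multi-session or nested designs, and no
  participant-level covariance.
* The procedure controls the SE of item means only — no robust or ordinal
  SE variants, and no reliability planning; combine with a conventional
  power analysis when a specific hypothesis test also matters.
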