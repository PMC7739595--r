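---
title: "Methods: network models of stress-related injury risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network models of stress-related injury risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sports-injury occurrence is multifactorial: psychosocial stress (major
life events, personality dispositions) and physiological stress markers
(muscle stiffness, heart rate variability, postural stability) interact
in ways that single-predictor regressions do not capture. `injurybn`
implements a repeated-measures analysis of such cohorts built on Bayesian
networks: a joint distribution factorised over a directed acyclic graph
(DAG), learned from data under theory-driven constraints, then queried
for conditional injury probabilities.

Two complementary analyses are provided:

1. **A two-time-slice network (2TBN)** on median-split (Low/High)
   variables. Each row pairs two consecutive measurement occasions;
   time-varying variables appear as `x_1` (time T) and `x_2` (time T+1),
   and arcs from the later slice into the earlier one are forbidden, so
   the learned structure respects the order of data collection.
2. **A change-score network** on standardised within-participant changes
   between occasions, keeping the variables continuous (conditional
   linear Gaussian, CLG) and collapsing the outcome to whether the
   participant was injured at any point in the study. This targets the
   *amount* of change rather than threshold crossings.

## Instrument scoring

* **Life events** (69-item survey, ratings −4..+4 or "not experienced"):
  NLE is the magnitude of the summed negative ratings, PLE the summed
  positive ratings, TLE their sum of absolute values, so TLE = NLE + PLE.
  NLE is reported as a positive magnitude because the published score
  ranges (0–93) are positive; the verbal scoring rule is sign-ambiguous.
* **Personality subscales** (51 items, 1..4): per-subscale sums. Only the
  BIS item count (17, pinned by its 17–68 score span) and the total of 51
  are fixed by the source; the default map (FFFS 8, BIS 17, RI 4, GDP 7,
  RR 8, I 7) satisfies the published spans and is caller-overridable.
* **Heart rate variability**: inter-beat intervals are artifact-filtered
  by a centered running median rule (window 11 beats, relative tolerance
  0.2 — a documented stand-in, since the original filter's algorithm is
  not published), the first 3 min and last 2 min are discarded, and RMSSD
  is computed on the remaining 5-min window. The natural log of RMSSD is
  returned alongside, because the published Low/High boundaries (e.g.
  4.01 = ln 55.1 ms) are clearly on the log scale even though the
  transform is never stated. The printed defining equation is actually
  the mean-RR formula; it is exposed as `mean_rr()` while
  `compute_rmssd()` implements the canonical statistic.
* **Muscle stiffness**: per site, the median of five impulses; a set with
  coefficient of variation ≥ 3% is flagged for re-measurement; the total
  is the sum of the eight site medians (four muscles, both limbs).
* **Balance errors**: six stances each capped at 10 errors, summed to
  0–60; asymmetry is `100·|L−R|/mean(L,R)` over the single-leg stances
  (the source says only "percentage difference between limbs").

## Data preparation

Missing stiffness and HRV measurements (missing completely at random in
the emulated design) are imputed by bagged regression trees: 25 bootstrap
CART trees per target column, trained on all other columns, refined over
two sweeps because both targets can be missing simultaneously. No
dedicated tree package is available in the target environment, so the
trees (greedy variance-reduction splits, categorical levels ordered by
mean response) are part of the package. Imputation precedes
discretisation: prediction in the continuous space is better determined
than after binarisation.

For the 2TBN, negative life events are accumulated over occasions (a
running total, reflecting the persisting load of earlier events),
log-scaled as `ln(x+1)` — zero counts are common, and this choice
reproduces the published boundary correspondences 13 ↔ 2.64 and
93 ↔ 4.54 — and median-split per time point (the published boundaries
drift across occasions); time-stable explanatory variables are split on
pooled values. Ties at the boundary go to "Low", matching the inclusive
notation "0–13 (Low) / >13–93 (High)". The untransformed baseline NLE is
retained as an explanatory variable. For the change table, per-interval
differences are pooled and standardised to mean 0, sd 1; baseline NLE is
dropped so the change in NLE is the only life-event variable.

## Structure learning

Scores are decomposable BIC values in natural logs, higher better:
`logLik(node | parents) − (d/2)·log N`, with
`d = (states−1)·prod(parent states)` for discrete families and
`d = configs·(continuous parents + 2)` for CLG families. Search is Tabu:
single-arc add/delete/reverse moves, a memory of the 10 most recent
moves whose inverses are forbidden (aspiration overrides the memory when
a move beats the incumbent), at most 100 iterations, stopping after 15
non-improving ones. These constants are package defaults — the source
names the algorithm but no parameters — and the optimality tests use a
more generous setting (length 25, 300 iterations, 40 non-improving), as
exact optimality on every instance is only guaranteed in that regime.
Blacklists encode temporal order (no `_2 → _1` arcs), the
independent-to-explanatory restriction, the same-variable persistence
arcs `x_1 → x_2` (deliberately excluded: they dominate the score while
adding no substantive information), named explanatory pairs that would
be nonsensical reversed, and — for the CLG network — every
continuous-to-discrete arc, which the CLG family requires. Whitelists
force the NLE-to-concurrent-injury arcs, which theory expects but the
data alone do not select.

Model averaging follows the bootstrap: R = 1,000 row resamples by
default (reduced and stated where tests need speed), a Tabu search on
each, arc strength = fraction of models containing the arc in either
direction, direction = fraction of those in the canonical orientation.
Arcs with strength ≥ 0.3 are retained (a `strict` flag gives `>`, since
the original threshold's openness is unstated), labelled significant
above 0.5. If the thresholded arcs contain a cycle — a case the source
never addresses — the weakest arc on a cycle is dropped iteratively;
orientation ties (direction exactly 0.5) are broken toward acyclicity,
else lexicographically. Bootstrap resampling is by table row; a
participant-level option exists because the resampling unit is unstated.

## Inference

Conditional probability queries use likelihood weighting: ancestral
sampling with evidence nodes clamped, each sample weighted by the
product of the clamped nodes' conditional probabilities (Gaussian
densities for continuous evidence — the source does not describe its
handling of continuous evidence, so density weighting is the documented
choice). Estimates carry a Monte-Carlo standard error and effective
sample size; an exact enumeration oracle covers small discrete networks
in the tests. Markov blankets (parents, children, co-parents) drive the
query tables: every combination of blanket states, with continuous
variables at −1 SD / mean / +1 SD of the standardised change (values
−1, 0, +1). The regression stage draws joint samples of the BIS, HRV and
FFFS changes from the fitted network and fits
`FFFS ~ BIS + HRV + BIS:HRV` by a normal–inverse-gamma Gibbs sampler
with independent normal(0, 5²) priors on all coefficients (the published
prior), 4,000 retained draws.

## The synthetic cohort

The generator is the package's stated world: 351 recruited athletes, 94
lost after the first occasion, and — forced by the published total of
650 measurement sessions and its missingness arithmetic (31/650 = 4.77%,
70/650 = 10.77%) — 121 retained participants stopping after T2 and 136
completing all three occasions. Demographics follow the published
margins (120/231 female/male, 46% previously injured); continuous
measures are first-order autoregressive around profile means whose
values sit inside the published Low/High spans (total stiffness around
2,150–2,400 N/m, ln RMSSD around 4.0, balance totals around 16);
life-event counts are negative-binomial with roughly a quarter zeros in
the 4-month windows, matching the reported 26%. Injury per reporting
interval is logistic in the standardised stiffness change, NLE change
and stiffness level — the study's headline associations — scaled by a
single `effect_scale` (0 gives exact independence). The per-interval
base rate 0.216 is solved so the expected any-injury share of retained
participants is the published 46% under the default retention pattern.
The remote final report is collected from every retained participant and
reuses the last observed change, since nothing is said about how the
remote interval differs.

What the generator does **not** emulate: seasonality and periodised
training, injury severity and duration, informative dropout, reporting
error differences between in-person and remote occasions, and item-level
questionnaire structure. A green end-to-end test therefore establishes
that the pipeline recovers the dependencies this world contains — not
that the study's exact published strengths or BIC values are reproduced;
those depend on the study's seeded imputation of its own cohort and are
documented as non-reproducible targets.

## What the recovery benchmarks mean

The structure-recovery tests sample 6-node binary ground truths with
in-degree at most 2, about four arcs on average, and monotone logistic
conditionals shifting the log-odds by ±2 per parent, centred so no
configuration saturates. This is the operational meaning of "strong,
recoverable effects": denser graphs are *not* merely harder — they can
be unidentifiable in principle, because explaining-away can make a true
arc conditionally so weak that the BIC optimum at n = 5,000 genuinely
excludes it (we observed true graphs scoring 12 BIC points below the
learned optimum in dense draws), and saturated logistic families bury
their weakest parent regardless of sample size. Even in the sparse
world, one benchmark shortfall remains and is reported rather than
hidden: bootstrap averaging learns a Markov-equivalence class per
resample, and when a resample's best class misorients a collider, the
spouses acquire a moralisation arc; such false arcs reach 30–50%
bootstrap frequency in a minority of seeds, which is why the
false-arc-below-0.3 criterion fails on about 3 seeds in 20. This is an
intrinsic property of arc-frequency model averaging, not of this
implementation.

## Numerical choices and degenerate inputs

CPT smoothing defaults to a pseudo-count of 1 so likelihood weighting
never divides by zero; raw maximum likelihood (`smoothing = 0`) errors
on unobserved parent configurations. CLG configurations with too few
rows to fit fall back to the pooled fit with a floor on the residual sd.
A median split on constant data, an all-missing imputation column, a
zero-probability evidence set, and an all-rejected IBI recording are
errors, not silent results. All randomness flows from a single seed
through a deterministic child-seed map, so stages can be re-run
independently yet reproducibly; identical configuration and seed give
bitwise-identical outputs.

## Known limitations

Exact inference is enumeration-only (no junction tree); structure search
is heuristic beyond 4 nodes (with the optimality guarantee tested only
there); the imputer is a single-imputation method with no uncertainty
propagation; and the text's apparent swap of the BIS and HRV regression
coefficients relative to its own table is documented (the table's
assignment is used) but cannot be resolved from the sources.
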