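---
title: "Methods: comparative-risk life-expectancy modelling in lexrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative-risk life-expectancy modelling in lexrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexrisk)
```

## The model in brief

`lexrisk` implements a synthetic (multi-source) comparative risk assessment
model of mortality. Its parameterization has five parts, bundled into a
`parameter_bundle`:

1. **Cause-specific death rates** `m_d(age, sex)` per person-year on an
   abridged age grid (`[0,1)`, `[1,5)`, then 5-year groups to the open-ended
   `[95, Inf)`).
2. **Risk-factor exposure distributions**: a population mean (and optional
   spread) per (factor, sex, age group) for continuous factors, category
   prevalences for categorical ones.
3. **Relative-risk dose-response functions** per (factor, disease, sex, age
   group): log-linear in the distance from the TMREL, interval (piecewise
   log-linear between knots, constant beyond them), or categorical lookup.
4. **Mediation factors** `MF in [0,1]` per (factor, mediator, disease)
   pathway.
5. **Risk-reversal half-lives** per (factor, disease) pair.

A person's profile fixes exposure values (held constant over life unless a
change event is given). The engine normalizes each raw RR by the population
reference so the average person has normalized risk `r = 1`; consequently a
reference profile reproduces the observed life table *exactly*, which is
the model's calibration anchor and is enforced to 1e-9 years in the test
suite.

## Normalization modes

Whether the continuous-factor reference should be the RR at the mean
exposure or the mean of the RR over the exposure distribution is a genuine
modelling choice; the two differ for convex dose-response curves. The
package implements both: `rr_at_mean` (default) evaluates the dose-response
at the cell's mean; `mean_rr` integrates the RR against a normal exposure
distribution with the cell's mean and spread, truncated to the factor's
declared support, to an absolute tolerance of 1e-8 (Gauss–Kronrod
quadrature via `stats::integrate`). Categorical factors always use the
prevalence-weighted mean RR, which makes the expectation of the normalized
risk exactly 1 by construction. The mode used is recorded in every output's
settings fingerprint so results from different modes are never silently
compared.

## Combination, mediation and the additive floor

Per disease the default combination is additive in excess risk,
`R_d = 1 + sum_i (r_i - 1)`, with a multiplicative `prod r_i` option. With
a single deviating factor the two coincide (a tested invariant). Summed
negative excesses can push the additive `R_d` to or below zero, a region
the additive independence model does not meaningfully describe; the engine
floors `R_d` at `rr_floor = 0.05` (configurable) and warns whenever the
floor engages. The floor value is a pragmatic guard — low enough never to
bind in realistic profiles, strictly positive so the life table stays
defined.

Mediation converts total effects into direct effects: the TMREL-relative
excess is scaled by `prod_j (1 - MF_ij,d)` *before* normalization, and the
population reference is computed under the same scaling. Doing both sides
under one mode preserves calibration exactly in either mode, and makes
`MF = 1` on every pathway collapse a factor's direct effect to zero — both
are tested invariants. Following standard practice, single-factor scenarios
(elimination gains, exposure sweeps) report total effects (mediation off),
while multi-factor scenarios apply the mediation adjustment so mediated
effects are not double-counted; `mediation = "auto"` switches on exactly
this rule (off for one explicit factor, on for two or more).

## Life-table construction

The life table is a Chiang-style abridged period table with radix 1:
`q_x = n m_x / (1 + (n - a_x) m_x)`, `a_x = n/2` for closed intervals
except `a_0 = 0.1` years (the standard infant-mortality convention — infant
deaths cluster early in the first year), and terminal group person-years
`L = l/m`. These are the conventional textbook choices; with constant
hazard `m = 0.02` the abridged table reproduces the exponential closed
forms (`e_0 = 1/m` within 0.5%, survival `exp(-mt)` within 0.01, 10-year
death risk `1 - e^{-10m}` within 0.01) and agrees with a single-year-grid
recomputation within 0.2 years — all enforced in the acceptance tests.
Conditional life expectancy is only defined at grid boundaries; the ages of
interest (30/50/70) are boundaries, and refusing within-interval
interpolation keeps results exactly reproducible.

Cause-group death risks over a horizon attribute each interval's deaths to
causes in proportion to the cause's share of the all-cause rate in that
interval; the shares sum to one, so cause-group risks decompose the
all-cause risk exactly (tested to 1e-12).

## The lagged risk-reversal model

After an exposure change at age `A`, the normalized excess risk decays as
`r(t) = r_new + (r_old - r_new) 2^{-(t-A)/h}` with a half-life `h` specific
to each (factor, disease) pair. The decay acts on the normalized-RR scale
(equivalently the excess `r - 1`), the natural scale once rates are
`m * R`. Within the life table the trajectory is evaluated at each age
group's midpoint and held constant within the group, which leaves the
life-table machinery untouched; the terminal group uses a nominal 5-year
width for its midpoint. A pair without a lag entry, or `lag = FALSE`,
switches instantaneously, so the no-lag model is the lag model with an
empty lag table. Two ordering properties follow from the pointwise bounds
`r(t)` between `r_new` and `r_old` and are enforced as tests: for a
beneficial change the lagged gain lies in `[0, no-lag gain]` for every
`h > 0`, and the gap to the no-lag gain grows monotonically with `h`.

## Scenario conventions

* **Elimination gains** set one factor to its TMREL, everything else at the
  population reference, total-effect model; a gain can be negative when the
  TMREL is not population-optimal (protective dose-response segments).
* **Exposure sweeps** hold other factors at reference and report deltas
  against the first (best) level of the sweep.
* **Simultaneous multi-factor changes** compare conditional LE at the
  shared change age with and without the changes, mediation-adjusted.
* **Sequential gains** apply one change at a time, each step's baseline
  being the previous step's profile. Because the final profile is the same
  whatever the order, the final cumulative delta is order-independent
  (tested to 1e-9) and equals the simultaneous delta; *intermediate* steps
  are context-dependent and may differ substantially between orderings.
* **Survival comparisons** return the never-exposed, exposed, and
  with-change curves; the with-change curve is bracketed by the other two
  at every boundary after the change age.

## What the synthetic generator emulates — and what it does not

`generate_bundle()` produces miniature bundles with the full structure of a
real parameterization: a Gompertz all-cause curve `m(age) = A e^{B age}`
(defaults `A = 5e-5`, `B = 0.085`, chosen once to put life expectancy in
the 75–85-year range of high-income countries, with a mild male excess)
split exactly across causes by a Dirichlet draw; harmful-monotone
log-linear continuous factors (TMREL 0, slopes 0.01–0.07 per unit, i.e.
RRs of roughly 1.3–2 at typical exposures); dichotomous factors with
exposed-category RRs of 1.3–2.5 and prevalences of 5–35%; sparse mediation
(density 0.15, MF 0.1–0.6); and half-lives of 2–20 years. Draws use one
seeded generator and the seed is recorded in the manifest, so bundles are
byte-reproducible.

What it does *not* emulate: age- or sex-varying dose-response shapes
(functions are constant across groups), J-shaped or interval dose-response
curves, infant-mortality humps, cohort effects, correlated exposures, or
parameter uncertainty. Passing tests on synthetic bundles therefore
demonstrate the *mechanics* — calibration, normalization, combination,
lag, life-table arithmetic — not the realism of any particular country's
estimates, which depend entirely on the parameter bundle supplied.

The hand-written toy fixture (`generate_toy_fixture()`, also shipped under
`inst/extdata/toy_bundle/`) is built for closed-form checking: its
dichotomous factor (prevalence 0.2, RR 2) has population reference
`0.8 + 0.2 * 2 = 1.2`, so eliminating it must equal substituting
`m/1.2` into the affected cause directly — an oracle the acceptance suite
enforces to 1e-12.

## Numerical choices and degenerate inputs

* Interval dose-response functions interpolate in log-RR (linearity on the
  multiplicative scale) and extrapolate as constants beyond terminal knots,
  so extrapolated risk is bounded.
* Quadrature for `mean_rr` truncates the normal at eight standard
  deviations or the declared support, whichever is tighter, and
  renormalizes by the truncated mass.
* Zero rates are allowed everywhere except the terminal group (its
  person-years `L = l/m` would be undefined); a bundle with an all-zero
  terminal rate is rejected.
* Categorical prevalences must sum to 1 within 1e-9 per cell; generated
  bundles construct them by normalization so they sum exactly.
* Change events are evaluated at group midpoints; a change age beyond the
  terminal group start is rejected.
* Problem sizes throughout the tests are deliberately small — 21 age
  groups, up to 8 diseases and 10 factors, 20-seed property loops — which
  keeps every property check closed-form-verifiable and the whole suite
  fast while exercising all code paths.

## Known limitations

* No statistical interactions between risk factors beyond mediation, and
  no age-trend smoothing of RRs: both are taken as given per age group.
* Period-table interpretation: estimates assume current age/sex-specific
  rates persist; they are not cohort forecasts.
* One change event per factor; no induction/latency period before risk
  starts to reverse.
* No uncertainty intervals: the model is deterministic given its
  parameters.
* Conditional life expectancy only at grid boundaries.
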