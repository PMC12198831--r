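---
title: "Model structure, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crctriage)
```

`crctriage` is an individual patient-level simulation of diagnostic
triage for symptomatic colorectal cancer (CRC): a short-term model of
the referral-and-investigation episode chained to a lifetime
annual-cycle Markov model. This vignette documents the model's
structure, its assumptions and the design decisions that were genuinely
open, in enough detail that a reader can judge what results computed
with the shipped defaults do and do not show.

## The synthetic population

Real triage cohorts are confidential; what is publishable is aggregate
data — per-variable quantile tables and a correlation structure. The
generator treats those aggregates as the ground truth to be emulated.
It samples correlated standard normals from the configured correlation
matrix (a Gaussian copula), converts them to uniform ranks, and
*refits* each variable's ranks onto its quantile grid by monotone
linear interpolation (`apply_quantile_refit()`). Sex enters the same
mechanism as a latent-threshold normal, so one sampler covers all
covariates. Beyond the outermost grid points values are held flat and
clipped to the configured physical bounds — extrapolating a lognormal
tail for FIT would manufacture implausible extreme values the aggregate
data cannot support.

The shipped validation-style and derivation-style configurations are
synthetic stand-ins, not reconstructions: plausible grids for an
English symptomatic FIT cohort (strongly right-skewed FIT with ~19% at
or above 10 µg Hb/g, ages 18–100 with median near 58, 58% female, 91%
with a recent full blood count). The derivation-style cohort is
slightly older with a heavier FIT tail. Any user-supplied YAML
configuration with the same schema replaces them
(`read_population_config()`).

What the generator does *not* emulate: missing blood values,
within-person measurement repeats, regional case-mix differences, and
any covariate the correlation matrix does not name. Tests passing on
these synthetic cohorts therefore validate the *machinery* (marginal
fidelity, rank-correlation fidelity, determinism), not the
representativeness of the default aggregates.

## Risk models and calibration

Both model forms share a linear predictor with per-covariate transforms
(FIT on the `log1p` scale). The Cox form maps it to 1-year risk through
a baseline survival `S₀` at the 1-year horizon, `1 − S₀^exp(lp)`; the
logistic form through the inverse logit. The risk horizon is fixed at
one year because baseline prevalence is calibrated against 1-year
incidence.

The shipped coefficients are hand-set stand-ins (the fitted source
algorithm is not public). Two parameters were calibrated once, with
`calibrate_risk_model()` against a 2-million-person draw of the default
validation-style population, and frozen: the Cox `S₀` and the logistic
intercept, each pinned so mean predicted risk equals the 1.2% 1-year
CRC incidence of the cohort being emulated (the derivation-style
configuration then averages ≈1.5% under the same model). Because CRC
status is allocated *from* these risks, the Cox score is, by
construction, the best possible ranking of the synthetic population —
real-world discrimination of any fitted score will be lower, so
score-versus-FIT comparisons on the defaults are upper bounds on the
score's advantage.

One practical consequence: the stand-in score's probability scale is
not the source algorithm's, so a given nominal threshold (say 0.64%)
refers a different fraction of patients than the published algorithm
would. Cross-arm comparisons in the examples are therefore made at
detection-matched thresholds (equal cancers detected at USC), which is
how the published threshold pairings were constructed in the first
place.

## Disease allocation

Each person carries one mutually exclusive colorectal state — CRC
(stage I–IV), high-risk adenoma, low-risk adenoma or normal — plus an
independent IBD flag. CRC is a Bernoulli draw at
`prevalence_scaling × risk` (scaling defaults to 1 and exists so
user-supplied risk models can be rescaled to a target prevalence);
stage is drawn from a configurable baseline stage distribution.
High-risk adenomas are allocated within FIT strata (≥10 / <10) at
stratum prevalences, weighted within the stratum proportionally to the
risk score — the source describes score-based allocation without a
formula, and proportional weighting is the least-structured choice that
preserves the stratum totals. Low-risk adenomas are uniform; IBD rates
come from a decade-of-age × FIT-stratum table, declining with age and
much higher above FIT 10.

## The short-term diagnostic model

Everyone pays the GP appointment and FIT. Score strategies additionally
pay the £0.01 algorithm cost for all, and the £8.38 blood count for the
9% without a recent one (or for everyone, in the costing scenario).
Referred patients attend with the uptake probability, are assigned CTC
with probability `ctc_fraction` (else colonoscopy), and each present
condition is detected with the investigation's per-condition
sensitivity. CRC that is unreferred, non-attending or missed follows
the delayed route: a personalised delay drawn from a lognormal
truncated to [2 weeks, 2 years] whose location parameter is solved
numerically so the truncated mean equals 3 months (σ = 0.9 by default —
the source states only the mean and range; a lognormal is the
conventional right-skewed waiting-time family). Delayed cases accrue
extra GP contacts, an emergency presentation in a configured fraction,
and — a documented assumption the source leaves open — the definitive
investigation cost at delayed diagnosis. IBD not detected at urgent
investigation is delayed by a fixed 1.34 years. Colonoscopy harm is the
expected complication decrement in the base case and exactly one
QALY-day (1/365.25) per colonoscopy in the harm scenario.

Every person carries one fixed vector of uniform draws (uptake,
investigation assignment, detections, delay, emergency) reused by every
strategy — common random numbers — so a person whose referral status
agrees under two strategies has identical outcomes under both, and
strategy incrementals are paired rather than noisy differences of
independent simulations.

All short-term costs are booked in year 0 undiscounted (delays never
exceed two years and the discounting error on these small amounts is
below other structural uncertainty).

## The lifetime model

Per-person traces are **expected-value** (fractional state occupancy),
not Monte-Carlo walks: randomness is confined to the population,
allocation and pathway, which makes deterministic analyses exactly
reproducible and defines CRC deaths as expectations. Cycles are annual
from baseline age to an absorbing cap at 100, accruals at cycle start,
no half-cycle correction, year-0 accruals undiscounted
(`discount()` divides by `(1+r)^⌊t⌋`).

Stage shift during delay is continuous-time: each annual progression
probability `p` becomes a rate `λ = −ln(1−p)` and the I→II→III→IV chain
is exposed for the exact delay duration (closed-form solution of the
sequential first-order chain; cross-checked in the tests against a
matrix-exponential and a Monte-Carlo oracle). The diagnosed trace then
starts at the next cycle boundary: the person spends the whole pre-
diagnosis cycles at general-population utility with life-table
mortality only — CRC death before diagnosis is not modelled, a
simplification consistent with delays of at most two years.

After diagnosis, annual CRC death probabilities are looked up by stage,
sex, age band *at diagnosis* and year since diagnosis (1–10; later
years reuse the year-10 row, the usual registry-table convention),
competing with life-table mortality (CRC death is applied first within
a cycle). Utilities are general-population values by age band and sex
times a stage×phase multiplier; costs accrue by stage and phase
(first year, subsequent, terminal — the terminal cost attaches to the
CRC-death increment of each cycle). All tables are labelled synthetic
stand-ins shaped like English registry and national life-table data,
replaceable via `read_survival_table()` / `read_life_table()`.

Adenoma and IBD consequences exist in the state space but are inert in
the base case; the corresponding scenarios switch them on. Undetected
high-risk adenomas then progress annually toward stage-I CRC (diagnosed
at incidence — a generous assumption that, if anything, understates the
benefit of removal); detected ones are removed. IBD cases receive a
chronic annual cost and utility multiplier, with the complicated course
for delayed cases — modelled as a lifetime stream rather than a one-off
penalty, weighted by all-cause survival only (the CRC interaction is
ignored for this adjustment).

## Economics, scenarios, uncertainty

Outcomes are summed and rescaled by the exact multiplier `scale/n`
after summation (per million by default). INMB is `λ·ΔQ − ΔC` at
£20,000/QALY; ICERs are reported but flagged when the cost and QALY
deltas disagree in sign, where a ratio misleads. Subgroups default to
age <50 / 50–69 / ≥70 by sex; unscaled cell sums reconcile exactly with
the population totals.

Scenarios are pure configuration edits (`apply_scenario()`), asserted
in the tests to touch only their documented fields. The PSA draws beta
distributions for probabilities, gamma for costs and beta for the
transition probabilities (families are a health-economics convention;
the source does not specify them), redraws a fresh population per run
at a run-indexed seed — population sampling is part of the uncertainty —
and evaluates all strategies per run with common random numbers.
Credible intervals use linearly interpolated order statistics
(quantile type 7), pinned for test determinism. With all-fixed
distributions the PSA collapses exactly to the deterministic run at the
derived seed.

## Problem sizes and numerical choices

The reference analysis sizes are 2 million patients deterministic and
500 runs × 100,000 patients probabilistic. The package's own test suite
and examples run the identical code at reduced sizes chosen for quick
iteration — 10⁵–10⁶ for distributional calibration checks (binomial
3-SD tolerances), a few thousand patients for pipeline properties, and
small PSA grids for the uncertainty machinery — since the expected-value
lifetime traces make per-person results independent of cohort size
except through sampling noise. Equal transition rates in the stage
chain are separated by a 10⁻¹⁰ nudge (the closed form requires distinct
rates); delays of exactly zero are the identity; empty strata and
uncovered table keys raise explicit errors naming the key.

## Known limitations

Endoscopy capacity and queueing are not modelled; CRC recurrence and
within-stage progression are absent; adenoma/IBD scenario parameters
are weakly informed; the defaults' absolute cost and QALY magnitudes
carry no evidential weight — directions, orderings and identities are
the tested claims, and headline-scale reproduction requires the
confidential source aggregates, coefficients and calibrated tables,
loaded through the structured-text interfaces.
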