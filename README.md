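# crctriage

Individual patient-level simulation for the health economics of
colorectal cancer (CRC) triage in symptomatic primary care.

In England, patients presenting to their GP with bowel symptoms are
offered a faecal immunochemical test (FIT), and those at or above
10 µg Hb/g faeces are referred on the urgent-suspected-cancer (USC)
pathway for colonoscopy or CT colonography. Multivariable risk scores
that combine the FIT value with age, sex and full-blood-count analytes
can detect the same number of cancers with fewer referrals. Whether such
a score is *worth using* is an economic question: referrals saved are
mostly in younger, lower-risk patients, and the few cancers among them
are then diagnosed late, losing quality-adjusted life years (QALYs) in
exactly the group with most life expectancy at stake.

`crctriage` makes that trade-off computable end to end:

- **Synthetic populations** — a Gaussian copula over age, sex, FIT and
  blood-count analytes, with each marginal refitted onto a published
  quantile grid (aggregate data in, correlated patient records out).
- **Risk stratification** — pluggable Cox-form
  (`risk = 1 − S₀^exp(βᵀx)`) or logistic-form 1-year CRC risk models,
  and referral rules at any FIT or risk threshold (inclusive `≥`).
- **Disease allocation** — CRC (stage I–IV) assigned randomly from each
  person's risk (baseline prevalence 1.2% in the validation-style
  cohort, 1.5% derivation-style), high/low-risk adenomas by FIT stratum,
  IBD by age band and FIT.
- **Short-term diagnostic model** — referral uptake, colonoscopy/CTC
  assignment and sensitivity, personalised diagnostic delay (truncated
  lognormal, mean 3 months, 2 weeks–2 years), emergency presentations,
  and all testing costs (including the £8.38 blood count and £0.01
  algorithm cost in the score arm).
- **Lifetime Markov model** — annual cycles to age 100; stage shift
  during delay via continuous-time exposure of the I→II→III→IV chain
  (`λ = −ln(1−p)`); CRC mortality by stage, sex, age band and time
  since diagnosis competing with life-table mortality; utilities and
  costs by stage and phase; discounting at 3.5%.
- **Economics** — per-million strategy outcomes, pairwise incrementals
  and `INMB = λ·ΔQALY − ΔCost` at £20,000/QALY, subgroup results,
  threshold sweeps.
- **Uncertainty** — scenario analyses (adenoma/IBD consequences,
  derivation cohort, logistic model, colonoscopy harm, faster
  progression, doubled delay, discount rates, extra testing costs) and
  probabilistic sensitivity analysis with CEACs and credible intervals.

The quantile grids, correlation matrix, risk-model coefficients and
natural-history tables shipped as defaults are clearly-labelled
synthetic stand-ins with realistic shapes; every one of them can be
replaced from structured-text files (YAML/CSV) via the `read_*`
loaders.

## Worked example

Compare FIT 10 against the risk score at a detection-matched threshold
(the shipped stand-in score's probability scale differs from the source
algorithm's, so thresholds are matched on cancers detected, as the
threshold comparisons are constructed in practice):

```r
library(crctriage)

cfg <- run_config(
  n = 50000, seed = 42,
  strategies = list(strategy("refer_all"), strategy("fit", 10),
                    strategy("cox", 0.0129, label = "risk score (matched)")))
res <- run_analysis(cfg)
res$outcomes[, c("strategy", "cost", "qaly", "crc_deaths",
                 "usc_referrals", "usc_crc_diagnoses")]
#>               strategy       cost     qaly crc_deaths usc_referrals usc_crc_diagnoses
#> 1            refer all 1141477333 15991800    6378.68       1000000             11160
#> 2               FIT 10  697046565 15991805    6421.52        193200              9020
#> 3 risk score (matched)  666195023 15991578    6431.53        134900              9040

incremental(res$outcomes[3, ], res$outcomes[2, ], cfg$econ)[
  , c("comparison", "delta_cost", "delta_qaly", "delta_usc_referrals", "inmb")]
#>                       comparison delta_cost delta_qaly delta_usc_referrals     inmb
#> 1 risk score (matched) vs FIT 10  -30851542     -227.2              -58300 26308248
```

All quantities are per million patients. The score detects slightly
more cancers at USC than FIT 10 (9,040 vs 9,020) with 58,300 fewer
urgent referrals, saving £30.9m; 227 QALYs are lost because the
expedited diagnoses shift from younger to older patients, but at
£20,000/QALY the net monetary benefit is +£26.3m per million patients —
the qualitative result that makes risk-score triage a cost-saving
disinvestment with a small, concentrated QALY harm.

Scenario and probabilistic analyses follow the same configuration
object:

```r
res_1b <- run_analysis(apply_scenario(cfg, "1b"))        # adenoma + IBD harm
pr <- run_psa(cfg, psa_config(n_runs = 50, n_patients = 10000, master_seed = 1))
probability_cost_effective(pr, wtp = 20000)
ceac(pr)
```

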