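config_fields <- function(cfg) {
  lapply(cfg, function(x) serialize(x, NULL, version = 2))
}

changed_fields <- function(a, b) {
  fa <- config_fields(a)
  fb <- config_fields(b)
  names(fa)[!mapply(identical, fa, fb)]
}

test_that("scenarios change exactly their documented fields", {
  base <- small_run_config(n = 100, seed = 1)
  expect_identical(apply_scenario(base, "base"), base)
  expect_equal(changed_fields(base, apply_scenario(base, "6a")),
               c("econ", "scenario"))
  expect_equal(apply_scenario(base, "6a")$econ$discount_rate, 0.05)
  expect_equal(apply_scenario(base, "6b")$econ$discount_rate, 0.015)
  expect_equal(changed_fields(base, apply_scenario(base, "2")),
               c("cohort", "scenario"))
  expect_equal(changed_fields(base, apply_scenario(base, "3")),
               c("risk_model_kind", "scenario"))
  expect_equal(changed_fields(base, apply_scenario(base, "7")),
               c("pathway", "scenario"))
  expect_equal(apply_scenario(base, "7")$pathway$fbc_charge_fraction, 1)
  s5a <- apply_scenario(base, "5a")
  expect_equal(changed_fields(base, s5a), c("delay", "scenario"))
  expect_equal(s5a$delay$mean, 0.5)
  expect_equal(s5a$delay$min, base$delay$min)
  expect_equal(s5a$delay$max, base$delay$max)
  s5c <- apply_scenario(base, "5c")
  expect_equal(sort(changed_fields(base, s5c)),
               sort(c("delay", "tables", "scenario")))
  expect_true(s5c$tables$transition$fast_mode)
  expect_equal(s5c$delay$mean, 0.5)
  expect_equal(changed_fields(base, apply_scenario(base, "1a")), "scenario")
  # long aliases accepted
  expect_equal(apply_scenario(base, "6a_discount_5")$econ$discount_rate, 0.05)
  expect_error(apply_scenario(base, "9z"), "unknown scenario")
})

test_that("run_analysis is reproducible and writes a manifest bundle", {
  cfg <- small_run_config(n = 400, seed = 17)
  d1 <- file.path(tempdir(), "runA")
  d2 <- file.path(tempdir(), "runB")
  run_analysis(cfg, out_dir = d1)
  run_analysis(cfg, out_dir = d2)
  for (f in c("strategy_outcomes.csv", "incrementals.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  man <- yaml::read_yaml(file.path(d1, "manifest.yaml"))
  expect_equal(man$seed, 17)
  expect_equal(man$n, 400)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("refer-all refers everyone and dominates USC cancer detection", {
  cfg <- small_run_config(n = 1200, seed = 19)
  res <- run_analysis(cfg)
  o <- res$outcomes
  expect_equal(o$usc_referrals[o$strategy == "refer all"], 1e6)
  expect_true(all(o$usc_crc_diagnoses[o$strategy == "refer all"] >=
                    o$usc_crc_diagnoses))
  expect_true(all(o$usc_crc_diagnoses <= o$usc_referrals))
})

test_that("threshold sweeps are monotone in referrals and anchored at refer-all", {
  cfg <- run_config(n = 1500, seed = 23, strategies = list(strategy("refer_all")))
  sw <- threshold_sweep(cfg, fit_thresholds = c(10, 40, 150),
                        risk_thresholds = c(0.005, 0.02, 0.08))
  expect_equal(nrow(sw), 7)
  fit_rows <- sw[grepl("^FIT", sw$strategy), ]
  fit_rows <- fit_rows[order(as.numeric(sub("FIT ", "", fit_rows$strategy))), ]
  expect_true(all(diff(fit_rows$usc_referrals) <= 0))
  # a zero risk threshold refers everyone like refer-all; the rows differ
  # only by the score arm's own testing costs (algorithm + blood counts)
  sw0 <- threshold_sweep(cfg, fit_thresholds = numeric(0),
                         risk_thresholds = 0)
  row0 <- sw0[sw0$strategy != "refer all", ]
  base0 <- sw0[sw0$strategy == "refer all", ]
  expect_equal(row0$usc_referrals, 1e6)
  expect_equal(row0$usc_crc_diagnoses, base0$usc_crc_diagnoses)
  expect_equal(row0$qaly, base0$qaly)
  cohort0 <- simulate_cohort(cfg)
  pp <- pathway_params()
  testing_cost <- (nrow(cohort0$pop$persons) * pp$cost_algorithm +
                     sum(!cohort0$pop$persons$has_recent_fbc) * pp$cost_fbc) *
    1e6 / nrow(cohort0$pop$persons)
  expect_equal(row0$inmb_vs_refer_all, -testing_cost)
  expect_error(threshold_sweep(cfg, numeric(0), numeric(0)), "threshold")
})

test_that("triage economics reproduce the qualitative findings", {
  cfg <- run_config(n = 20000, seed = 29,
                    strategies = list(strategy("refer_all")))
  sw <- threshold_sweep(cfg, fit_thresholds = c(10, 40),
                        risk_thresholds = c(0.0064, 0.03))
  # (i) INMB against refer-all rises with the threshold in both arms
  fit_inmb <- sw$inmb_vs_refer_all[match(c("FIT 10", "FIT 40"), sw$strategy)]
  expect_true(all(fit_inmb > 0))
  expect_gt(fit_inmb[2], fit_inmb[1])
  cox_inmb <- sw$inmb_vs_refer_all[grepl("score", sw$strategy)]
  expect_true(all(cox_inmb > 0))
  # (ii) at matched USC CRC detection the risk score refers fewer people
  cohort <- simulate_cohort(cfg)
  has_crc <- cohort$states$crc_stage != "none"
  fit_ref <- stratify(cohort$pop, strategy("fit", 10))
  target_det <- sum(fit_ref & has_crc)
  tau <- quantile(cohort$risks, 1 - mean(fit_ref))  # equal referral count
  n_ref_score <- sum(cohort$risks >= tau)
  det_score <- sum(cohort$risks >= tau & has_crc)
  expect_gte(det_score, target_det)  # same referrals, more cancers caught
})

test_that("modelling adenoma and IBD consequences can invert the ranking", {
  strategies <- list(strategy("refer_all"), strategy("cox", 0.03))
  base_cfg <- run_config(n = 8000, seed = 31, strategies = strategies)
  base_res <- run_analysis(base_cfg)
  # base case: high-threshold triage beats refer-all
  expect_gt(base_res$incrementals$inmb[1], 0)
  s1b <- apply_scenario(base_cfg, "1b")
  res_1b <- run_analysis(s1b)
  # with missed adenomas and IBD carrying lifetime harm, refer-all gains
  expect_lt(res_1b$incrementals$inmb[1], base_res$incrementals$inmb[1])
  expect_lt(res_1b$incrementals$inmb[1], 0)
})

test_that("configuration files round-trip through the YAML loaders", {
  pc <- default_population_config("validation", n = 1234, seed = 5)
  f <- tempfile(fileext = ".yaml")
  write_population_config(pc, f)
  back <- read_population_config(f)
  expect_equal(back$marginals$fit$values, pc$marginals$fit$values)
  expect_equal(back$correlation, pc$correlation)
  expect_equal(back$n, 1234)
  expect_identical(generate_population(back)$persons,
                   generate_population(pc)$persons)
  unlink(f)
  dv <- prevalence_config(prevalence_scaling = 1.1)
  f2 <- tempfile(fileext = ".yaml")
  write_prevalence_config(dv, f2)
  back2 <- read_prevalence_config(f2)
  expect_equal(back2$crc_stage_distribution, dv$crc_stage_distribution)
  expect_equal(back2$prevalence_scaling, 1.1)
  expect_equal(back2$ibd_prevalence$prob, dv$ibd_prevalence$prob)
  unlink(f2)
})
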