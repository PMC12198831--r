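test_that("personalised delays respect their range and configured mean", {
  dm <- delay_model()
  d <- sample_delay(dm, 1e5, seed = 21)
  expect_true(all(d >= 2 / 52 & d <= 2))
  expect_lt(abs(mean(d) - 0.25), 0.005)
  deg <- delay_model(mean = 0.25, min = 0.25, max = 0.25)
  expect_equal(sample_delay(deg, 10, seed = 1), rep(0.25, 10))
  expect_error(delay_model(mean = 3, min = 0.1, max = 2), "min <= mean")
  # doubled-delay variant keeps the bounds
  dm2 <- delay_model(mean = 0.5)
  d2 <- sample_delay(dm2, 1e5, seed = 22)
  expect_true(all(d2 >= 2 / 52 & d2 <= 2))
  expect_lt(abs(mean(d2) - 0.5), 0.01)
})

test_that("investigation assignment follows the CTC fraction (binomial oracle)", {
  p0 <- pathway_params(ctc_fraction = 0)
  expect_true(all(investigation_assignment(p0, 100, seed = 1) == "colonoscopy"))
  p1 <- pathway_params(ctc_fraction = 1)
  expect_true(all(investigation_assignment(p1, 100, seed = 1) == "ctc"))
  p3 <- pathway_params(ctc_fraction = 0.3)
  n <- 1e5
  share <- sum(investigation_assignment(p3, n, seed = 2) == "ctc")
  expect_lt(abs(share - 0.3 * n), 3 * sqrt(n * 0.3 * 0.7))
})

test_that("colonoscopy harm is a full QALY-day under its scenario", {
  expect_identical(colonoscopy_harm_qaly("4"), 1 / 365.25)
  p0 <- pathway_params(complication_probability = 0)
  expect_equal(colonoscopy_harm_qaly("base", p0), 0)
  p <- pathway_params(complication_probability = 0.25,
                      complication_qaly_loss = 0.02)
  expect_equal(colonoscopy_harm_qaly("base", p), 0.005)
})

path_fixture <- function(n = 400, seed = 31) {
  cfg <- small_run_config(n = n, seed = seed)
  simulate_cohort(cfg)
}

test_that("short-term costs floor at GP + FIT and follow the strategy arm", {
  ch <- path_fixture()
  params <- pathway_params()
  dm <- delay_model()
  n <- nrow(ch$pop$persons)
  none <- rep(FALSE, n)
  d_fit <- run_pathway(ch$pop, ch$states, none, strategy("fit", 10),
                       params, dm, "base", ch$draws)
  # non-referred, CRC-free person pays exactly GP + FIT
  clean <- !d_fit$referred & ch$states$crc_stage == "none"
  expect_true(all(d_fit$short_term_cost[clean] ==
                    params$cost_gp_appointment + params$cost_fit))
  d_cox <- run_pathway(ch$pop, ch$states, none, strategy("cox", 0.01),
                       params, dm, "base", ch$draws)
  expect_true(all(d_cox$short_term_cost >=
                    params$cost_gp_appointment + params$cost_fit))
  # score arm adds exactly the algorithm cost plus FBC for those lacking one
  lacking <- sum(!ch$pop$persons$has_recent_fbc)
  expect_equal(sum(d_cox$short_term_cost) - sum(d_fit$short_term_cost),
               n * params$cost_algorithm + lacking * params$cost_fbc)
  # a person without a recent blood count is charged 8.38 and 0.01
  i <- which(!ch$pop$persons$has_recent_fbc & clean)[1]
  expect_equal(d_cox$short_term_cost[i],
               params$cost_gp_appointment + params$cost_fit + 8.38 + 0.01)
  # full-charge scenario bills every score-arm patient
  p7 <- params
  p7$fbc_charge_fraction <- 1
  d7 <- run_pathway(ch$pop, ch$states, none, strategy("cox", 0.01),
                    p7, dm, "base", ch$draws)
  expect_equal(sum(d7$short_term_cost) - sum(d_fit$short_term_cost),
               n * (params$cost_algorithm + params$cost_fbc))
})

test_that("perfect detection recovers every baseline CRC case with zero delay", {
  ch <- path_fixture(n = 600, seed = 33)
  params <- pathway_params(uptake_probability = 1,
                           colonoscopy_sensitivity = c(crc = 1, adenoma = 1, ibd = 1),
                           ctc_sensitivity = c(crc = 1, adenoma = 1, ibd = 1))
  referred <- rep(TRUE, 600)
  d <- run_pathway(ch$pop, ch$states, referred, strategy("refer_all"),
                   params, delay_model(), "base", ch$draws)
  has_crc <- ch$states$crc_stage != "none"
  expect_equal(sum(d$crc_detected_usc), sum(has_crc))
  expect_true(all(d$crc_diagnosis_delay[has_crc] == 0))
  expect_true(all(d$crc_detected_usc[d$crc_detected_usc] %in% TRUE &
                    d$attended[d$crc_detected_usc]))
})

test_that("undetected disease is delayed within bounds; IBD gets its fixed delay", {
  ch <- path_fixture(n = 800, seed = 35)
  d <- run_pathway(ch$pop, ch$states, rep(FALSE, 800), strategy("fit", 10),
                   pathway_params(), delay_model(), "base", ch$draws)
  delayed <- ch$states$crc_stage != "none"
  expect_true(all(d$crc_diagnosis_delay[delayed] >= 2 / 52 &
                    d$crc_diagnosis_delay[delayed] <= 2))
  expect_true(all(d$crc_diagnosis_delay[!delayed] == 0))
  expect_true(all(d$ibd_diagnosis_delay[ch$states$ibd] == 1.34))
})

test_that("common random numbers pair outcomes across strategies", {
  ch <- path_fixture(n = 500, seed = 37)
  dm <- delay_model()
  params <- pathway_params()
  ref_a <- stratify(ch$pop, strategy("fit", 10))
  ref_b <- stratify(ch$pop, strategy("fit", 28))
  d_a <- run_pathway(ch$pop, ch$states, ref_a, strategy("fit", 10),
                     params, dm, "base", ch$draws)
  d_b <- run_pathway(ch$pop, ch$states, ref_b, strategy("fit", 28),
                     params, dm, "base", ch$draws)
  same <- ref_a == ref_b
  cols <- c("attended", "investigation", "crc_detected_usc",
            "crc_diagnosis_delay", "short_term_cost")
  expect_identical(d_a[same, cols], d_b[same, cols])
})
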