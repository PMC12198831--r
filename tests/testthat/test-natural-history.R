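test_that("discounting follows the annual closed form", {
  expect_equal(discount(100, 5, 0), 100)
  expect_equal(discount(100, 1, 0.035), 100 / 1.035)
  expect_equal(discount(50, 10, 0.015), 50 / 1.015^10)
  expect_equal(discount(7, 0, 0.2), 7)  # year 0 undiscounted
  expect_error(discount(1, -1, 0.035), ">= 0")
})

test_that("stage shift during delay matches the matrix-exponential oracle", {
  tp <- transition_params(stage_progression = c(I_II = 0.4, II_III = 0.3,
                                                III_IV = 0.2))
  expect_equal(progress_during_delay("II", 0, tp),
               c(I = 0, II = 1, III = 0, IV = 0))
  expect_equal(progress_during_delay("IV", 1.7, tp),
               c(I = 0, II = 0, III = 0, IV = 1))
  # oracle: expm of the generator, independent of the closed-form chain
  lam <- -log(1 - c(0.4, 0.3, 0.2))
  Q <- matrix(0, 4, 4)
  Q[1, 1:2] <- c(-lam[1], lam[1])
  Q[2, 2:3] <- c(-lam[2], lam[2])
  Q[3, 3:4] <- c(-lam[3], lam[3])
  for (d in c(0.25, 1, 1.9)) {
    P <- as.matrix(Matrix::expm(Q * d))
    for (s in 1:3) {
      got <- progress_during_delay(c("I", "II", "III")[s], d, tp)
      expect_equal(unname(got), P[s, ], tolerance = 1e-7)
    }
  }
})

test_that("stage shift matches a Monte-Carlo exposure oracle", {
  tp <- transition_params(stage_progression = c(I_II = 0.4, II_III = 0.3,
                                                III_IV = 0.2))
  lam <- -log(1 - c(0.4, 0.3, 0.2))
  set.seed(77)
  n <- 1e5
  # simulate sequential exponential sojourns from stage I over delay 1
  t1 <- rexp(n, lam[1])
  t2 <- rexp(n, lam[2])
  t3 <- rexp(n, lam[3])
  stage <- 1 + (t1 < 1) + (t1 + t2 < 1) + (t1 + t2 + t3 < 1)
  mc <- tabulate(stage, 4) / n
  got <- progress_during_delay("I", 1, tp)
  for (s in 1:4) {
    se <- sqrt(mc[s] * (1 - mc[s]) / n)
    expect_lt(abs(got[[s]] - mc[s]), 3 * se + 1e-9)
  }
  # sampling mode draws from the same distribution
  draws <- replicate(2000, progress_during_delay("I", 1, tp, mode = "sample",
                                                 seed = sample.int(1e6, 1)))
  expect_lt(abs(mean(draws == "I") - got[["I"]]), 0.05)
})

test_that("negative delay and unknown stage are rejected", {
  tp <- transition_params()
  expect_error(progress_during_delay("I", -0.1, tp), ">= 0")
  expect_error(progress_during_delay("V", 1, tp), "unknown stage")
})

test_that("a disease-free immortal person accrues closed-form LY and QALYs", {
  tb <- immortal_tables()
  econ0 <- economics_config(discount_rate = 0)
  person <- data.frame(id = 1, age = 60, sex = "F")
  res <- run_lifecourse(person, blank_state(), blank_diag(), tb, econ0)
  expect_equal(res$discounted_ly, 40)
  expect_equal(res$discounted_qaly, 40)
  r <- 0.035
  econ <- economics_config(discount_rate = r)
  res_d <- run_lifecourse(person, blank_state(), blank_diag(), tb, econ)
  expect_equal(res_d$discounted_qaly, sum(1 / (1 + r)^(0:39)))
  expect_equal(res_d$undiscounted_qaly, 40)
})

test_that("occupancy is conserved at every cycle of the CRC trace", {
  tb <- markov_tables()
  for (case in list(c(55, "M", "III"), c(42, "F", "I"), c(80, "M", "IV"))) {
    tr <- crc_occupancy_trace(as.numeric(case[1]), case[2], case[3], tb)
    total <- tr$alive_start + c(0, cumsum(tr$die_crc + tr$die_other))[seq_len(nrow(tr))]
    expect_true(all(abs(total - 1) < 1e-9))
    expect_true(all(tr$die_crc >= 0 & tr$die_other >= 0))
  }
})

test_that("QALYs never exceed life years and both are non-negative", {
  tb <- markov_tables()
  econ <- economics_config()
  set.seed(55)
  for (i in 1:25) {
    person <- data.frame(id = i, age = runif(1, 18, 95),
                         sex = sample(c("F", "M"), 1))
    st <- blank_state(crc_stage = sample(c("none", "I", "II", "III", "IV"), 1))
    dg <- blank_diag()
    if (st$crc_stage != "none") dg$crc_diagnosis_delay <- runif(1, 0, 2)
    res <- run_lifecourse(person, st, dg, tb, econ)
    expect_lte(res$discounted_qaly, res$discounted_ly + 1e-9)
    expect_gte(res$discounted_qaly, 0)
    expect_lte(res$discounted_cost, res$undiscounted_cost + 1e-9)
    expect_lte(res$discounted_ly, res$undiscounted_ly + 1e-9)
  }
})

test_that("longer delays never gain QALYs and never lose CRC deaths", {
  tb <- markov_tables()
  econ <- economics_config()
  person <- data.frame(id = 1, age = 45, sex = "M")
  st <- blank_state(crc_stage = "II")
  prev_q <- Inf
  prev_d <- -Inf
  for (delay in c(0, 0.5, 1, 2)) {
    dg <- blank_diag()
    dg$crc_detected_usc <- delay == 0
    dg$crc_diagnosis_delay <- delay
    res <- run_lifecourse(person, st, dg, tb, econ)
    expect_lte(res$discounted_qaly, prev_q + 1e-9)
    expect_gte(res$crc_death_probability, prev_d - 1e-9)
    prev_q <- res$discounted_qaly
    prev_d <- res$crc_death_probability
  }
})

test_that("fast-transition mode worsens delayed outcomes in every age band", {
  econ <- economics_config()
  for (age in c(40, 60, 80)) {
    person <- data.frame(id = 1, age = age, sex = "F")
    st <- blank_state(crc_stage = "I")
    dg <- blank_diag()
    dg$crc_diagnosis_delay <- 1
    base_tb <- markov_tables()
    fast_tb <- markov_tables()
    fast_tb$transition$fast_mode <- TRUE
    q_base <- run_lifecourse(person, st, dg, base_tb, econ)$discounted_qaly
    q_fast <- run_lifecourse(person, st, dg, fast_tb, econ)$discounted_qaly
    dg0 <- blank_diag()
    dg0$crc_detected_usc <- TRUE
    q_im_b <- run_lifecourse(person, st, dg0, base_tb, econ)$discounted_qaly
    q_im_f <- run_lifecourse(person, st, dg0, fast_tb, econ)$discounted_qaly
    expect_gte((q_im_f - q_fast) + 1e-9, q_im_b - q_base)
  }
})

test_that("IBD adjustments are inert off-scenario and hand-computable on", {
  tb <- toy_tables()
  econ0 <- economics_config(discount_rate = 0)
  person <- data.frame(id = 1, age = 98, sex = "F")
  dg <- blank_diag()
  dg$ibd_detected_usc <- FALSE
  off <- ibd_lifecourse_adjustment(person, dg, tb, econ0, "base")
  expect_equal(off$discounted_cost, 0)
  expect_equal(off$discounted_qaly, 0)
  # hand: 2 cycles (ages 98, 99), all-cause survival 1, 0.9;
  # complicated course: cost 3500/yr, utility delta 0.8 * (0.85 - 1)
  on <- ibd_lifecourse_adjustment(person, dg, tb, econ0, "1b")
  expect_equal(on$discounted_cost, 3500 * (1 + 0.9))
  expect_equal(on$discounted_qaly, 0.8 * (0.85 - 1) * (1 + 0.9))
  dg2 <- dg
  dg2$ibd_detected_usc <- TRUE
  routine <- ibd_lifecourse_adjustment(person, dg2, tb, econ0, "1b")
  expect_lt(on$discounted_qaly, routine$discounted_qaly)
  expect_gt(on$discounted_cost, routine$discounted_cost)
})

test_that("adenoma progression feeds CRC incidence per the enumeration oracle", {
  econ0 <- economics_config(discount_rate = 0)
  person <- data.frame(id = 1, age = 40, sex = "F")
  # scenario off or detected: zero delta
  tb <- toy_tables()
  off <- adenoma_lifecourse(person, detected = FALSE, "high_risk", tb, econ0,
                            "base")
  expect_equal(off$crc_death_probability, 0)
  det <- adenoma_lifecourse(person, detected = TRUE, "high_risk", tb, econ0,
                            "1a")
  expect_equal(det$discounted_qaly, 0)
  # zero progression: detected and undetected coincide
  tb0 <- toy_tables()
  tb0$transition$adenoma_progression[] <- 0
  same <- adenoma_lifecourse(person, detected = FALSE, "high_risk", tb0,
                             econ0, "1a")
  expect_equal(same$discounted_qaly, 0, tolerance = 1e-12)
  expect_equal(same$crc_death_probability, 0)
  # enumeration: lethal stage I, deathless background, 2 usable cycles
  # of progression at p => incidence 1 - (1-p)^2 registered as CRC death
  p <- 0.3
  life0 <- expand.grid(age = 0:100, sex = c("F", "M"), stringsAsFactors = FALSE)
  life0$annual_death_prob <- ifelse(life0$age == 100, 1, 0)
  surv1 <- expand.grid(stage = c("I", "II", "III", "IV"), sex = c("F", "M"),
                       age_band = c("18-49", "50-69", "70+"),
                       year_since_dx = 1:10, stringsAsFactors = FALSE)
  surv1$annual_death_prob <- 1
  tb1 <- markov_tables(
    transition = transition_params(adenoma_progression = c(low_high = 0,
                                                           high_crc = p)),
    survival = surv1, life = life0,
    utility_cost = default_utility_cost_table())
  person97 <- data.frame(id = 1, age = 96, sex = "F")
  res <- adenoma_lifecourse(person97, detected = FALSE, "high_risk", tb1,
                            econ0, "1a")
  # incidence in cycles 1-3 is diagnosed at ages 97-99 (< 100) with
  # certain CRC death; cycle-4 incidence would be diagnosed at the age cap
  expect_equal(res$crc_death_probability, 1 - (1 - p)^3, tolerance = 1e-9)
})
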