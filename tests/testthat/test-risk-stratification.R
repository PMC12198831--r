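toy_person <- data.frame(id = 1, age = 60, sex = "M", fit = 20,
                         haemoglobin = 130, mcv = 88, platelets = 300,
                         has_recent_fbc = TRUE)

test_that("linear predictor matches hand arithmetic with transforms", {
  m <- cox_risk_model(c(fit = 0.5, age = 0.02, sex = 1),
                      transforms = c(fit = "log1p"),
                      baseline_survival_at_horizon = 0.99)
  # hand: 0.5*log1p(20) + 0.02*60 + 1*1
  expect_equal(linear_predictor(m, toy_person),
               0.5 * log1p(20) + 1.2 + 1)
  m0 <- cox_risk_model(c(fit = 0, age = 0), baseline_survival_at_horizon = 0.9)
  expect_equal(linear_predictor(m0, toy_person), 0)
  m1 <- cox_risk_model(c(age = 0.5), baseline_survival_at_horizon = 0.9)
  expect_equal(linear_predictor(m1, data.frame(age = 2)), 1.0)
  expect_error(linear_predictor(m, data.frame(age = 60, sex = "M")),
               "fit")
})

test_that("piecewise-linear transforms interpolate between knots", {
  m <- cox_risk_model(c(age = 1), baseline_survival_at_horizon = 0.99,
                      transforms = c(age = "pw_linear"),
                      transform_args = list(age = list(knots = list(c(40, 0), c(60, 1)))))
  expect_equal(linear_predictor(m, data.frame(age = 50)), 0.5)
  expect_equal(linear_predictor(m, data.frame(age = 20)), 0)  # flat beyond knots
})

test_that("Cox risk follows the closed form 1 - S0^exp(lp)", {
  base <- cox_risk_model(c(age = 0), baseline_survival_at_horizon = 0.988)
  expect_equal(cox_risk(base, toy_person), 0.012)
  none <- cox_risk_model(c(age = 0), baseline_survival_at_horizon = 1)
  expect_equal(cox_risk(none, toy_person), 0)
  m <- cox_risk_model(c(age = log(2)), baseline_survival_at_horizon = 0.988)
  expect_equal(cox_risk(m, data.frame(age = 1)), 1 - 0.988^2)
  expect_error(cox_risk_model(c(age = 0), baseline_survival_at_horizon = 0),
               "0, 1")
})

test_that("logistic risk follows the inverse-logit closed form", {
  m <- logistic_risk_model(0, c(age = 0))
  expect_equal(logistic_risk(m, toy_person), 0.5)
  m2 <- logistic_risk_model(-4.6, c(age = 0.2))
  expect_equal(logistic_risk(m2, data.frame(age = 1)),
               plogis(-4.4), tolerance = 1e-12)
  m3 <- logistic_risk_model(-100, c(age = 0))
  expect_lt(logistic_risk(m3, toy_person), 1e-20)
})

test_that("risk is monotone in covariates per coefficient sign and bounded", {
  m <- default_cox_model()
  lo <- toy_person
  hi <- toy_person
  hi$fit <- 400
  expect_gt(cox_risk(m, hi), cox_risk(m, lo))
  hi2 <- toy_person
  hi2$haemoglobin <- 90  # negative coefficient: lower Hb, higher risk
  expect_gt(cox_risk(m, hi2), cox_risk(m, toy_person))
  pop <- generate_population(default_population_config(n = 2000, seed = 2))
  r <- cox_risk(m, pop$persons)
  expect_true(all(r >= 0 & r < 1))
})

test_that("stratification uses an inclusive threshold and supports all kinds", {
  pop <- structure(list(persons = data.frame(
    id = 1:3, age = c(50, 60, 70), sex = "F",
    fit = c(9.9, 10.0, 250), has_recent_fbc = TRUE)), class = "population")
  expect_equal(stratify(pop, strategy("fit", 10)), c(FALSE, TRUE, TRUE))
  expect_equal(stratify(pop, strategy("refer_all")), rep(TRUE, 3))
  expect_equal(stratify(pop, strategy("cox", 0.0064),
                        risks = c(0.001, 0.0064, 0.05)),
               c(FALSE, TRUE, TRUE))
  expect_error(stratify(pop, strategy("cox", 0.01)), "risk model")
})

test_that("referral sets are nested as the threshold rises", {
  pop <- generate_population(default_population_config(n = 5000, seed = 9))
  risks <- cox_risk(default_cox_model(), pop$persons)
  prev_fit <- prev_cox <- NULL
  for (tau in c(2, 10, 40, 150)) {
    ref <- stratify(pop, strategy("fit", tau))
    if (!is.null(prev_fit)) expect_true(all(!ref | prev_fit))
    prev_fit <- ref
  }
  for (tau in c(0.005, 0.01, 0.03, 0.08)) {
    ref <- stratify(pop, strategy("cox", tau), risks = risks)
    if (!is.null(prev_cox)) expect_true(all(!ref | prev_cox))
    prev_cox <- ref
  }
})

test_that("performance summary counts referrals, sensitivity and specificity", {
  flags <- c(TRUE, TRUE, FALSE, FALSE)
  all_ref <- performance_summary(rep(TRUE, 4), flags)
  expect_equal(all_ref$sensitivity, 1)
  expect_equal(all_ref$specificity, 0)
  none <- performance_summary(rep(FALSE, 4), flags)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  split <- performance_summary(c(TRUE, FALSE, TRUE, FALSE), flags)
  expect_equal(split$sensitivity, 0.5)
  expect_equal(split$ppv, 0.5)
  expect_error(performance_summary(TRUE, flags), "length")
})

test_that("risk model files round-trip through the YAML loader", {
  m <- default_cox_model()
  f <- tempfile(fileext = ".yaml")
  write_risk_model(m, f)
  back <- read_risk_model(f)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$baseline_survival_at_horizon,
               m$baseline_survival_at_horizon)
  expect_equal(cox_risk(back, toy_person), cox_risk(m, toy_person))
  unlink(f)
  ml <- default_logistic_model()
  f2 <- tempfile(fileext = ".yaml")
  write_risk_model(ml, f2)
  expect_equal(logistic_risk(read_risk_model(f2), toy_person),
               logistic_risk(ml, toy_person))
  unlink(f2)
})

test_that("calibration pins mean predicted risk to its target", {
  pop <- generate_population(default_population_config(n = 20000, seed = 4))
  m <- calibrate_risk_model(default_cox_model(), pop, 0.02)
  expect_equal(mean(cox_risk(m, pop$persons)), 0.02, tolerance = 1e-8)
  ml <- calibrate_risk_model(default_logistic_model(), pop, 0.015)
  expect_equal(mean(logistic_risk(ml, pop$persons)), 0.015, tolerance = 1e-8)
})
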