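# Default configurations.
#
# The aggregate quantile grids, correlation matrix, risk-model coefficients
# and prevalence tables shipped here are SYNTHETIC STAND-INS: plausible
# values for an English symptomatic primary-care FIT population, chosen to
# reproduce the headline calibration targets (1-year CRC prevalence 1.2%
# in the validation-style cohort, 1.5% in the derivation-style cohort,
# 91% with a recent full blood count, strongly right-skewed FIT). They are
# not the confidential source aggregates; every loader accepts user files
# with the same structure so real tables can be substituted.

default_marginals <- function(cohort = c("validation", "derivation")) {
  cohort <- match.arg(cohort)
  # derivation-style cohort is slightly older with a heavier FIT tail,
  # which raises its model-based 1-year CRC risk to ~1.5%
  age_vals <- if (cohort == "validation")
    c(18, 26, 35, 45, 58, 70, 78, 86, 93, 100)
  else c(18, 28.5, 38.5, 48.5, 61.5, 72.5, 80, 87.5, 94, 100)
  fit_vals <- if (cohort == "validation")
    c(0, 0, 1.8, 5, 9, 24, 68, 400, 1200, 3000)
  else c(0, 0, 2.1, 6.2, 11.5, 32, 90, 500, 1350, 3000)
  probs10 <- c(0.001, 0.05, 0.25, 0.50, 0.75, 0.90, 0.95, 0.99, 0.999, 1)
  list(
    age = marginal_spec("age", probs10, age_vals,
                        lower_bound = 18, upper_bound = 100),
    sex = marginal_spec("sex", c(0.58, 1), c(0, 1), binary = TRUE),
    fit = marginal_spec("fit", c(0.30, 0.50, 0.70, 0.80, 0.90, 0.95, 0.99, 0.999, 1),
                        fit_vals[-1], transform = "log",
                        lower_bound = 0, upper_bound = 3000),
    haemoglobin = marginal_spec("haemoglobin",
                                c(0.001, 0.01, 0.25, 0.50, 0.75, 0.99, 1),
                                c(60, 95, 127, 137, 147, 172, 195),
                                lower_bound = 50, upper_bound = 200),
    mcv = marginal_spec("mcv", c(0.001, 0.01, 0.25, 0.50, 0.75, 0.99, 1),
                        c(55, 72, 86, 90, 94, 103, 125),
                        lower_bound = 50, upper_bound = 130),
    platelets = marginal_spec("platelets",
                              c(0.001, 0.01, 0.25, 0.50, 0.75, 0.99, 1),
                              c(40, 140, 218, 258, 306, 540, 990),
                              transform = "log",
                              lower_bound = 20, upper_bound = 1200)
  )
}

default_correlation <- function() {
  vars <- c("age", "sex", "fit", "haemoglobin", "mcv", "platelets")
  R <- diag(6)
  dimnames(R) <- list(vars, vars)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("age", "fit", 0.15)
  set_r("age", "haemoglobin", -0.15)
  set_r("age", "mcv", 0.20)
  set_r("age", "platelets", -0.08)
  set_r("sex", "haemoglobin", 0.35)   # 1 = male
  set_r("sex", "platelets", -0.15)
  set_r("sex", "fit", 0.05)
  set_r("fit", "haemoglobin", -0.25)
  set_r("fit", "mcv", -0.15)
  set_r("fit", "platelets", 0.18)
  set_r("haemoglobin", "mcv", 0.30)
  set_r("mcv", "platelets", -0.12)
  R
}

#' Default synthetic population configuration
#'
#' A labelled synthetic stand-in for the aggregate data of the cohorts the
#' model emulates. `"validation"` gives baseline model-based CRC risk
#' averaging ~1.2%; `"derivation"` is older with a heavier FIT tail,
#' averaging ~1.5%.
#'
#' @param cohort `"validation"` (base case) or `"derivation"`.
#' @param n cohort size.
#' @param seed RNG seed.
#' @return a [population_config()].
#' @export
default_population_config <- function(cohort = c("validation", "derivation"),
                                      n = 10000, seed = 1) {
  cohort <- match.arg(cohort)
  population_config(marginals = default_marginals(cohort),
                    correlation = default_correlation(),
                    n = n, seed = seed,
                    recent_fbc_probability = 0.91,
                    cohort_label = cohort)
}
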