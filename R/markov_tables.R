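#' Annual transition parameters for the natural-history model
#'
#' Annual probabilities of CRC stage progression (I to II, II to III, III
#' to IV; stage IV is absorbing) used both for the stage shift during
#' diagnostic delay and for adenoma progression scenarios. `fast_mode`
#' holds the upper-bound probabilities applied by the accelerated-
#' progression scenario; they must dominate the base values.
#'
#' @param stage_progression named vector `c(I_II=, II_III=, III_IV=)`.
#' @param adenoma_progression named vector `c(low_high=, high_crc=)`
#'   (annual probabilities, used only when adenoma scenarios are active).
#' @param fast_stage_progression upper-bound stage probabilities for the
#'   fast-transition scenario.
#' @return an object of class `transition_params`.
#' @export
transition_params <- function(stage_progression = c(I_II = 0.35, II_III = 0.45,
                                                    III_IV = 0.55),
                              adenoma_progression = c(low_high = 0.02,
                                                      high_crc = 0.05),
                              fast_stage_progression = c(I_II = 0.60,
                                                         II_III = 0.70,
                                                         III_IV = 0.80)) {
  assert_prob(stage_progression, "stage_progression")
  assert_prob(adenoma_progression, "adenoma_progression")
  assert_prob(fast_stage_progression, "fast_stage_progression")
  if (any(fast_stage_progression < stage_progression))
    stopf("fast-mode probabilities must be >= base probabilities")
  structure(list(stage_progression = stage_progression,
                 adenoma_progression = adenoma_progression,
                 fast_stage_progression = fast_stage_progression,
                 fast_mode = FALSE),
            class = "transition_params")
}

active_progression <- function(params) {
  if (isTRUE(params$fast_mode)) params$fast_stage_progression
  else params$stage_progression
}

age_band3 <- function(age) {
  cut(age, breaks = c(-Inf, 49, 69, Inf), labels = c("18-49", "50-69", "70+"))
}

#' Default annual CRC survival table (synthetic stand-in)
#'
#' Annual CRC-death probability by stage, sex, age band at diagnosis and
#' year since diagnosis (1-10; later years reuse the year-10 row).
#' Constructed from a first-year probability per stage with geometric
#' decline over follow-up, modest male excess and higher case fatality in
#' the oldest band -- the shape of English stage-specific registry
#' survival, not the registry values themselves.
#'
#' @return data.frame `stage, sex, age_band, year_since_dx,
#'   annual_death_prob`.
#' @export
default_survival_table <- function() {
  q1 <- c(I = 0.02, II = 0.06, III = 0.15, IV = 0.45)
  decay <- c(I = 0.70, II = 0.75, III = 0.85, IV = 0.90)
  age_mult <- c(`18-49` = 0.80, `50-69` = 1.00, `70+` = 1.30)
  sex_mult <- c(F = 1.00, M = 1.10)
  grid <- expand.grid(stage = names(q1), sex = c("F", "M"),
                      age_band = names(age_mult), year_since_dx = 1:10,
                      stringsAsFactors = FALSE)
  grid$annual_death_prob <- pmin(
    q1[grid$stage] * decay[grid$stage]^(grid$year_since_dx - 1) *
      age_mult[grid$age_band] * sex_mult[grid$sex], 0.95)
  grid
}

#' Default all-cause life table (synthetic stand-in)
#'
#' Gompertz-shaped annual death probability by single year of age (0-100)
#' and sex, with `q(100) = 1` by convention (age 100 is absorbing).
#'
#' @return data.frame `age, sex, annual_death_prob`.
#' @export
default_life_table <- function() {
  age <- 0:100
  qf <- pmin(2e-4 * exp(0.088 * pmax(age - 18, 0)) + 2e-4, 0.7)
  qm <- pmin(1.4 * qf, 0.7)
  qf[age == 100] <- 1
  qm[age == 100] <- 1
  rbind(data.frame(age = age, sex = "F", annual_death_prob = qf),
        data.frame(age = age, sex = "M", annual_death_prob = qm))
}

#' Default utility and cost table (synthetic stand-in)
#'
#' General-population utilities by age band and sex; CRC utility
#' multipliers and annual costs by stage and phase (first year after
#' diagnosis, subsequent years, terminal year); IBD annual cost and
#' utility multiplier for routine versus complicated courses. Costs in
#' GBP, 2023 prices.
#'
#' @return an object of class `utility_cost_table`.
#' @export
default_utility_cost_table <- function() {
  structure(list(
    general_utility = matrix(c(0.92, 0.93, 0.85, 0.86, 0.76, 0.78),
                             nrow = 3, byrow = TRUE,
                             dimnames = list(c("18-49", "50-69", "70+"),
                                             c("F", "M"))),
    stage_utility_mult = matrix(c(0.85, 0.95, 0.80, 0.92, 0.72, 0.85, 0.55, 0.60),
                                nrow = 4, byrow = TRUE,
                                dimnames = list(c("I", "II", "III", "IV"),
                                                c("year1", "subsequent"))),
    stage_cost = matrix(c(12000, 1200, 18000, 1600, 26000, 2500, 32000, 9000),
                        nrow = 4, byrow = TRUE,
                        dimnames = list(c("I", "II", "III", "IV"),
                                        c("year1", "subsequent"))),
    terminal_cost = 14000,
    ibd = data.frame(course = c("routine", "complicated"),
                     annual_cost = c(1500, 3500),
                     utility_mult = c(0.92, 0.85))
  ), class = "utility_cost_table")
}

#' Bundle the lifetime-model tables
#'
#' Validates and pre-indexes the transition parameters, CRC survival
#' table, life table and utility/cost table into the fast lookup
#' structures used by the trace engine.
#'
#' @param transition a [transition_params()].
#' @param survival a survival data.frame as from
#'   [default_survival_table()] (or [read_survival_table()]).
#' @param life a life-table data.frame as from [default_life_table()].
#' @param utility_cost a [default_utility_cost_table()]-style object.
#' @return an object of class `markov_tables`.
#' @export
markov_tables <- function(transition = transition_params(),
                          survival = default_survival_table(),
                          life = default_life_table(),
                          utility_cost = default_utility_cost_table()) {
  stopifnot(inherits(transition, "transition_params"))
  assert_prob(survival$annual_death_prob, "survival$annual_death_prob")
  assert_prob(life$annual_death_prob, "life$annual_death_prob")
  # life lookup matrix [age 0..100, sex]
  life_q <- matrix(NA_real_, nrow = 101, ncol = 2,
                   dimnames = list(0:100, c("F", "M")))
  life_q[cbind(life$age + 1, match(life$sex, c("F", "M")))] <-
    life$annual_death_prob
  if (anyNA(life_q)) stopf("life table must cover ages 0-100 for both sexes")
  # survival lookup array [stage, sex, band, year 1..10]
  surv_q <- array(NA_real_, dim = c(4, 2, 3, 10),
                  dimnames = list(c("I", "II", "III", "IV"), c("F", "M"),
                                  c("18-49", "50-69", "70+"), 1:10))
  yr <- pmin(survival$year_since_dx, 10)
  surv_q[cbind(match(survival$stage, c("I", "II", "III", "IV")),
               match(survival$sex, c("F", "M")),
               match(survival$age_band, c("18-49", "50-69", "70+")), yr)] <-
    survival$annual_death_prob
  if (anyNA(surv_q))
    stopf("survival table must cover every stage x sex x age band x year 1-10")
  structure(list(transition = transition, life_q = life_q, surv_q = surv_q,
                 uc = utility_cost),
            class = "markov_tables")
}

#' Read lifetime-model tables from delimited files
#'
#' Loaders for user-supplied replacements of the shipped stand-ins. The
#' survival table needs columns `stage,sex,age_band,year_since_dx,
#' annual_death_prob`; the life table `age,sex,annual_death_prob`.
#'
#' @param path CSV file path.
#' @rdname table_io
#' @export
read_survival_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stage", "sex", "age_band", "year_since_dx", "annual_death_prob")
  if (!all(need %in% names(x))) stopf("survival table needs columns %s",
                                      paste(need, collapse = ","))
  x
}

#' @rdname table_io
#' @export
read_life_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "sex", "annual_death_prob") %in% names(x)))
    stopf("life table needs columns age,sex,annual_death_prob")
  x
}
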