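# Lifetime annual-cycle model.
#
# Per-person traces are expected-value (fractional state occupancy), not
# Monte-Carlo walks: randomness is confined to population generation,
# disease allocation and the short-term pathway, so deterministic analyses
# are reproducible and CRC deaths are well-defined expectations. Accruals
# happen at cycle start with no half-cycle correction; year-0 accruals are
# undiscounted. Age 100 is an absorbing cap.

crc_stages <- c("I", "II", "III", "IV")

# occupancy over the I->II->III->IV chain after continuous exposure of
# length t, starting from stage `start_idx`: analytic solution of the
# sequential first-order chain with rates lambda = -log(1 - p_annual)
chain_occupancy <- function(start_idx, t, lambda) {
  lam <- c(lambda, 0)  # stage IV absorbing
  # nudge ties apart; the closed form needs distinct rates
  while (anyDuplicated(lam)) lam <- lam + seq_along(lam) * 1e-10
  out <- matrix(0, nrow = length(t), ncol = 4,
                dimnames = list(NULL, crc_stages))
  for (j in start_idx:4) {
    ks <- start_idx:j
    rate_prod <- if (j > start_idx) prod(lam[start_idx:(j - 1)]) else 1
    acc <- 0
    for (k in ks) {
      denom <- prod(lam[setdiff(ks, k)] - lam[k])
      acc <- acc + exp(-lam[k] * t) / denom
    }
    out[, j] <- rate_prod * acc
  }
  out
}

#' Stage progression during diagnostic delay
#'
#' Converts each annual progression probability p to a rate
#' `lambda = -log(1 - p)` and exposes the four-stage chain for the delay
#' duration. In `"expected"` mode the full stage distribution at diagnosis
#' is returned; in `"sample"` mode a single stage is drawn from it.
#' Stage IV is absorbing and a zero delay is the identity.
#'
#' @param stage starting stage, one of `"I","II","III","IV"`.
#' @param delay delay in years (>= 0).
#' @param params a [transition_params()] (fast-mode respected).
#' @param mode `"expected"` or `"sample"`.
#' @param seed seed for `"sample"` mode.
#' @return named length-4 probability vector (`"expected"`) or a single
#'   stage label (`"sample"`).
#' @export
progress_during_delay <- function(stage, delay, params,
                                  mode = c("expected", "sample"),
                                  seed = NULL) {
  mode <- match.arg(mode)
  if (delay < 0) stopf("delay must be >= 0")
  i <- match(stage, crc_stages)
  if (is.na(i)) stopf("unknown stage '%s'", stage)
  p <- active_progression(params)
  dist <- chain_occupancy(i, delay, -log(1 - p))[1, ]
  dist <- dist / sum(dist)
  if (mode == "expected") return(dist)
  if (!is.null(seed)) set.seed(derive_seed(seed, stream = 31L))
  sample(crc_stages, 1, prob = dist)
}

# ---- trace engine ---------------------------------------------------------

new_trace <- function() {
  c(dc = 0, dq = 0, dly = 0, uc = 0, uq = 0, uly = 0, crc_death = 0)
}

band_of <- function(age) {
  if (age <= 49) "18-49" else if (age <= 69) "50-69" else "70+"
}

# expected-value trace for a person diagnosed with CRC `stage` at age
# `age_dx`, `offset` years after model start; discounted to model start
crc_trace_raw <- function(age_dx, sex, stage, offset, tables, r,
                          horizon_age = 100) {
  out <- new_trace()
  if (age_dx >= horizon_age) return(out)
  band_dx <- band_of(age_dx)
  uc <- tables$uc
  alive <- 1
  j <- 1L
  repeat {
    a <- age_dx + j - 1L
    if (a >= horizon_age || alive <= 0) break
    t <- offset + j - 1L
    disc <- 1 / (1 + r)^t
    phase <- if (j == 1L) "year1" else "subsequent"
    util <- uc$general_utility[band_of(a), sex] *
      uc$stage_utility_mult[stage, phase]
    cost <- uc$stage_cost[stage, phase]
    out["uly"] <- out["uly"] + alive
    out["uq"] <- out["uq"] + alive * util
    out["uc"] <- out["uc"] + alive * cost
    out["dly"] <- out["dly"] + alive * disc
    out["dq"] <- out["dq"] + alive * util * disc
    out["dc"] <- out["dc"] + alive * cost * disc
    q_crc <- tables$surv_q[stage, sex, band_dx, min(j, 10L)]
    q_oth <- tables$life_q[as.character(min(a, 100)), sex]
    die_crc <- alive * q_crc
    die_oth <- alive * (1 - q_crc) * q_oth
    out["crc_death"] <- out["crc_death"] + die_crc
    out["uc"] <- out["uc"] + die_crc * uc$terminal_cost
    out["dc"] <- out["dc"] + die_crc * uc$terminal_cost * disc
    alive <- alive - die_crc - die_oth
    j <- j + 1L
  }
  out
}

# disease-free trace from integer age `age0`, starting `offset` years
# after model start; returns trace plus the surviving fraction at the end
# of `n_cycles` cycles (NULL = to horizon)
well_trace_raw <- function(age0, sex, tables, r, offset = 0,
                           n_cycles = NULL, horizon_age = 100) {
  out <- new_trace()
  alive <- 1
  uc <- tables$uc
  max_cycles <- max(horizon_age - age0, 0)
  nc <- if (is.null(n_cycles)) max_cycles else min(n_cycles, max_cycles)
  for (j in seq_len(nc)) {
    a <- age0 + j - 1L
    t <- offset + j - 1L
    disc <- 1 / (1 + r)^t
    util <- uc$general_utility[band_of(a), sex]
    out["uly"] <- out["uly"] + alive
    out["uq"] <- out["uq"] + alive * util
    out["dly"] <- out["dly"] + alive * disc
    out["dq"] <- out["dq"] + alive * util * disc
    alive <- alive * (1 - tables$life_q[as.character(min(a, 100)), sex])
  }
  attr(out, "surviving") <- alive
  out
}

# lifetime cost/utility deltas of living with IBD (relative to no IBD):
# chronic annual cost and a utility multiplier, weighted by all-cause
# survival only (CRC interaction ignored for the adjustment)
ibd_adjust_raw <- function(age0, sex, course, tables, r, horizon_age = 100) {
  out <- new_trace()
  row <- tables$uc$ibd[tables$uc$ibd$course == course, ]
  if (nrow(row) != 1L) stopf("unknown IBD course '%s'", course)
  alive <- 1
  for (j in seq_len(max(horizon_age - age0, 0))) {
    a <- age0 + j - 1L
    t <- j - 1L
    disc <- 1 / (1 + r)^t
    du <- tables$uc$general_utility[band_of(a), sex] * (row$utility_mult - 1)
    out["uc"] <- out["uc"] + alive * row$annual_cost
    out["dc"] <- out["dc"] + alive * row$annual_cost * disc
    out["uq"] <- out["uq"] + alive * du
    out["dq"] <- out["dq"] + alive * du * disc
    alive <- alive * (1 - tables$life_q[as.character(min(a, 100)), sex])
  }
  out
}

# expected-value trace of an undetected adenoma carrier: annual
# progression low->high->CRC; incident CRC is diagnosed stage I at the
# next cycle boundary and follows the diagnosed-CRC trace
adenoma_trace_raw <- function(age0, sex, start, tables, r, cache,
                              horizon_age = 100) {
  out <- new_trace()
  ap <- tables$transition$adenoma_progression
  occ <- c(low = as.numeric(start == "low_risk"),
           high = as.numeric(start == "high_risk"))
  uc <- tables$uc
  for (j in seq_len(max(horizon_age - age0, 0))) {
    a <- age0 + j - 1L
    t <- j - 1L
    disc <- 1 / (1 + r)^t
    alive <- sum(occ)
    if (alive <= 1e-12) break
    util <- uc$general_utility[band_of(a), sex]
    out["uly"] <- out["uly"] + alive
    out["uq"] <- out["uq"] + alive * util
    out["dly"] <- out["dly"] + alive * disc
    out["dq"] <- out["dq"] + alive * util * disc
    q_oth <- tables$life_q[as.character(min(a, 100)), sex]
    inc <- occ["high"] * ap[["high_crc"]] * (1 - q_oth)
    if (inc > 0 && a + 1L < horizon_age) {
      tr <- cached_crc_trace(cache, a + 1L, sex, "I", t + 1L, tables, r,
                             horizon_age)
      out <- out + inc * tr
    }
    occ <- c(low = occ[["low"]] * (1 - ap[["low_high"]]) * (1 - q_oth),
             high = (occ[["high"]] * (1 - ap[["high_crc"]]) +
                       occ[["low"]] * ap[["low_high"]]) * (1 - q_oth))
  }
  out
}

cached <- function(cache, key, expr) {
  if (is.null(cache)) return(force(expr))
  if (is.null(cache[[key]])) cache[[key]] <- force(expr)
  cache[[key]]
}

cached_crc_trace <- function(cache, age_dx, sex, stage, offset, tables, r,
                             horizon_age) {
  cached(cache, sprintf("crc|%d|%s|%s|%d|%d", age_dx, sex, stage, offset,
                        horizon_age),
         crc_trace_raw(age_dx, sex, stage, offset, tables, r, horizon_age))
}

#' Per-cycle state occupancy of the diagnosed-CRC trace
#'
#' Audit view of the lifetime trace for a diagnosed CRC case: one row per
#' annual cycle with the alive fraction at cycle start and the CRC and
#' other-cause death increments during the cycle. Occupancy is conserved:
#' at every cycle, alive + cumulative deaths = 1.
#'
#' @param age_dx integer age at diagnosis.
#' @param sex `"F"` or `"M"`.
#' @param stage diagnosed stage.
#' @param tables a [markov_tables()].
#' @param horizon_age absorbing age cap.
#' @return data.frame `cycle, age, alive_start, die_crc, die_other`.
#' @export
crc_occupancy_trace <- function(age_dx, sex, stage, tables,
                                horizon_age = 100) {
  band_dx <- band_of(age_dx)
  alive <- 1
  rows <- list()
  j <- 1L
  while (age_dx + j - 1L < horizon_age) {
    a <- age_dx + j - 1L
    q_crc <- tables$surv_q[stage, sex, band_dx, min(j, 10L)]
    q_oth <- tables$life_q[as.character(min(a, 100)), sex]
    die_crc <- alive * q_crc
    die_oth <- alive * (1 - q_crc) * q_oth
    rows[[j]] <- data.frame(cycle = j, age = a, alive_start = alive,
                            die_crc = die_crc, die_other = die_oth)
    alive <- alive - die_crc - die_oth
    j <- j + 1L
  }
  do.call(rbind, rows)
}

scenario_has_adenoma_effects <- function(scenario) scenario %in% c("1a", "1b")
scenario_has_ibd_effects <- function(scenario) identical(scenario, "1b")

# expected lifecourse of one person; internal workhorse shared by
# run_lifecourse() and run_lifecourse_population()
lifecourse_one <- function(age, sex, crc_stage, adenoma, ibd,
                           crc_detected_usc, crc_delay, adenoma_detected,
                           ibd_detected_usc, short_cost, short_qaly_loss,
                           tables, econ, scenario, cache, horizon_age = 100) {
  r <- econ$discount_rate
  a0 <- min(as.integer(floor(age)), 100L)
  tr <- new_trace()
  stage_at_dx <- "none"
  if (crc_stage != "none") {
    d <- if (crc_detected_usc) 0 else crc_delay
    k <- if (d <= 0) 0L else as.integer(ceiling(d - 1e-9))
    k <- min(k, max(horizon_age - a0, 0L))
    dist <- progress_during_delay(crc_stage, d, tables$transition)
    pre <- well_trace_raw(a0, sex, tables, r, offset = 0, n_cycles = k,
                          horizon_age = horizon_age)
    surv <- attr(pre, "surviving")
    tr <- tr + as.numeric(pre)
    for (s in crc_stages) {
      if (dist[[s]] < 1e-12) next
      tr <- tr + surv * dist[[s]] *
        cached_crc_trace(cache, a0 + k, sex, s, k, tables, r, horizon_age)
    }
    stage_at_dx <- crc_stages[which.max(dist)]
  } else if (scenario_has_adenoma_effects(scenario) && adenoma != "none" &&
             !adenoma_detected) {
    tr <- tr + cached(cache, sprintf("ade|%d|%s|%s|%d", a0, sex, adenoma,
                                     horizon_age),
                      adenoma_trace_raw(a0, sex, adenoma, tables, r, cache,
                                        horizon_age))
  } else {
    tr <- tr + as.numeric(cached(cache, sprintf("well|%d|%s|%d", a0, sex,
                                                horizon_age),
                                 well_trace_raw(a0, sex, tables, r,
                                                horizon_age = horizon_age)))
  }
  if (scenario_has_ibd_effects(scenario) && ibd) {
    course <- if (ibd_detected_usc) "routine" else "complicated"
    tr <- tr + cached(cache, sprintf("ibd|%d|%s|%s|%d", a0, sex, course,
                                     horizon_age),
                      ibd_adjust_raw(a0, sex, course, tables, r, horizon_age))
  }
  # short-term costs and harms land in year 0, undiscounted
  tr["dc"] <- tr["dc"] + short_cost
  tr["uc"] <- tr["uc"] + short_cost
  tr["dq"] <- tr["dq"] - short_qaly_loss
  tr["uq"] <- tr["uq"] - short_qaly_loss
  list(trace = tr, stage_at_diagnosis = stage_at_dx)
}

#' Lifetime expected outcomes for one person
#'
#' Runs the annual-cycle lifetime model for a single person given their
#' baseline state and short-term diagnostic outcome: disease-free accrual,
#' or the delayed-diagnosis stage shift followed by the diagnosed-CRC
#' trace with stage/age/sex/time-since-diagnosis CRC mortality competing
#' with other-cause mortality; adenoma progression and IBD adjustments
#' when the corresponding scenario is active.
#'
#' @param person one-row data.frame with `age`, `sex`.
#' @param baseline_state one-row data.frame with `crc_stage`, `adenoma`,
#'   `ibd`.
#' @param diag one-row data.frame from [run_pathway()].
#' @param tables a [markov_tables()].
#' @param econ an [economics_config()].
#' @param scenario scenario id.
#' @param horizon_age absorbing age cap (default 100; lower values force a
#'   short horizon, used by the hand-checkable fixtures).
#' @return one-row data.frame: `discounted_cost`, `discounted_qaly`,
#'   `discounted_ly`, `undiscounted_cost`, `undiscounted_qaly`,
#'   `undiscounted_ly`, `crc_death_probability`, `stage_at_diagnosis`.
#' @export
run_lifecourse <- function(person, baseline_state, diag, tables, econ,
                           scenario = "base", horizon_age = 100) {
  res <- lifecourse_one(person$age, person$sex,
                        as.character(baseline_state$crc_stage),
                        as.character(baseline_state$adenoma),
                        baseline_state$ibd,
                        diag$crc_detected_usc, diag$crc_diagnosis_delay,
                        diag$adenoma_detected, diag$ibd_detected_usc,
                        diag$short_term_cost, diag$short_term_qaly_loss,
                        tables, econ, scenario, cache = NULL,
                        horizon_age = horizon_age)
  tr <- res$trace
  data.frame(person_id = person$id %||% 1L,
             discounted_cost = tr[["dc"]], discounted_qaly = tr[["dq"]],
             discounted_ly = tr[["dly"]], undiscounted_cost = tr[["uc"]],
             undiscounted_qaly = tr[["uq"]], undiscounted_ly = tr[["uly"]],
             crc_death_probability = tr[["crc_death"]],
             stage_at_diagnosis = res$stage_at_diagnosis)
}

#' Lifetime expected outcomes for a whole population
#'
#' Memoised population driver for [run_lifecourse()]: traces are cached by
#' (age, sex, state) so large cohorts reuse the small number of distinct
#' expected-value traces.
#'
#' @param pop a `population`.
#' @param states data.frame from [allocate_baseline_states()].
#' @param diag data.frame from [run_pathway()].
#' @inheritParams run_lifecourse
#' @return data.frame with one row per person (columns as
#'   [run_lifecourse()]).
#' @export
run_lifecourse_population <- function(pop, states, diag, tables, econ,
                                      scenario = "base", horizon_age = 100) {
  persons <- pop$persons
  n <- nrow(persons)
  stopifnot(nrow(states) == n, nrow(diag) == n)
  cache <- new.env(parent = emptyenv())
  cols <- matrix(0, nrow = n, ncol = 7,
                 dimnames = list(NULL, c("dc", "dq", "dly", "uc", "uq",
                                         "uly", "crc_death")))
  stage_dx <- character(n)
  crc_stage <- as.character(states$crc_stage)
  adenoma <- as.character(states$adenoma)
  for (i in seq_len(n)) {
    res <- lifecourse_one(persons$age[i], persons$sex[i], crc_stage[i],
                          adenoma[i], states$ibd[i],
                          diag$crc_detected_usc[i],
                          diag$crc_diagnosis_delay[i],
                          diag$adenoma_detected[i], diag$ibd_detected_usc[i],
                          diag$short_term_cost[i],
                          diag$short_term_qaly_loss[i],
                          tables, econ, scenario, cache, horizon_age)
    cols[i, ] <- res$trace
    stage_dx[i] <- res$stage_at_diagnosis
  }
  data.frame(person_id = persons$id,
             discounted_cost = cols[, "dc"], discounted_qaly = cols[, "dq"],
             discounted_ly = cols[, "dly"], undiscounted_cost = cols[, "uc"],
             undiscounted_qaly = cols[, "uq"],
             undiscounted_ly = cols[, "uly"],
             crc_death_probability = cols[, "crc_death"],
             stage_at_diagnosis = stage_dx)
}

#' Lifetime cost/QALY deltas from IBD course (scenario effect)
#'
#' Difference streams for an IBD case under the scenario that models IBD
#' consequences: delayed cases follow the complicated course, cases
#' detected at urgent investigation the routine course. Inert (all-zero)
#' when the scenario is off.
#'
#' @param person one-row data.frame with `age`, `sex`.
#' @param diag one-row data.frame from [run_pathway()].
#' @param tables a [markov_tables()].
#' @param econ an [economics_config()].
#' @param scenario scenario id.
#' @return one-row data.frame of discounted/undiscounted cost and QALY
#'   deltas relative to no IBD.
#' @export
ibd_lifecourse_adjustment <- function(person, diag, tables, econ,
                                      scenario = "base") {
  if (!scenario_has_ibd_effects(scenario))
    return(data.frame(discounted_cost = 0, discounted_qaly = 0,
                      undiscounted_cost = 0, undiscounted_qaly = 0))
  course <- if (diag$ibd_detected_usc) "routine" else "complicated"
  tr <- ibd_adjust_raw(as.integer(floor(person$age)), person$sex, course,
                       tables, econ$discount_rate)
  data.frame(discounted_cost = tr[["dc"]], discounted_qaly = tr[["dq"]],
             undiscounted_cost = tr[["uc"]], undiscounted_qaly = tr[["uq"]])
}

#' Lifetime consequences of adenoma detection (scenario effect)
#'
#' Under the adenoma scenarios an undetected high-risk adenoma progresses
#' annually towards CRC, feeding cancer incidence in later cycles, while a
#' detected one is removed and the person follows the disease-free trace.
#' Returns the undetected-minus-detected delta; inert when the scenario is
#' off or progression probabilities are zero.
#'
#' @param person one-row data.frame with `age`, `sex`.
#' @param detected logical: adenoma removed at investigation.
#' @param start `"low_risk"` or `"high_risk"`.
#' @param tables a [markov_tables()].
#' @param econ an [economics_config()].
#' @param scenario scenario id.
#' @return one-row data.frame of cost/QALY/CRC-death deltas.
#' @export
adenoma_lifecourse <- function(person, detected, start = "high_risk",
                               tables, econ, scenario = "base") {
  zero <- data.frame(discounted_cost = 0, discounted_qaly = 0,
                     crc_death_probability = 0)
  if (!scenario_has_adenoma_effects(scenario) || detected) return(zero)
  a0 <- as.integer(floor(person$age))
  cache <- new.env(parent = emptyenv())
  und <- adenoma_trace_raw(a0, person$sex, start, tables,
                           econ$discount_rate, cache)
  det <- well_trace_raw(a0, person$sex, tables, econ$discount_rate)
  data.frame(discounted_cost = und[["dc"]] - det[["dc"]],
             discounted_qaly = und[["dq"]] - det[["dq"]],
             crc_death_probability = und[["crc_death"]])
}
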