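#' Short-term diagnostic pathway parameters
#'
#' Costs (GBP, 2023 prices), probabilities and test characteristics of the
#' short-term model. Unit costs and sensitivities are labelled stand-ins
#' representative of NHS reference costs; the blood-count cost (8.38) and
#' algorithm running cost (0.01) are the published per-person figures.
#'
#' @param uptake_probability probability a referred person attends
#'   definitive investigation.
#' @param colonoscopy_sensitivity,ctc_sensitivity named vectors with
#'   entries `crc`, `adenoma`, `ibd`.
#' @param ctc_fraction share of attended investigations done by CT
#'   colonography rather than colonoscopy.
#' @param cost_gp_appointment,cost_fit,cost_fbc,cost_algorithm,cost_colonoscopy,cost_ctc,cost_extra_gp,cost_emergency
#'   unit costs in GBP.
#' @param emergency_fraction_delayed fraction of delayed CRC cases
#'   presenting as an emergency.
#' @param extra_gp_appointments_delayed number of additional GP
#'   appointments accrued per delayed CRC case.
#' @param complication_probability,complication_cost,complication_qaly_loss
#'   colonoscopy complication risk with its cost and QALY decrement
#'   (applied in expectation per colonoscopy).
#' @param fbc_charge_fraction fraction of risk-score-arm patients charged
#'   for a new blood count. At the default 0.09 the charge follows each
#'   person's `has_recent_fbc` flag (91% already have one); setting 1
#'   charges everyone (cost scenario).
#' @return an object of class `pathway_params`.
#' @export
pathway_params <- function(uptake_probability = 0.95,
                           colonoscopy_sensitivity = c(crc = 0.95, adenoma = 0.90, ibd = 0.90),
                           ctc_fraction = 0.15,
                           ctc_sensitivity = c(crc = 0.90, adenoma = 0.60, ibd = 0.40),
                           cost_gp_appointment = 42,
                           cost_fit = 5,
                           cost_fbc = 8.38,
                           cost_algorithm = 0.01,
                           cost_colonoscopy = 650,
                           cost_ctc = 180,
                           cost_extra_gp = 42,
                           cost_emergency = 3700,
                           emergency_fraction_delayed = 0.20,
                           extra_gp_appointments_delayed = 2,
                           complication_probability = 0.0005,
                           complication_cost = 1500,
                           complication_qaly_loss = 0.01,
                           fbc_charge_fraction = 0.09) {
  p <- as.list(environment())
  for (nm in c("uptake_probability", "ctc_fraction",
               "emergency_fraction_delayed", "complication_probability",
               "fbc_charge_fraction"))
    assert_prob(p[[nm]], nm)
  assert_prob(colonoscopy_sensitivity, "colonoscopy_sensitivity")
  assert_prob(ctc_sensitivity, "ctc_sensitivity")
  for (nm in grep("^cost_", names(p), value = TRUE))
    if (any(p[[nm]] < 0)) stopf("'%s' must be >= 0", nm)
  structure(p, class = "pathway_params")
}

#' Personalised diagnostic delay model
#'
#' Delays for CRC cases not diagnosed through the urgent pathway follow a
#' lognormal distribution truncated to `[min, max]`, with the location
#' parameter solved numerically so the truncated mean equals `mean`. The
#' lognormal captures the right skew of waiting times; defaults give a
#' 3-month mean delay ranging from 2 weeks to 2 years. IBD carries a fixed
#' delay.
#'
#' @param mean target mean delay in years (default 0.25).
#' @param min,max truncation bounds in years (defaults 2/52 and 2).
#' @param sigma lognormal scale parameter (default 0.9).
#' @param ibd_delay fixed IBD diagnostic delay in years (default 1.34).
#' @return an object of class `delay_model` with the solved `meanlog`.
#' @export
delay_model <- function(mean = 0.25, min = 2 / 52, max = 2, sigma = 0.9,
                        ibd_delay = 1.34) {
  if (!(min <= mean && mean <= max)) stopf("need min <= mean <= max")
  if (min == max) {
    meanlog <- log(min)
  } else {
    trunc_mean <- function(mu) {
      a <- (log(min) - mu) / sigma
      b <- (log(max) - mu) / sigma
      z <- stats::pnorm(b) - stats::pnorm(a)
      if (z < 1e-12) return(if (a > 0) min else max)  # mass outside range
      exp(mu + sigma^2 / 2) *
        (stats::pnorm(b - sigma) - stats::pnorm(a - sigma)) / z
    }
    meanlog <- stats::uniroot(function(mu) trunc_mean(mu) - mean,
                              c(log(min), log(max)), extendInt = "upX",
                              tol = 1e-12)$root
  }
  structure(list(mean = mean, min = min, max = max, sigma = sigma,
                 meanlog = meanlog, ibd_delay = ibd_delay),
            class = "delay_model")
}

#' Sample personalised diagnostic delays
#'
#' Inverse-CDF sampling of the truncated lognormal; `u` allows externally
#' supplied uniform draws (the common-random-numbers contract).
#'
#' @param model a [delay_model()].
#' @param n number of draws (ignored when `u` given).
#' @param seed integer seed (ignored when `u` given).
#' @param u optional uniform(0,1) draws.
#' @return delays in years, all within `[min, max]`.
#' @export
sample_delay <- function(model, n = 1, seed = NULL, u = NULL) {
  stopifnot(inherits(model, "delay_model"))
  if (is.null(u)) {
    if (!is.null(seed)) set.seed(derive_seed(seed, stream = 21L))
    u <- stats::runif(n)
  }
  if (model$min == model$max) return(rep(model$min, length(u)))
  plo <- stats::plnorm(model$min, model$meanlog, model$sigma)
  phi <- stats::plnorm(model$max, model$meanlog, model$sigma)
  stats::qlnorm(plo + u * (phi - plo), model$meanlog, model$sigma)
}

#' Assign definitive investigations
#'
#' CT colonography with probability `ctc_fraction`, colonoscopy otherwise.
#'
#' @param params a [pathway_params()].
#' @param n number of assignments (ignored when `u` given).
#' @param seed integer seed (ignored when `u` given).
#' @param u optional uniform draws.
#' @return character vector of `"colonoscopy"` / `"ctc"`.
#' @export
investigation_assignment <- function(params, n = 1, seed = NULL, u = NULL) {
  if (is.null(u)) {
    if (!is.null(seed)) set.seed(derive_seed(seed, stream = 22L))
    u <- stats::runif(n)
  }
  ifelse(u < params$ctc_fraction, "ctc", "colonoscopy")
}

#' Per-colonoscopy QALY harm
#'
#' Base case: the expected complication decrement
#' `complication_probability * complication_qaly_loss`. Under the
#' colonoscopy-harm scenario every colonoscopy costs one full day of
#' quality-adjusted life, `1/365.25` QALYs.
#'
#' @param scenario scenario id (see [apply_scenario()]).
#' @param params a [pathway_params()].
#' @return QALY loss per colonoscopy.
#' @export
colonoscopy_harm_qaly <- function(scenario = "base",
                                  params = pathway_params()) {
  if (identical(scenario, "4")) 1 / 365.25
  else params$complication_probability * params$complication_qaly_loss
}

#' Common-random-number draws for the short-term pathway
#'
#' One fixed vector of uniforms per person (uptake, investigation
#' assignment, per-condition detection, delay, emergency presentation),
#' generated once per simulated cohort and reused by every strategy so
#' strategy comparisons are paired: a person whose referral status agrees
#' under two strategies receives identical outcomes under both.
#'
#' @param n number of persons.
#' @param seed integer seed.
#' @return data.frame of uniform draws.
#' @export
crn_draws <- function(n, seed) {
  set.seed(derive_seed(seed, stream = 23L))
  data.frame(u_uptake = stats::runif(n), u_inv = stats::runif(n),
             u_det_crc = stats::runif(n), u_det_ade = stats::runif(n),
             u_det_ibd = stats::runif(n), u_delay = stats::runif(n),
             u_emerg = stats::runif(n))
}

#' Run the short-term diagnostic model
#'
#' Applies the referral decision, uptake, investigation assignment and
#' per-condition detection draws, samples personalised delays for CRC
#' cases not diagnosed urgently, and accrues all short-term costs and
#' harms. Every person pays the GP appointment and FIT test; risk-score
#' strategies additionally pay the algorithm cost for everyone and a blood
#' count for patients without a recent one (or for all patients when
#' `fbc_charge_fraction = 1`). Delayed CRC cases accrue extra GP
#' appointments, an emergency presentation in a configured fraction, and
#' the definitive investigation at delayed diagnosis. CRC missed at
#' investigation follows the same delayed route as non-referred CRC.
#'
#' @param pop a `population`.
#' @param states baseline states from [allocate_baseline_states()].
#' @param referred logical referral vector from [stratify()].
#' @param strat the [strategy()] that produced `referred`.
#' @param params a [pathway_params()].
#' @param dmodel a [delay_model()].
#' @param scenario scenario id (affects colonoscopy harm only; cost and
#'   flag changes arrive through `params` via [apply_scenario()]).
#' @param draws common-random-number draws from [crn_draws()].
#' @return data.frame of per-person diagnostic outcomes.
#' @export
run_pathway <- function(pop, states, referred, strat, params, dmodel,
                        scenario = "base", draws) {
  persons <- pop$persons
  n <- nrow(persons)
  if (length(referred) != n) stopf("referral vector length mismatch")
  if (nrow(states) != n) stopf("baseline state length mismatch")
  if (nrow(draws) != n) stopf("CRN draw length mismatch")

  attended <- referred & draws$u_uptake < params$uptake_probability
  investigation <- rep("none", n)
  investigation[attended] <- investigation_assignment(params,
                                                      u = draws$u_inv[attended])
  sens_for <- function(cond) {
    ifelse(investigation == "colonoscopy", params$colonoscopy_sensitivity[[cond]],
           ifelse(investigation == "ctc", params$ctc_sensitivity[[cond]], 0))
  }
  has_crc <- states$crc_stage != "none"
  has_ade <- states$adenoma != "none"

  crc_detected <- attended & has_crc & draws$u_det_crc < sens_for("crc")
  ade_detected <- attended & has_ade & draws$u_det_ade < sens_for("adenoma")
  ibd_detected <- attended & states$ibd & draws$u_det_ibd < sens_for("ibd")

  crc_delay <- numeric(n)
  delayed_crc <- has_crc & !crc_detected
  crc_delay[delayed_crc] <- sample_delay(dmodel, u = draws$u_delay[delayed_crc])
  ibd_delay <- ifelse(states$ibd & !ibd_detected, dmodel$ibd_delay, 0)

  cost <- rep(params$cost_gp_appointment + params$cost_fit, n)
  if (strat$kind %in% c("cox", "logistic")) {
    cost <- cost + params$cost_algorithm
    charged <- if (params$fbc_charge_fraction >= 1) rep(TRUE, n)
               else !persons$has_recent_fbc
    cost <- cost + ifelse(charged, params$cost_fbc, 0)
  }
  inv_cost <- ifelse(investigation == "colonoscopy",
                     params$cost_colonoscopy +
                       params$complication_probability * params$complication_cost,
                     ifelse(investigation == "ctc", params$cost_ctc, 0))
  cost <- cost + inv_cost
  # delayed CRC: investigation at delayed diagnosis, extra GP contact,
  # emergency presentation in a fraction of cases
  emerg <- delayed_crc & draws$u_emerg < params$emergency_fraction_delayed
  cost <- cost + ifelse(delayed_crc,
                        params$cost_colonoscopy +
                          params$extra_gp_appointments_delayed * params$cost_extra_gp,
                        0) +
    ifelse(emerg, params$cost_emergency, 0)

  # harm applies to performed colonoscopies; the delayed-diagnosis
  # investigation is costed but its harm is not double-counted
  qaly_loss <- ifelse(investigation == "colonoscopy",
                      colonoscopy_harm_qaly(scenario, params), 0)

  data.frame(person_id = persons$id,
             referred = referred,
             attended = attended,
             investigation = investigation,
             crc_detected_usc = crc_detected,
             crc_diagnosis_delay = crc_delay,
             adenoma_detected = ade_detected,
             ibd_detected_usc = ibd_detected,
             ibd_diagnosis_delay = ibd_delay,
             emergency_presentation = emerg,
             short_term_cost = cost,
             short_term_qaly_loss = qaly_loss)
}
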