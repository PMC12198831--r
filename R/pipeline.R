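#' Assemble a run configuration
#'
#' Bundles every input of a deterministic model run: the synthetic-cohort
#' settings, risk models, disease prevalence, short-term pathway
#' parameters, delay model, lifetime-model tables, economics settings,
#' strategy list and scenario id. All components default to the shipped
#' stand-ins.
#'
#' @param n cohort size.
#' @param seed integer seed (mandatory: no silent nondeterminism).
#' @param strategies list of [strategy()] objects.
#' @param cohort `"validation"` (base case) or `"derivation"`.
#' @param population optional [population_config()] overriding `cohort`.
#' @param risk_model_kind `"cox"` (base case) or `"logistic"`.
#' @param cox_model,logistic_model risk models.
#' @param prevalence a [prevalence_config()].
#' @param pathway a [pathway_params()].
#' @param delay a [delay_model()].
#' @param tables a [markov_tables()].
#' @param econ an [economics_config()].
#' @param scenario scenario id (see [apply_scenario()]).
#' @return an object of class `run_config`.
#' @export
run_config <- function(n, seed,
                       strategies = default_strategies(),
                       cohort = "validation",
                       population = NULL,
                       risk_model_kind = "cox",
                       cox_model = default_cox_model(),
                       logistic_model = default_logistic_model(),
                       prevalence = prevalence_config(),
                       pathway = pathway_params(),
                       delay = delay_model(),
                       tables = markov_tables(),
                       econ = economics_config(),
                       scenario = "base") {
  if (missing(seed)) stopf("a seed is required")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 strategies = strategies, cohort = cohort,
                 population = population, risk_model_kind = risk_model_kind,
                 cox_model = cox_model, logistic_model = logistic_model,
                 prevalence = prevalence, pathway = pathway, delay = delay,
                 tables = tables, econ = econ, scenario = scenario),
            class = "run_config")
}

#' Default strategy set
#'
#' Refer-all plus the headline FIT thresholds (10, 13, 28, 40 ug Hb/g) and
#' the matched risk-score thresholds (0.64%, 1%, 2%, 3%).
#'
#' @param risk_kind `"cox"` or `"logistic"` for the score strategies.
#' @return list of [strategy()] objects.
#' @export
default_strategies <- function(risk_kind = "cox") {
  c(list(strategy("refer_all")),
    lapply(c(10, 13, 28, 40), function(t) strategy("fit", t)),
    lapply(c(0.0064, 0.01, 0.02, 0.03),
           function(t) strategy(risk_kind, t)))
}

scenario_ids <- c("base", "1a", "1b", "2", "3", "4", "5a", "5b", "5c",
                  "6a", "6b", "7")

#' Apply a scenario to a run configuration
#'
#' Pure function: returns a copy of the configuration with exactly the
#' documented fields changed. Scenario ids (long aliases such as
#' `"1a_adenomas"` are accepted and truncated at the first underscore):
#' \describe{
#'   \item{base}{no change.}
#'   \item{1a}{adenoma detection has lifetime consequences.}
#'   \item{1b}{adenoma and IBD detection have lifetime consequences.}
#'   \item{2}{derivation-style synthetic population (higher CRC risk).}
#'   \item{3}{logistic risk model instead of Cox.}
#'   \item{4}{colonoscopy harm of one full day of QALYs (1/365.25).}
#'   \item{5a}{mean diagnostic delay doubled to 0.5 years (bounds kept).}
#'   \item{5b}{fast (upper-bound) stage-transition probabilities.}
#'   \item{5c}{5a and 5b combined.}
#'   \item{6a}{discount rate 5\%.}
#'   \item{6b}{discount rate 1.5\%.}
#'   \item{7}{all risk-score-arm patients charged for a blood count.}
#' }
#' @param config a [run_config()].
#' @param id scenario id.
#' @return the modified configuration.
#' @export
apply_scenario <- function(config, id) {
  stopifnot(inherits(config, "run_config"))
  id <- sub("_.*$", "", as.character(id))
  if (!id %in% scenario_ids) stopf("unknown scenario id '%s'", id)
  cfg <- config
  cfg$scenario <- id
  if (id == "2") cfg$cohort <- "derivation"
  if (id == "3") cfg$risk_model_kind <- "logistic"
  if (id %in% c("5a", "5c"))
    cfg$delay <- delay_model(mean = 0.5, min = config$delay$min,
                             max = config$delay$max,
                             sigma = config$delay$sigma,
                             ibd_delay = config$delay$ibd_delay)
  if (id %in% c("5b", "5c")) cfg$tables$transition$fast_mode <- TRUE
  if (id == "6a") cfg$econ$discount_rate <- 0.05
  if (id == "6b") cfg$econ$discount_rate <- 0.015
  if (id == "7") cfg$pathway$fbc_charge_fraction <- 1.0
  cfg
}

active_risk_model <- function(config) {
  if (config$risk_model_kind == "logistic") config$logistic_model
  else config$cox_model
}

#' Simulate one cohort: population, risks, baseline states, CRN draws
#'
#' The strategy-independent half of the pipeline; every strategy is then
#' evaluated against the same cohort and the same random draws (common
#' random numbers), so strategy comparisons are paired.
#'
#' @param config a [run_config()].
#' @return list with `pop`, `risks`, `states`, `draws`, `model`.
#' @export
simulate_cohort <- function(config) {
  pcfg <- config$population %||%
    default_population_config(config$cohort, n = config$n, seed = config$seed)
  pop <- generate_population(pcfg)
  model <- active_risk_model(config)
  risks <- predict_risk(model, pop$persons)
  states <- allocate_baseline_states(pop, risks, config$prevalence,
                                     config$seed)
  draws <- crn_draws(nrow(pop$persons), config$seed)
  list(pop = pop, risks = risks, states = states, draws = draws,
       model = model)
}

#' Evaluate one strategy on a simulated cohort
#'
#' @param cohort output of [simulate_cohort()].
#' @param strat a [strategy()].
#' @param config the [run_config()].
#' @return list with `outcome` (a `strategy_outcome` row), `referred`,
#'   `diag`, `lifecourse`.
#' @export
evaluate_strategy <- function(cohort, strat, config) {
  referred <- stratify(cohort$pop, strat, risks = cohort$risks)
  diag <- run_pathway(cohort$pop, cohort$states, referred, strat,
                      config$pathway, config$delay, config$scenario,
                      cohort$draws)
  lifecourse <- run_lifecourse_population(cohort$pop, cohort$states, diag,
                                          config$tables, config$econ,
                                          config$scenario)
  outcome <- aggregate_outcomes(lifecourse, diag, config$econ, strat$label)
  list(outcome = outcome, referred = referred, diag = diag,
       lifecourse = lifecourse)
}

#' Run a full deterministic analysis
#'
#' Orchestrates population generation, risk scoring, disease allocation,
#' the short-term pathway, the lifetime model and economic aggregation for
#' every configured strategy, producing a strategy-outcome table and
#' pairwise incrementals against the first strategy (by convention
#' refer-all) and against the matched comparator pairs. When `out_dir` is
#' given, the tables are written as CSV together with a YAML run manifest
#' (configuration fingerprint and seed), and a rerun with the same
#' configuration reproduces the outputs byte-identically.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return (invisibly when writing) list with `outcomes`, `incrementals`,
#'   `per_person` (per-strategy person-level tables), `cohort`.
#' @export
run_analysis <- function(config, out_dir = NULL) {
  cohort <- simulate_cohort(config)
  evals <- lapply(config$strategies, function(s)
    evaluate_strategy(cohort, s, config))
  outcomes <- do.call(rbind, lapply(evals, `[[`, "outcome"))
  baseline <- evals[[1]]$outcome
  incr <- do.call(rbind, lapply(evals[-1], function(e)
    incremental(e$outcome, baseline, config$econ)))
  bundle <- list(outcomes = outcomes, incrementals = incr,
                 per_person = lapply(evals, `[`, c("diag", "lifecourse")),
                 cohort = cohort)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(outcomes, file.path(out_dir, "strategy_outcomes.csv"),
                     row.names = FALSE)
    if (!is.null(incr))
      utils::write.csv(incr, file.path(out_dir, "incrementals.csv"),
                       row.names = FALSE)
    manifest <- list(package_version = as.character(utils::packageVersion("crctriage")),
                     n = config$n, seed = config$seed,
                     scenario = config$scenario,
                     cohort = config$cohort,
                     config_fingerprint = config_fingerprint(config),
                     strategies = vapply(config$strategies, `[[`, "",
                                         "label"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    return(invisible(bundle))
  }
  bundle
}

#' Threshold sweep against the refer-all baseline
#'
#' Evaluates a grid of FIT and risk-score thresholds on one shared cohort
#' and reports each strategy's outcome and its incrementals against
#' refer-all, sorted by USC CRC diagnoses (the x-axis of
#' cost-effectiveness frontier plots).
#'
#' @param config a [run_config()] (its `strategies` field is ignored).
#' @param fit_thresholds numeric vector of FIT thresholds.
#' @param risk_thresholds numeric vector of risk-probability thresholds.
#' @return data.frame: one row per strategy with outcome columns and
#'   `inmb_vs_refer_all`.
#' @export
threshold_sweep <- function(config, fit_thresholds, risk_thresholds) {
  if (length(fit_thresholds) == 0 && length(risk_thresholds) == 0)
    stopf("at least one threshold is required")
  cohort <- simulate_cohort(config)
  strategies <- c(list(strategy("refer_all")),
                  lapply(fit_thresholds, function(t) strategy("fit", t)),
                  lapply(risk_thresholds,
                         function(t) strategy(config$risk_model_kind, t)))
  evals <- lapply(strategies, function(s)
    evaluate_strategy(cohort, s, config))
  outcomes <- do.call(rbind, lapply(evals, `[[`, "outcome"))
  base <- evals[[1]]$outcome
  outcomes$inmb_vs_refer_all <- vapply(seq_len(nrow(outcomes)), function(i)
    incremental(outcomes[i, ], base, config$econ)$inmb, numeric(1))
  outcomes[order(outcomes$usc_crc_diagnoses), ]
}
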