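#' Parameter uncertainty distribution
#'
#' One sampled parameter of the probabilistic sensitivity analysis,
#' addressed by a path into the run configuration (e.g.
#' `"pathway$uptake_probability"`). Conventional families: beta for
#' probabilities and utilities, gamma for costs, lognormal for
#' hazard-type parameters, `fixed` for point values.
#'
#' @param path `$`-separated path into a [run_config()] (list indices are
#'   followed by name).
#' @param family `"beta"`, `"gamma"`, `"lognormal"` or `"fixed"`.
#' @param ... hyperparameters: `shape1`/`shape2` (beta), `shape`/`rate`
#'   (gamma), `meanlog`/`sdlog` (lognormal), `value` (fixed).
#' @param lower,upper optional truncation bounds (rejection-free: samples
#'   are clamped).
#' @return an object of class `parameter_distribution`.
#' @export
parameter_distribution <- function(path,
                                   family = c("beta", "gamma", "lognormal",
                                              "fixed"),
                                   ..., lower = -Inf, upper = Inf) {
  family <- match.arg(family)
  hp <- list(...)
  need <- switch(family, beta = c("shape1", "shape2"),
                 gamma = c("shape", "rate"), lognormal = c("meanlog", "sdlog"),
                 fixed = "value")
  if (!all(need %in% names(hp)))
    stopf("family '%s' needs hyperparameters %s", family,
          paste(need, collapse = ","))
  bad <- switch(family,
                beta = hp$shape1 <= 0 || hp$shape2 <= 0,
                gamma = hp$shape <= 0 || hp$rate <= 0,
                lognormal = hp$sdlog < 0,
                fixed = FALSE)
  if (bad) stopf("invalid hyperparameters for family '%s'", family)
  structure(list(path = path, family = family, hyper = hp,
                 lower = lower, upper = upper),
            class = "parameter_distribution")
}

#' Draw one parameter set
#'
#' Independent draws, one per distribution; `fixed` families return their
#' point value. Clamped to each distribution's truncation bounds.
#'
#' @param dists list of [parameter_distribution()] objects.
#' @param seed integer seed.
#' @return named list (by path) of sampled values.
#' @export
sample_parameters <- function(dists, seed) {
  set.seed(derive_seed(seed, stream = 41L))
  vals <- lapply(dists, function(d) {
    h <- d$hyper
    x <- switch(d$family,
                fixed = h$value,
                beta = stats::rbeta(1, h$shape1, h$shape2),
                gamma = stats::rgamma(1, shape = h$shape, rate = h$rate),
                lognormal = stats::rlnorm(1, h$meanlog, h$sdlog))
    min(max(x, d$lower), d$upper)
  })
  names(vals) <- vapply(dists, `[[`, "", "path")
  vals
}

set_config_path <- function(config, path, value) {
  keys <- strsplit(path, "$", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, k) call("[[", acc, k), keys,
                 accumulate = FALSE, init = quote(config))
  eval(call("<-", expr, value))
  config
}

apply_parameter_set <- function(config, params) {
  for (p in names(params)) config <- set_config_path(config, p, params[[p]])
  config
}

#' Default PSA distributions
#'
#' Varies the short-term pathway probabilities and costs and the annual
#' stage-transition probabilities around their base-case values (beta for
#' probabilities, gamma for costs with ~10-20% coefficients of variation).
#' Population aggregates are not varied: a fresh population draw per run
#' already carries the sampling uncertainty.
#'
#' @return list of [parameter_distribution()] objects.
#' @export
default_psa_distributions <- function() {
  list(
    parameter_distribution("pathway$uptake_probability", "beta",
                           shape1 = 95, shape2 = 5),
    parameter_distribution("pathway$ctc_fraction", "beta",
                           shape1 = 15, shape2 = 85),
    parameter_distribution("pathway$emergency_fraction_delayed", "beta",
                           shape1 = 20, shape2 = 80),
    parameter_distribution("pathway$cost_colonoscopy", "gamma",
                           shape = 100, rate = 100 / 650),
    parameter_distribution("pathway$cost_ctc", "gamma",
                           shape = 100, rate = 100 / 180),
    parameter_distribution("pathway$cost_emergency", "gamma",
                           shape = 50, rate = 50 / 3700),
    parameter_distribution("tables$transition$stage_progression$I_II",
                           "beta", shape1 = 35, shape2 = 65),
    parameter_distribution("tables$transition$stage_progression$II_III",
                           "beta", shape1 = 45, shape2 = 55),
    parameter_distribution("tables$transition$stage_progression$III_IV",
                           "beta", shape1 = 55, shape2 = 45)
  )
}

#' PSA configuration
#'
#' @param n_runs number of model runs (default 500).
#' @param n_patients patients per run (default 100000).
#' @param master_seed integer master seed; run seeds are derived from it.
#' @param wtp_grid willingness-to-pay grid for the CEAC (GBP/QALY).
#' @return an object of class `psa_config`.
#' @export
psa_config <- function(n_runs = 500, n_patients = 100000, master_seed = 1,
                       wtp_grid = seq(0, 50000, by = 5000)) {
  if (n_runs < 1 || n_patients < 1) stopf("n_runs and n_patients must be >= 1")
  structure(list(n_runs = as.integer(n_runs),
                 n_patients = as.integer(n_patients),
                 master_seed = as.integer(master_seed),
                 wtp_grid = wtp_grid),
            class = "psa_config")
}

#' Run a probabilistic sensitivity analysis
#'
#' Per run: one parameter draw, one fresh population at a run-indexed
#' seed, and every strategy evaluated on that population with common
#' random numbers. Runs are independent given their derived seeds, so any
#' execution order yields identical per-run results, and the whole PSA is
#' reproducible from the master seed.
#'
#' @param config a [run_config()] (its `n` and `seed` are replaced per
#'   run).
#' @param psa a [psa_config()].
#' @param dists list of [parameter_distribution()] objects (default
#'   [default_psa_distributions()]).
#' @return an object of class `psa_result`: `outcomes` (run x strategy
#'   table) and `wtp_grid`.
#' @export
run_psa <- function(config, psa, dists = default_psa_distributions()) {
  stopifnot(inherits(psa, "psa_config"))
  rows <- vector("list", psa$n_runs)
  for (run in seq_len(psa$n_runs)) {
    res <- tryCatch({
      params <- sample_parameters(dists, derive_seed(psa$master_seed, run,
                                                     stream = 42L))
      cfg <- apply_parameter_set(config, params)
      cfg$n <- psa$n_patients
      cfg$seed <- derive_seed(psa$master_seed, run, stream = 43L)
      cohort <- simulate_cohort(cfg)
      out <- do.call(rbind, lapply(cfg$strategies, function(s)
        evaluate_strategy(cohort, s, cfg)$outcome))
      out$run <- run
      out
    }, error = function(e) stopf("PSA run %d failed: %s", run,
                                 conditionMessage(e)))
    rows[[run]] <- res
  }
  structure(list(outcomes = do.call(rbind, rows), wtp_grid = psa$wtp_grid,
                 econ = config$econ),
            class = "psa_result")
}

#' Probability each strategy is cost-effective
#'
#' Fraction of PSA runs in which the strategy attains the maximum net
#' monetary benefit (`wtp * qaly - cost`) among the compared strategies;
#' exact ties share their run equally, so probabilities sum to 1.
#'
#' @param result a `psa_result` (or its `outcomes` data.frame).
#' @param wtp willingness-to-pay per QALY.
#' @return named numeric vector of probabilities by strategy.
#' @export
probability_cost_effective <- function(result, wtp) {
  out <- if (inherits(result, "psa_result")) result$outcomes else result
  if (nrow(out) == 0L) stopf("empty PSA result")
  strategies <- unique(out$strategy)
  wins <- stats::setNames(numeric(length(strategies)), strategies)
  for (r in unique(out$run)) {
    sub <- out[out$run == r, ]
    nmb <- wtp * sub$qaly - sub$cost
    best <- which(nmb >= max(nmb) - 1e-9)
    wins[sub$strategy[best]] <- wins[sub$strategy[best]] + 1 / length(best)
  }
  wins / length(unique(out$run))
}

#' Cost-effectiveness acceptability curves
#'
#' [probability_cost_effective()] evaluated over a willingness-to-pay
#' grid; at every grid point the strategy probabilities sum to 1.
#'
#' @param result a `psa_result`.
#' @param wtp_grid willingness-to-pay grid (defaults to the result's
#'   grid).
#' @return data.frame `wtp, strategy, probability`.
#' @export
ceac <- function(result, wtp_grid = NULL) {
  wtp_grid <- wtp_grid %||% result$wtp_grid
  if (length(wtp_grid) == 0L) stopf("empty willingness-to-pay grid")
  rows <- lapply(wtp_grid, function(l) {
    p <- probability_cost_effective(result, l)
    data.frame(wtp = l, strategy = names(p), probability = unname(p))
  })
  do.call(rbind, rows)
}

#' Equal-tailed empirical credible interval
#'
#' Empirical 2.5th and 97.5th percentiles (for `level = 0.95`) with
#' linear interpolation between order statistics (quantile type 7).
#'
#' @param values numeric vector (>= 2 values).
#' @param level interval mass (default 0.95).
#' @return named numeric `c(lo, hi)`.
#' @export
credible_interval <- function(values, level = 0.95) {
  if (length(values) < 2L) stopf("credible interval needs >= 2 values")
  a <- (1 - level) / 2
  q <- stats::quantile(values, c(a, 1 - a), names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' Incremental results per PSA run for a strategy pair
#'
#' @param result a `psa_result`.
#' @param a,b strategy labels.
#' @param cfg an [economics_config()].
#' @return data.frame of per-run incrementals (see [incremental()]).
#' @export
psa_incrementals <- function(result, a, b, cfg = economics_config()) {
  out <- result$outcomes
  rows <- lapply(unique(out$run), function(r) {
    sa <- out[out$run == r & out$strategy == a, ]
    sb <- out[out$run == r & out$strategy == b, ]
    if (nrow(sa) != 1L || nrow(sb) != 1L)
      stopf("strategy '%s' or '%s' missing in run %d", a, b, r)
    cbind(run = r, incremental(sa, sb, cfg))
  })
  do.call(rbind, rows)
}
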