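#' Multivariable CRC risk models (Cox and logistic forms)
#'
#' Both model forms share a linear predictor over person-level covariates
#' with per-covariate transforms. The Cox form converts the linear
#' predictor to 1-year risk through a baseline survival probability at the
#' 1-year horizon, `risk = 1 - S0^exp(lp)`; the logistic form through
#' `plogis(intercept + lp)`. Coefficients are data, not code: the package
#' ships a clearly-labelled synthetic stand-in (see
#' [default_cox_model()]), and [read_risk_model()] loads user-supplied
#' coefficient files.
#'
#' @param coefficients named numeric vector, one entry per covariate, on
#'   the log-hazard-ratio (Cox) or log-odds-ratio (logistic) scale.
#' @param baseline_survival_at_horizon S0 in (0, 1]: probability of
#'   remaining CRC-free at 1 year for a person with linear predictor 0.
#' @param transforms named character vector mapping each covariate to
#'   `"identity"`, `"log1p"` or `"pw_linear"`; defaults to identity for
#'   any covariate not named. `"pw_linear"` requires a `knots` entry in
#'   `transform_args` (list of `c(x, y)` breakpoints, interpolated
#'   linearly and extended flat).
#' @param transform_args named list of extra arguments for piecewise-linear
#'   transforms.
#' @return an object of class `cox_risk_model` / `logistic_risk_model`
#'   (both inherit `risk_model`).
#' @rdname risk_model
#' @export
cox_risk_model <- function(coefficients, baseline_survival_at_horizon,
                           transforms = NULL, transform_args = list()) {
  if (baseline_survival_at_horizon <= 0 || baseline_survival_at_horizon > 1)
    stopf("baseline_survival_at_horizon must be in (0, 1]")
  new_risk_model("cox_risk_model", coefficients, transforms, transform_args,
                 baseline_survival_at_horizon = baseline_survival_at_horizon)
}

#' @param intercept logistic-model intercept on the log-odds scale.
#' @rdname risk_model
#' @export
logistic_risk_model <- function(intercept, coefficients, transforms = NULL,
                                transform_args = list()) {
  new_risk_model("logistic_risk_model", coefficients, transforms,
                 transform_args, intercept = intercept)
}

new_risk_model <- function(class, coefficients, transforms, transform_args, ...) {
  if (is.null(names(coefficients)) || any(names(coefficients) == ""))
    stopf("coefficients must be named")
  tr <- stats::setNames(rep("identity", length(coefficients)), names(coefficients))
  if (!is.null(transforms)) {
    bad <- setdiff(names(transforms), names(coefficients))
    if (length(bad)) stopf("transform for unknown covariate: %s", bad[1])
    ok <- transforms %in% c("identity", "log1p", "pw_linear")
    if (!all(ok)) stopf("unknown transform kind '%s'", transforms[!ok][1])
    tr[names(transforms)] <- transforms
  }
  structure(list(coefficients = coefficients, transforms = tr,
                 transform_args = transform_args, ...),
            class = c(class, "risk_model"))
}

apply_transform <- function(x, kind, args = NULL) {
  switch(kind,
         identity = x,
         log1p = log1p(x),
         pw_linear = {
           if (is.null(args$knots)) stopf("pw_linear transform needs knots")
           kx <- vapply(args$knots, `[`, numeric(1), 1)
           ky <- vapply(args$knots, `[`, numeric(1), 2)
           stats::approx(kx, ky, xout = x, rule = 2)$y
         },
         stopf("unknown transform '%s'", kind))
}

#' Linear predictor of a risk model
#'
#' `sum(beta_i * t_i(x_i))` over the model's covariates with transforms
#' applied. Vectorised over persons: `persons` may be a single-row or
#' multi-row data.frame.
#'
#' @param model a `risk_model`.
#' @param persons data.frame supplying every covariate the model names
#'   (sex may be given as "F"/"M" and is converted to 0/1).
#' @return numeric vector, one linear predictor per row.
#' @export
linear_predictor <- function(model, persons) {
  stopifnot(inherits(model, "risk_model"))
  if (inherits(persons, "population")) persons <- persons$persons
  lp <- numeric(nrow(persons))
  for (cov in names(model$coefficients)) {
    if (!cov %in% names(persons))
      stopf("person data lacks covariate '%s' required by the risk model", cov)
    x <- persons[[cov]]
    if (cov == "sex" && is.character(x)) x <- as.numeric(x == "M")
    lp <- lp + model$coefficients[[cov]] *
      apply_transform(x, model$transforms[[cov]],
                      model$transform_args[[cov]])
  }
  lp
}

#' 1-year CRC risk under the Cox model form
#'
#' @inheritParams linear_predictor
#' @return risk probabilities in [0, 1).
#' @export
cox_risk <- function(model, persons) {
  stopifnot(inherits(model, "cox_risk_model"))
  s0 <- model$baseline_survival_at_horizon
  1 - s0^exp(linear_predictor(model, persons))
}

#' CRC risk under the logistic model form
#'
#' @inheritParams linear_predictor
#' @return risk probabilities in (0, 1).
#' @export
logistic_risk <- function(model, persons) {
  stopifnot(inherits(model, "logistic_risk_model"))
  stats::plogis(model$intercept + linear_predictor(model, persons))
}

#' Predicted risk, dispatching on model form
#' @inheritParams linear_predictor
#' @export
predict_risk <- function(model, persons) {
  if (inherits(model, "cox_risk_model")) cox_risk(model, persons)
  else if (inherits(model, "logistic_risk_model")) logistic_risk(model, persons)
  else stopf("not a risk model")
}

#' Calibrate a model's baseline parameter to a target mean risk
#'
#' Solves (by monotone root-finding) for the Cox baseline survival or
#' logistic intercept such that the model's mean predicted risk over a
#' reference population equals `target`. This is how the shipped stand-in
#' models were pinned to the 1-year CRC incidence of the cohorts they
#' emulate (1.2% validation-style, 1.5% derivation-style).
#'
#' @param model a `risk_model`.
#' @param persons reference population (data.frame or `population`).
#' @param target target mean risk in (0, 1).
#' @return the model with its baseline parameter replaced.
#' @export
calibrate_risk_model <- function(model, persons, target) {
  stopifnot(target > 0, target < 1)
  lp <- linear_predictor(model, persons)
  if (inherits(model, "cox_risk_model")) {
    f <- function(log_h0) mean(1 - exp(-exp(log_h0 + lp))) - target
    r <- stats::uniroot(f, c(-40, 10), tol = 1e-12)
    model$baseline_survival_at_horizon <- exp(-exp(r$root))
  } else {
    f <- function(a) mean(stats::plogis(a + lp)) - target
    r <- stats::uniroot(f, c(-40, 40), tol = 1e-12)
    model$intercept <- r$root
  }
  model
}

#' Default synthetic stand-in risk models
#'
#' Coefficients are plausible, hand-set values (FIT on the log1p scale,
#' age, male sex, haemoglobin, MCV, platelets) -- a synthetic stand-in for
#' the confidential fitted algorithm, calibrated so the mean 1-year risk
#' over the default validation-style population is 1.2%. Relative to a
#' FIT-only rule at matched cancer detection, the score shifts referrals
#' towards older patients because of its age term.
#'
#' @return a `cox_risk_model` / `logistic_risk_model`.
#' @rdname default_risk_models
#' @export
default_cox_model <- function() {
  cox_risk_model(
    coefficients = c(fit = 0.72, age = 0.042, sex = 0.35,
                     haemoglobin = -0.025, mcv = -0.04, platelets = 0.0025),
    transforms = c(fit = "log1p"),
    baseline_survival_at_horizon = .default_cox_s0
  )
}

#' @rdname default_risk_models
#' @export
default_logistic_model <- function() {
  logistic_risk_model(
    intercept = .default_logistic_intercept,
    coefficients = c(fit = 0.75, age = 0.045, sex = 0.35,
                     haemoglobin = -0.026, mcv = -0.042, platelets = 0.0026),
    transforms = c(fit = "log1p")
  )
}

# calibration constants frozen from calibrate_risk_model() against a 2e6
# draw of the default validation-style population (mean 1-year risk 1.2%)
.default_cox_s0 <- 0.95320323307808
.default_logistic_intercept <- -2.99392861497705

#' Read / write a risk model as a YAML file
#'
#' File schema: `kind: cox|logistic`, `baseline_survival_at_horizon` or
#' `intercept`, `coefficients: {name: value}`, optional
#' `transforms: {name: kind}`.
#'
#' @param path file path.
#' @rdname risk_model_io
#' @export
read_risk_model <- function(path) {
  y <- yaml::read_yaml(path)
  coefs <- unlist(y$coefficients)
  tr <- if (!is.null(y$transforms)) unlist(y$transforms)
  if (identical(y$kind, "cox"))
    cox_risk_model(coefs, y$baseline_survival_at_horizon, tr)
  else if (identical(y$kind, "logistic"))
    logistic_risk_model(y$intercept, coefs, tr)
  else stopf("unknown risk model kind '%s'", y$kind %||% "<missing>")
}

#' @param model a `risk_model`.
#' @rdname risk_model_io
#' @export
write_risk_model <- function(model, path) {
  y <- list(kind = if (inherits(model, "cox_risk_model")) "cox" else "logistic",
            coefficients = as.list(model$coefficients),
            transforms = as.list(model$transforms))
  if (inherits(model, "cox_risk_model"))
    y$baseline_survival_at_horizon <- model$baseline_survival_at_horizon
  else y$intercept <- model$intercept
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}
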