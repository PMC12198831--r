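#' Referral strategy
#'
#' A referral rule for the urgent-suspected-cancer (USC) pathway: a FIT
#' threshold in ug Hb/g faeces, a risk-score threshold (Cox or logistic
#' form) on the probability scale, or refer-all. The comparison is
#' inclusive: scores equal to or above the threshold are referred.
#'
#' @param kind one of `"fit"`, `"cox"`, `"logistic"`, `"refer_all"`.
#' @param threshold referral threshold: ug Hb/g for `"fit"` (e.g. 10, 13,
#'   28, 40), a probability for the risk-score kinds (e.g. 0.0064, 0.01,
#'   0.02, 0.03). Ignored for `"refer_all"`.
#' @param label display label; defaults to e.g. `"FIT 10"` or
#'   `"score 0.64%"`.
#' @return an object of class `strategy`.
#' @export
strategy <- function(kind = c("fit", "cox", "logistic", "refer_all"),
                     threshold = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (kind != "refer_all") {
    if (is.null(threshold)) stopf("strategy kind '%s' needs a threshold", kind)
    if (threshold < 0) stopf("threshold must be >= 0")
    if (kind %in% c("cox", "logistic") && threshold > 1)
      stopf("risk thresholds are probabilities (<= 1)")
  } else threshold <- NA_real_
  if (is.null(label)) {
    label <- switch(kind,
                    refer_all = "refer all",
                    fit = sprintf("FIT %g", threshold),
                    sprintf("%s score %.4g%%", kind, 100 * threshold))
  }
  structure(list(kind = kind, threshold = threshold, label = label),
            class = "strategy")
}

#' Apply a referral strategy to a population
#'
#' @param pop a `population` (or persons data.frame).
#' @param strat a [strategy()].
#' @param risk_model required for the risk-score kinds; ignored otherwise.
#' @param risks optional precomputed per-person risks (skips model
#'   evaluation).
#' @return logical vector: `TRUE` where the person is referred to USC.
#' @export
stratify <- function(pop, strat, risk_model = NULL, risks = NULL) {
  stopifnot(inherits(strat, "strategy"))
  persons <- if (inherits(pop, "population")) pop$persons else pop
  switch(strat$kind,
         refer_all = rep(TRUE, nrow(persons)),
         fit = persons$fit >= strat$threshold,
         {
           if (is.null(risks)) {
             if (is.null(risk_model))
               stopf("strategy kind '%s' needs a risk model or precomputed risks",
                     strat$kind)
             risks <- predict_risk(risk_model, persons)
           }
           risks >= strat$threshold
         })
}

#' Diagnostic performance of a referral rule
#'
#' Counting definitions against known disease flags: sensitivity =
#' referred cancers / cancers; specificity = non-referred non-cancers /
#' non-cancers; PPV = referred cancers / referrals.
#'
#' @param referred logical referral vector.
#' @param true_flags logical disease indicator, same length.
#' @return a one-row data.frame with `referrals`, `detected`,
#'   `sensitivity`, `specificity`, `ppv`.
#' @export
performance_summary <- function(referred, true_flags) {
  if (length(referred) != length(true_flags))
    stopf("referral and disease vectors differ in length")
  tp <- sum(referred & true_flags)
  data.frame(
    referrals = sum(referred),
    detected = tp,
    sensitivity = if (any(true_flags)) tp / sum(true_flags) else NA_real_,
    specificity = if (any(!true_flags)) sum(!referred & !true_flags) / sum(!true_flags) else NA_real_,
    ppv = if (any(referred)) tp / sum(referred) else NA_real_
  )
}
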