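#' Marginal distribution specified by a quantile grid
#'
#' Aggregate data releases for the populations this package emulates consist
#' of per-variable quantile tables rather than raw records. A
#' `marginal_spec` captures one such table: an ordered grid of
#' (probability, value) pairs interpreted as the inverse CDF of the
#' variable, plus optional clipping bounds. Generated latent ranks are
#' "refitted" onto this grid by monotone linear interpolation, so the
#' synthetic marginal reproduces the published quantiles.
#'
#' @param variable name of the variable (e.g. `"fit"`, `"age"`).
#' @param probs numeric vector of probabilities, strictly increasing,
#'   in [0, 1].
#' @param values numeric vector of the variable's quantiles at `probs`,
#'   non-decreasing.
#' @param transform transformation used on the original scale before
#'   correlation modelling (`"identity"`, `"log"`, `"logit"`). Recorded as
#'   metadata: generation samples latent Gaussians directly, so the
#'   transform does not alter the generated values, but it documents the
#'   scale on which the source correlation matrix was estimated.
#' @param lower_bound,upper_bound optional clip values in the variable's
#'   units; must bracket all grid values.
#' @param binary if `TRUE` the variable is 0/1: `values` must be `c(0, 1)`
#'   and `probs[1]` is the probability of the 0 level.
#' @return an object of class `marginal_spec`.
#' @examples
#' fit_m <- marginal_spec("fit", probs = c(.1, .5, .9, .99),
#'                        values = c(0, 2, 40, 300), lower_bound = 0)
#' apply_quantile_refit(c(0.1, 0.5, 0.9), fit_m)
#' @export
marginal_spec <- function(variable, probs, values,
                          transform = c("identity", "log", "logit"),
                          lower_bound = NULL, upper_bound = NULL,
                          binary = FALSE) {
  transform <- match.arg(transform)
  if (length(probs) == 0L) stopf("empty quantile grid for '%s'", variable)
  if (length(probs) != length(values))
    stopf("probs/values length mismatch for '%s'", variable)
  if (any(diff(probs) <= 0)) stopf("probabilities must be strictly increasing ('%s')", variable)
  assert_prob(probs, "probs")
  if (any(diff(values) < 0)) stopf("quantile values must be non-decreasing ('%s')", variable)
  if (binary && !identical(sort(unique(values)), c(0, 1)))
    stopf("binary marginal '%s' must have values 0/1", variable)
  if (!is.null(lower_bound) && lower_bound > min(values))
    stopf("lower_bound above smallest grid value ('%s')", variable)
  if (!is.null(upper_bound) && upper_bound < max(values))
    stopf("upper_bound below largest grid value ('%s')", variable)
  structure(list(variable = variable, probs = as.numeric(probs),
                 values = as.numeric(values), transform = transform,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 binary = binary),
            class = "marginal_spec")
}

#' Refit raw generated values onto a marginal's quantile grid
#'
#' The quantile-refitting step of the copula generator: a monotone,
#' rank-preserving remap of raw values onto the target marginal. Values in
#' [0, 1] are treated as uniform ranks; values on any other scale (e.g. the
#' latent standard-normal scale) are first converted to ranks through the
#' standard-normal CDF. Ranks are then pushed through the grid's inverse
#' CDF by linear interpolation, flat beyond the outermost grid points, and
#' clipped to the spec's bounds.
#'
#' @param raw_values numeric vector of ranks in [0, 1] or latent
#'   standard-normal values.
#' @param spec a [marginal_spec()].
#' @return numeric vector, same length and ordering as `raw_values`.
#' @export
apply_quantile_refit <- function(raw_values, spec) {
  stopifnot(inherits(spec, "marginal_spec"))
  u <- raw_values
  if (any(!is.finite(u))) stopf("raw_values must be finite")
  if (any(u < 0 | u > 1)) u <- stats::pnorm(u)
  if (spec$binary) {
    p0 <- spec$probs[match(0, spec$values)]
    return(as.numeric(u > p0))
  }
  if (length(spec$probs) == 1L) {
    out <- rep(spec$values, length(u))
  } else {
    out <- stats::approx(spec$probs, spec$values, xout = u,
                         rule = 2, ties = "ordered")$y
  }
  if (!is.null(spec$lower_bound)) out <- pmax(out, spec$lower_bound)
  if (!is.null(spec$upper_bound)) out <- pmin(out, spec$upper_bound)
  out
}
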