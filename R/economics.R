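#' Economic evaluation configuration
#'
#' @param wtp willingness-to-pay per QALY in GBP (default 20000).
#' @param discount_rate annual discount rate (default 0.035; scenario
#'   values 0.05 and 0.015).
#' @param scale reporting scale in persons (default one million).
#' @param currency_year price year (metadata; default 2023).
#' @return an object of class `economics_config`.
#' @export
economics_config <- function(wtp = 20000, discount_rate = 0.035,
                             scale = 1e6, currency_year = 2023) {
  if (wtp < 0) stopf("wtp must be >= 0")
  if (discount_rate < 0) stopf("discount_rate must be >= 0")
  structure(list(wtp = wtp, discount_rate = discount_rate, scale = scale,
                 currency_year = currency_year),
            class = "economics_config")
}

#' Aggregate person-level results into a strategy outcome
#'
#' Sums lifetime and short-term person-level results and rescales to the
#' reporting scale (per million by default) with the exact multiplier
#' `scale / n` applied after summation.
#'
#' @param lifecourse data.frame from [run_lifecourse_population()].
#' @param diag data.frame from [run_pathway()].
#' @param cfg an [economics_config()].
#' @param label strategy label.
#' @return one-row data.frame of class `strategy_outcome`: `cost`, `qaly`,
#'   `ly` (discounted), `crc_deaths`, `usc_referrals`,
#'   `usc_crc_diagnoses`, plus `n` and `scale`.
#' @export
aggregate_outcomes <- function(lifecourse, diag, cfg, label = "strategy") {
  n <- nrow(lifecourse)
  if (n == 0L) stopf("no person-level results to aggregate")
  if (nrow(diag) != n) stopf("lifecourse/diagnostic row mismatch")
  mult <- cfg$scale / n
  out <- data.frame(
    strategy = label,
    cost = sum(lifecourse$discounted_cost) * mult,
    qaly = sum(lifecourse$discounted_qaly) * mult,
    ly = sum(lifecourse$discounted_ly) * mult,
    undiscounted_cost = sum(lifecourse$undiscounted_cost) * mult,
    undiscounted_qaly = sum(lifecourse$undiscounted_qaly) * mult,
    crc_deaths = sum(lifecourse$crc_death_probability) * mult,
    usc_referrals = sum(diag$referred) * mult,
    usc_crc_diagnoses = sum(diag$crc_detected_usc) * mult,
    n = n, scale = cfg$scale
  )
  class(out) <- c("strategy_outcome", class(out))
  out
}

#' Incremental net monetary benefit
#'
#' `INMB = wtp * dQ - dC`.
#'
#' @param delta_cost incremental cost (GBP).
#' @param delta_qaly incremental QALYs.
#' @param wtp willingness-to-pay per QALY.
#' @return INMB in GBP.
#' @examples
#' inmb(-6.6e6, -45, 20000)  # 5.7e6
#' @export
inmb <- function(delta_cost, delta_qaly, wtp = 20000) {
  wtp * delta_qaly - delta_cost
}

#' Pairwise incremental comparison of two strategy outcomes
#'
#' Component-wise `a - b` with INMB at the configured willingness-to-pay;
#' antisymmetric by construction. The ICER is also reported but flagged
#' (`icer_sign_mixed`) when the cost and QALY deltas disagree in sign,
#' where an ICER is misleading.
#'
#' @param a,b `strategy_outcome` rows (same scale).
#' @param cfg an [economics_config()].
#' @return one-row data.frame of deltas plus `inmb`.
#' @export
incremental <- function(a, b, cfg = economics_config()) {
  if (a$scale != b$scale) stopf("strategy outcomes use different scales")
  d <- data.frame(
    comparison = sprintf("%s vs %s", a$strategy, b$strategy),
    delta_cost = a$cost - b$cost,
    delta_qaly = a$qaly - b$qaly,
    delta_ly = a$ly - b$ly,
    delta_crc_deaths = a$crc_deaths - b$crc_deaths,
    delta_usc_referrals = a$usc_referrals - b$usc_referrals,
    delta_usc_crc_diagnoses = a$usc_crc_diagnoses - b$usc_crc_diagnoses
  )
  d$inmb <- inmb(d$delta_cost, d$delta_qaly, cfg$wtp)
  d$icer <- ifelse(d$delta_qaly != 0, d$delta_cost / d$delta_qaly, NA_real_)
  d$icer_sign_mixed <- sign(d$delta_cost) * sign(d$delta_qaly) < 0
  d
}

default_age_bands <- function() {
  data.frame(band = c("<50", "50-69", ">=70"),
             lo = c(18, 50, 70), hi = c(50, 70, 100.0001))
}

#' Strategy outcomes by age band and sex subgroup
#'
#' Partitions persons into (band, sex) cells and aggregates each cell.
#' Unscaled cell sums reconcile exactly with the whole-population sums.
#'
#' @param pop a `population`.
#' @param lifecourse,diag person-level result tables.
#' @param cfg an [economics_config()].
#' @param bands data.frame `band, lo, hi` partitioning ages 18-100
#'   (band is `lo <= age < hi`); default `<50`, `50-69`, `>=70`.
#' @param label strategy label.
#' @return data.frame with one `strategy_outcome` row per cell.
#' @export
subgroup_outcomes <- function(pop, lifecourse, diag, cfg,
                              bands = default_age_bands(),
                              label = "strategy") {
  persons <- pop$persons
  idx <- findInterval(persons$age, c(bands$lo, max(bands$hi)))
  if (any(idx < 1 | idx > nrow(bands)))
    stopf("person age %s falls outside all bands",
          persons$age[which(idx < 1 | idx > nrow(bands))[1]])
  rows <- list()
  for (b in seq_len(nrow(bands))) for (s in c("F", "M")) {
    sel <- idx == b & persons$sex == s
    if (!any(sel)) next
    cell_cfg <- cfg
    cell_cfg$scale <- sum(sel)  # unscaled: raw cell sums
    r <- aggregate_outcomes(lifecourse[sel, , drop = FALSE],
                            diag[sel, , drop = FALSE], cell_cfg, label)
    r$age_band <- bands$band[b]
    r$sex <- s
    rows[[length(rows) + 1L]] <- r
  }
  do.call(rbind, rows)
}

#' Mean QALY loss per delayed CRC diagnosis in an age band
#'
#' For every CRC case in the band, the lifetime model is run twice on the
#' same person: once as if diagnosed immediately at the baseline stage and
#' once with the person's sampled delay (stage shift applied). The
#' reported value is the mean discounted QALY difference
#' (immediate - delayed) over cases in the band.
#'
#' @param pop a `population`.
#' @param states baseline states.
#' @param diag diagnostic outcomes (delays taken from
#'   `crc_diagnosis_delay`).
#' @param tables a [markov_tables()].
#' @param econ an [economics_config()].
#' @param band numeric length-2: ages `[lo, hi)` defining the band.
#' @return mean QALY loss per delayed case (>= 0 under progressive
#'   disease).
#' @export
qaly_loss_per_delayed_diagnosis <- function(pop, states, diag, tables, econ,
                                            band = c(18, 50)) {
  persons <- pop$persons
  sel <- states$crc_stage != "none" & !diag$crc_detected_usc &
    persons$age >= band[1] & persons$age < band[2]
  if (!any(sel)) stopf("no delayed CRC cases in band [%g, %g)", band[1], band[2])
  cache <- new.env(parent = emptyenv())
  losses <- vapply(which(sel), function(i) {
    a0 <- as.integer(floor(persons$age[i]))
    sx <- persons$sex[i]
    st <- as.character(states$crc_stage[i])
    immediate <- cached_crc_trace(cache, a0, sx, st, 0L, tables,
                                  econ$discount_rate, 100)[["dq"]]
    res <- lifecourse_one(persons$age[i], sx, st, "none", FALSE, FALSE,
                          diag$crc_diagnosis_delay[i], FALSE, FALSE, 0, 0,
                          tables, econ, "base", cache)
    immediate - res$trace[["dq"]]
  }, numeric(1))
  mean(losses)
}
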