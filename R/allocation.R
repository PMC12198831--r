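#' Baseline disease prevalence configuration
#'
#' Parameters governing allocation of the underlying, mutually exclusive
#' colorectal state (CRC stage I-IV, high- or low-risk adenoma, normal
#' epithelium) and the independent IBD flag.
#'
#' @param crc_stage_distribution probabilities over stages I-IV at
#'   baseline, summing to 1.
#' @param hr_adenoma_prevalence named vector `c(fit_ge10 = , fit_lt10 = )`:
#'   high-risk adenoma prevalence by FIT stratum.
#' @param lr_adenoma_prevalence low-risk adenoma prevalence (allocated
#'   uniformly).
#' @param ibd_prevalence data.frame with columns `age_lo`, `age_hi`
#'   (half-open bands `[lo, hi)`), `fit_stratum` (`"lt10"`/`"ge10"`),
#'   `prob`. Bands must cover ages 18-100 in both strata.
#' @param prevalence_scaling multiplier on per-person CRC risk (default 1;
#'   exposed so user-supplied risk models can be rescaled to a target
#'   prevalence).
#' @return an object of class `prevalence_config`.
#' @export
prevalence_config <- function(crc_stage_distribution = c(I = 0.24, II = 0.26,
                                                         III = 0.31, IV = 0.19),
                              hr_adenoma_prevalence = c(fit_ge10 = 0.08,
                                                        fit_lt10 = 0.015),
                              lr_adenoma_prevalence = 0.10,
                              ibd_prevalence = default_ibd_prevalence(),
                              prevalence_scaling = 1) {
  if (abs(sum(crc_stage_distribution) - 1) > 1e-9)
    stopf("crc_stage_distribution must sum to 1")
  assert_prob(crc_stage_distribution, "crc_stage_distribution")
  assert_prob(hr_adenoma_prevalence, "hr_adenoma_prevalence")
  assert_prob(lr_adenoma_prevalence, "lr_adenoma_prevalence")
  assert_prob(ibd_prevalence$prob, "ibd_prevalence$prob")
  if (prevalence_scaling < 0) stopf("prevalence_scaling must be >= 0")
  structure(list(crc_stage_distribution = crc_stage_distribution,
                 hr_adenoma_prevalence = hr_adenoma_prevalence,
                 lr_adenoma_prevalence = lr_adenoma_prevalence,
                 ibd_prevalence = ibd_prevalence,
                 prevalence_scaling = prevalence_scaling),
            class = "prevalence_config")
}

#' Default IBD prevalence table (synthetic stand-in)
#'
#' IBD probability by decade of age and FIT stratum. IBD is more prevalent
#' in the young than cancer and is associated with raised FIT, so rates
#' decline with age and are markedly higher in the FIT >= 10 stratum.
#'
#' @return a data.frame with columns `age_lo`, `age_hi`, `fit_stratum`,
#'   `prob`.
#' @export
default_ibd_prevalence <- function() {
  bands <- data.frame(age_lo = c(18, 30, 40, 50, 60, 70, 80),
                      age_hi = c(30, 40, 50, 60, 70, 80, 101))
  ge10 <- c(0.090, 0.070, 0.050, 0.035, 0.025, 0.018, 0.012)
  lt10 <- c(0.012, 0.009, 0.007, 0.005, 0.004, 0.003, 0.002)
  rbind(cbind(bands, fit_stratum = "ge10", prob = ge10),
        cbind(bands, fit_stratum = "lt10", prob = lt10))
}

stage_levels <- c("none", "I", "II", "III", "IV")

#' Allocate CRC status and stage at baseline
#'
#' Each person receives CRC with probability `prevalence_scaling * risk`
#' (capped at 1, with a warning counting capped persons); cases draw a
#' stage from the configured baseline stage distribution, independently.
#'
#' @param pop a `population`.
#' @param risks per-person 1-year CRC risk in [0, 1].
#' @param cfg a [prevalence_config()].
#' @param seed integer seed.
#' @return factor of `"none","I","II","III","IV"`, one per person.
#' @export
allocate_crc <- function(pop, risks, cfg, seed) {
  persons <- pop$persons
  if (length(risks) != nrow(persons)) stopf("risks length mismatch")
  assert_prob(risks, "risks")
  p <- cfg$prevalence_scaling * risks
  n_capped <- sum(p > 1)
  if (n_capped > 0) {
    warning(sprintf("%d scaled risks exceeded 1 and were capped", n_capped))
    p <- pmin(p, 1)
  }
  set.seed(derive_seed(seed, stream = 11L))
  has_crc <- stats::runif(length(p)) < p
  stage <- rep("none", length(p))
  if (any(has_crc))
    stage[has_crc] <- sample(names(cfg$crc_stage_distribution), sum(has_crc),
                             replace = TRUE, prob = cfg$crc_stage_distribution)
  factor(stage, levels = stage_levels)
}

#' Allocate adenoma states among CRC-free persons
#'
#' High-risk adenomas are allocated within each FIT stratum (>= 10 /
#' < 10) at the stratum prevalence, weighted proportionally to the
#' person's risk score (weights scaled so the stratum mean equals the
#' stratum prevalence, capped at 1). Low-risk adenomas are then allocated
#' uniformly among the remaining CRC- and HR-adenoma-free persons.
#'
#' @param pop a `population`.
#' @param crc_stage factor from [allocate_crc()].
#' @param risk_scores per-person risk scores (used only for within-stratum
#'   weighting).
#' @inheritParams allocate_crc
#' @return factor of `"none","low_risk","high_risk"`, one per person
#'   (always `"none"` for CRC cases).
#' @export
allocate_adenomas <- function(pop, crc_stage, risk_scores, cfg, seed) {
  persons <- pop$persons
  n <- nrow(persons)
  stopifnot(length(crc_stage) == n, length(risk_scores) == n)
  eligible <- crc_stage == "none"
  p_hr <- numeric(n)
  for (s in c("ge10", "lt10")) {
    in_s <- eligible & (if (s == "ge10") persons$fit >= 10 else persons$fit < 10)
    if (!any(in_s)) next
    prev <- cfg$hr_adenoma_prevalence[[paste0("fit_", s)]]
    w <- risk_scores[in_s]
    mw <- mean(w)
    p_hr[in_s] <- if (mw > 0) pmin(prev * w / mw, 1) else prev
  }
  set.seed(derive_seed(seed, stream = 12L))
  hr <- stats::runif(n) < p_hr & eligible
  lr_pool <- eligible & !hr
  lr <- stats::runif(n) < cfg$lr_adenoma_prevalence & lr_pool
  out <- rep("none", n)
  out[lr] <- "low_risk"
  out[hr] <- "high_risk"
  factor(out, levels = c("none", "low_risk", "high_risk"))
}

#' Allocate the IBD flag by age band and FIT stratum
#'
#' @inheritParams allocate_adenomas
#' @return logical vector, independent of the colorectal state.
#' @export
allocate_ibd <- function(pop, cfg, seed) {
  persons <- pop$persons
  tab <- cfg$ibd_prevalence
  stratum <- ifelse(persons$fit >= 10, "ge10", "lt10")
  p <- rep(NA_real_, nrow(persons))
  for (i in seq_len(nrow(tab))) {
    sel <- stratum == tab$fit_stratum[i] &
      persons$age >= tab$age_lo[i] & persons$age < tab$age_hi[i]
    p[sel] <- tab$prob[i]
  }
  if (anyNA(p))
    stopf("IBD prevalence table does not cover age %s (stratum %s)",
          persons$age[which(is.na(p))[1]], stratum[which(is.na(p))[1]])
  set.seed(derive_seed(seed, stream = 13L))
  stats::runif(nrow(persons)) < p
}

#' Allocate the full baseline health state for a population
#'
#' Convenience wrapper running [allocate_crc()], [allocate_adenomas()] and
#' [allocate_ibd()] with one seed. The colorectal state is mutually
#' exclusive (CRC cases cannot also carry an adenoma); IBD is an
#' independent flag.
#'
#' @inheritParams allocate_crc
#' @return data.frame `person_id`, `crc_stage`, `adenoma`, `ibd`.
#' @export
allocate_baseline_states <- function(pop, risks, cfg, seed) {
  crc <- allocate_crc(pop, risks, cfg, seed)
  ade <- allocate_adenomas(pop, crc, risks, cfg, seed)
  ibd <- allocate_ibd(pop, cfg, seed)
  data.frame(person_id = pop$persons$id, crc_stage = crc,
             adenoma = ade, ibd = ibd)
}
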