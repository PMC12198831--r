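#' Read / write a population configuration as YAML
#'
#' File schema mirrors [population_config()]: `cohort_label`, `n`, `seed`,
#' `recent_fbc_probability`, `marginals` (a map of variable name to
#' `probs`, `values`, optional `transform`, `lower_bound`, `upper_bound`,
#' `binary`) and `correlation` (list of rows, ordered as the marginals).
#'
#' @param path YAML file path.
#' @rdname population_config_io
#' @export
read_population_config <- function(path) {
  y <- yaml::read_yaml(path)
  marginals <- lapply(names(y$marginals), function(v) {
    m <- y$marginals[[v]]
    marginal_spec(v, probs = unlist(m$probs), values = unlist(m$values),
                  transform = m$transform %||% "identity",
                  lower_bound = m$lower_bound, upper_bound = m$upper_bound,
                  binary = isTRUE(m$binary))
  })
  names(marginals) <- names(y$marginals)
  R <- do.call(rbind, lapply(y$correlation, unlist))
  dimnames(R) <- list(names(marginals), names(marginals))
  population_config(marginals, R, n = y$n, seed = y$seed,
                    recent_fbc_probability = y$recent_fbc_probability %||% 0.91,
                    cohort_label = y$cohort_label %||% "custom")
}

#' @param config a [population_config()].
#' @rdname population_config_io
#' @export
write_population_config <- function(config, path) {
  stopifnot(inherits(config, "population_config"))
  marg <- lapply(config$marginals, function(m) {
    out <- list(probs = m$probs, values = m$values, transform = m$transform)
    if (!is.null(m$lower_bound)) out$lower_bound <- m$lower_bound
    if (!is.null(m$upper_bound)) out$upper_bound <- m$upper_bound
    if (m$binary) out$binary <- TRUE
    out
  })
  y <- list(cohort_label = config$cohort_label, n = config$n,
            seed = config$seed,
            recent_fbc_probability = config$recent_fbc_probability,
            marginals = marg,
            correlation = lapply(seq_len(nrow(config$correlation)),
                                 function(i) as.numeric(config$correlation[i, ])))
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Read / write a disease prevalence configuration as YAML
#'
#' Schema mirrors [prevalence_config()]; the IBD table is a list of rows
#' with `age_lo`, `age_hi`, `fit_stratum`, `prob`.
#'
#' @param path YAML file path.
#' @rdname prevalence_config_io
#' @export
read_prevalence_config <- function(path) {
  y <- yaml::read_yaml(path)
  ibd <- if (!is.null(y$ibd_prevalence))
    do.call(rbind, lapply(y$ibd_prevalence, as.data.frame))
  else default_ibd_prevalence()
  prevalence_config(
    crc_stage_distribution = unlist(y$crc_stage_distribution),
    hr_adenoma_prevalence = unlist(y$hr_adenoma_prevalence),
    lr_adenoma_prevalence = y$lr_adenoma_prevalence,
    ibd_prevalence = ibd,
    prevalence_scaling = y$prevalence_scaling %||% 1)
}

#' @param config a [prevalence_config()].
#' @rdname prevalence_config_io
#' @export
write_prevalence_config <- function(config, path) {
  stopifnot(inherits(config, "prevalence_config"))
  y <- list(crc_stage_distribution = as.list(config$crc_stage_distribution),
            hr_adenoma_prevalence = as.list(config$hr_adenoma_prevalence),
            lr_adenoma_prevalence = config$lr_adenoma_prevalence,
            ibd_prevalence = lapply(seq_len(nrow(config$ibd_prevalence)),
                                    function(i) as.list(config$ibd_prevalence[i, ])),
            prevalence_scaling = config$prevalence_scaling)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}
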