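# Shared fixtures: all built in code at test time.

# hand-checkable lifetime tables: flat 0.8 utility, 10% annual all-cause
# mortality, flat stage-specific CRC mortality, simple costs
toy_tables <- function(stage_I_II = 0.4, II_III = 0, III_IV = 0) {
  life <- expand.grid(age = 0:100, sex = c("F", "M"),
                      stringsAsFactors = FALSE)
  life$annual_death_prob <- ifelse(life$age == 100, 1, 0.1)
  surv <- expand.grid(stage = c("I", "II", "III", "IV"), sex = c("F", "M"),
                      age_band = c("18-49", "50-69", "70+"),
                      year_since_dx = 1:10, stringsAsFactors = FALSE)
  surv$annual_death_prob <- c(I = 0.1, II = 0.2, III = 0.3, IV = 0.5)[surv$stage]
  uc <- default_utility_cost_table()
  uc$general_utility[] <- 0.8
  uc$stage_utility_mult[] <- 0
  uc$stage_utility_mult["I", ] <- c(0.9, 0.95)
  uc$stage_utility_mult["II", ] <- c(0.75, 0.9)
  uc$stage_utility_mult["III", ] <- c(0.6, 0.7)
  uc$stage_utility_mult["IV", ] <- c(0.4, 0.4)
  uc$stage_cost[] <- 0
  uc$stage_cost["I", ] <- c(500, 50)
  uc$stage_cost["II", ] <- c(1000, 100)
  uc$stage_cost["III", ] <- c(2000, 200)
  uc$stage_cost["IV", ] <- c(4000, 400)
  uc$terminal_cost <- 500
  markov_tables(
    transition = transition_params(
      stage_progression = c(I_II = stage_I_II, II_III = II_III,
                            III_IV = III_IV),
      fast_stage_progression = c(I_II = max(stage_I_II, 0.6),
                                 II_III = max(II_III, 0.7),
                                 III_IV = max(III_IV, 0.8))),
    survival = surv, life = life, utility_cost = uc)
}

# deathless tables with perfect (1.0) utility: closed-form LY/QALY checks
immortal_tables <- function() {
  life <- expand.grid(age = 0:100, sex = c("F", "M"),
                      stringsAsFactors = FALSE)
  life$annual_death_prob <- ifelse(life$age == 100, 1, 0)
  uc <- default_utility_cost_table()
  uc$general_utility[] <- 1
  markov_tables(survival = default_survival_table(), life = life,
                utility_cost = uc)
}

# a no-op diagnostic outcome row (no referral, zero short-term totals)
blank_diag <- function(n = 1) {
  data.frame(person_id = seq_len(n), referred = FALSE, attended = FALSE,
             investigation = "none", crc_detected_usc = FALSE,
             crc_diagnosis_delay = 0, adenoma_detected = FALSE,
             ibd_detected_usc = FALSE, ibd_diagnosis_delay = 0,
             emergency_presentation = FALSE, short_term_cost = 0,
             short_term_qaly_loss = 0)
}

blank_state <- function(n = 1, crc_stage = "none", adenoma = "none",
                        ibd = FALSE) {
  data.frame(person_id = seq_len(n), crc_stage = crc_stage,
             adenoma = adenoma, ibd = ibd)
}

small_run_config <- function(n = 2000, seed = 11, strategies = NULL) {
  run_config(n = n, seed = seed,
             strategies = strategies %||% list(strategy("refer_all"),
                                               strategy("fit", 10),
                                               strategy("cox", 0.0064)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
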