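# shared small scenario builders for the unit tests

# single-group scenario with every effect switched off
null_config <- function(n_hospitals = 4L, volume = c(500L, 500L),
                        p_mort = 0.031, p_readm = 0.078, seed = 1L) {
  scenario_config(n_hospitals = n_hospitals, volume_range = volume,
                  groups = list(group_spec("general", p_mort, p_readm, 6.7)),
                  seed = seed)
}

# scenario with hospital effects but configurable case-mix effects
effect_config <- function(n_hospitals = 12L, volume = c(800L, 800L),
                          tau2 = c(mortality = 0.1, readmission = 0.1,
                                   long_los = 0.1),
                          effect_corr = diag(3), cm_effects = NULL,
                          seed = 1L, ...) {
  cm <- if (is.null(cm_effects)) default_casemix() else
    default_casemix(effects = cm_effects)
  scenario_config(n_hospitals = n_hospitals, volume_range = volume,
                  groups = list(group_spec("general", 0.05, 0.08, 7)),
                  tau2 = tau2, effect_corr = effect_corr, casemix = cm,
                  seed = seed, ...)
}

# equal planted effects on all three outcomes (shared latent scale)
shared_effects_df <- function(eta) {
  data.frame(hospital_id = sprintf("H%02d", seq_along(eta)),
             eta_mort = eta, eta_readm = eta, eta_los = eta,
             stringsAsFactors = FALSE)
}

# minimal admission data.frame for direct unit tests of analysis functions
make_records <- function(n, died, long_los, readmitted = NULL,
                         hospital = "H01", group = "g", year = 2010L) {
  data.frame(hospital_id = rep_len(hospital, n), group = rep_len(group, n),
             year = rep_len(year, n),
             age_group = factor(rep_len("55-64", n),
                                levels = c("18-39", "40-54", "55-64",
                                           "65-74", "75+"), ordered = TRUE),
             sex = rep_len(0L, n), unplanned = rep_len(0L, n),
             transfer_in = rep_len(0L, n), urgent_prior = rep_len(0L, n),
             elixhauser = rep_len(0L, n), los_days = rep_len(5, n),
             died = rep_len(as.integer(died), n),
             long_los = rep_len(as.logical(long_los), n),
             readmitted_30d = if (is.null(readmitted)) NA_integer_ else
               rep_len(as.integer(readmitted), n),
             stringsAsFactors = FALSE)
}
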