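#' Build a simulation scenario configuration
#'
#' A scenario describes a set of hospitals, the diagnosis/procedure groups
#' they admit, the planted between-hospital effects on each outcome, and the
#' patient-level couplings between length of stay (LOS) and the binary
#' outcomes.  It is the single source of truth for [generate_cohort()].
#'
#' Hospital effects are drawn on the log-odds scale for all three outcomes.
#' For long LOS the effect is mapped onto the location of the group's
#' log-normal LOS distribution so that a unit of `eta_los` shifts the
#' log-odds of exceeding the group's upper-quartile cutoff by approximately
#' one (see the methods vignette for the conversion).
#'
#' @param n_hospitals number of hospitals.
#' @param volume_range integer length-2 vector, min and max admissions per
#'   hospital; volumes are drawn uniformly on this range.
#' @param groups a list of group specifications, each a list with elements
#'   `name`, `p_mort` (baseline in-hospital mortality), `p_readm` (baseline
#'   30-day readmission among survivors), `los_meanlog`, `los_sdlog`
#'   (log-normal LOS parameters) and optionally `weight` (relative sampling
#'   weight, default 1).
#' @param years integer vector of discharge years.
#' @param year_trend named numeric `c(mortality=, readmission=, long_los=)`,
#'   per-year additive change of each outcome's log-odds (0 = no trend).
#' @param tau2 named numeric `c(mortality=, readmission=, long_los=)`,
#'   between-hospital variances of the planted effects (log-odds^2 scale).
#' @param effect_corr 3x3 correlation matrix of the hospital effects, in the
#'   order mortality, readmission, long_los.  Must be symmetric with unit
#'   diagonal and positive semi-definite.
#' @param coupling_mort_los patient-level log-odds ratio linking the latent
#'   upper-quartile-LOS indicator to mortality.
#' @param coupling_readm_los same, linking it to readmission.
#' @param early_death_short_los logical; when `TRUE`, patients who die have
#'   their LOS re-drawn from a short-LOS distribution (location shifted by
#'   `short_los_shift` on the log scale), emulating conditions where death
#'   occurs early in the admission.
#' @param short_los_shift meanlog shift (log-days) of the short-LOS
#'   distribution used for deaths when `early_death_short_los = TRUE`.
#' @param casemix list describing the case-mix covariate distributions and
#'   effects; see [default_casemix()].
#' @param seed default integer seed used by [generate_cohort()] when no seed
#'   is passed explicitly.
#'
#' @return an object of class `scenario_config` (a validated list).
#' @seealso [scenario_presets()], [generate_cohort()]
#' @export
scenario_config <- function(n_hospitals = 26,
                            volume_range = c(1000L, 4000L),
                            groups = list(group_spec("general", 0.031, 0.078, 6.7)),
                            years = 2007:2012,
                            year_trend = c(mortality = 0, readmission = 0, long_los = 0),
                            tau2 = c(mortality = 0, readmission = 0, long_los = 0),
                            effect_corr = diag(3),
                            coupling_mort_los = 0,
                            coupling_readm_los = 0,
                            early_death_short_los = FALSE,
                            short_los_shift = -1.0,
                            casemix = default_casemix(),
                            seed = 1L) {
  cfg <- structure(list(
    n_hospitals = as.integer(n_hospitals),
    volume_range = as.integer(volume_range),
    groups = groups,
    years = as.integer(years),
    year_trend = year_trend,
    tau2 = tau2,
    effect_corr = effect_corr,
    coupling_mort_los = coupling_mort_los,
    coupling_readm_los = coupling_readm_los,
    early_death_short_los = isTRUE(early_death_short_los),
    short_los_shift = short_los_shift,
    casemix = casemix,
    seed = as.integer(seed)
  ), class = "scenario_config")
  validate_config(cfg)
  cfg
}

#' Describe one diagnosis/procedure group
#'
#' @param name group label.
#' @param p_mort baseline in-hospital mortality probability.
#' @param p_readm baseline 30-day readmission probability among survivors.
#' @param mean_los mean LOS in days; together with `los_sdlog` this fixes the
#'   log-normal location `los_meanlog = log(mean_los) - los_sdlog^2/2`.
#' @param los_sdlog log-scale standard deviation of LOS.
#' @param weight relative sampling weight of the group within a hospital.
#' @return a list usable in the `groups` field of [scenario_config()].
#' @export
group_spec <- function(name, p_mort, p_readm, mean_los, los_sdlog = 0.9,
                       weight = 1) {
  list(name = as.character(name), p_mort = p_mort, p_readm = p_readm,
       los_meanlog = log(mean_los) - los_sdlog^2 / 2,
       los_sdlog = los_sdlog, weight = weight)
}

#' Default case-mix covariate distributions and effects
#'
#' Covariates are age group (five ordered bands), sex, unplanned admission,
#' transfer from another hospital, urgent admission in the previous month and
#' the Elixhauser comorbidity count.  Effects are log-odds ratios applied to
#' *centred* covariates, so setting them does not move the marginal outcome
#' rates away from the group baselines (to first order).
#'
#' @param effects named numeric of log-odds ratios: `age` (per age band),
#'   `sex`, `unplanned`, `transfer_in`, `urgent_prior`, `elixhauser`
#'   (per comorbidity).
#' @param age_probs probabilities of the five age bands.
#' @param sex_p,unplanned_p,transfer_p,urgent_p Bernoulli probabilities.
#' @param elix_mean Poisson mean of the comorbidity count (capped at 12).
#' @return a list for the `casemix` field of [scenario_config()].
#' @export
default_casemix <- function(effects = c(age = 0, sex = 0, unplanned = 0,
                                        transfer_in = 0, urgent_prior = 0,
                                        elixhauser = 0),
                            age_probs = c(0.12, 0.18, 0.25, 0.25, 0.20),
                            sex_p = 0.46, unplanned_p = 0.63,
                            transfer_p = 0.05, urgent_p = 0.52,
                            elix_mean = 1.4) {
  list(effects = effects, age_probs = age_probs, sex_p = sex_p,
       unplanned_p = unplanned_p, transfer_p = transfer_p,
       urgent_p = urgent_p, elix_mean = elix_mean)
}

age_band_labels <- function() c("18-39", "40-54", "55-64", "65-74", "75+")

outcome_names <- function() c("mortality", "readmission", "long_los")

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$n_hospitals < 1L) stop("n_hospitals must be >= 1")
  if (length(cfg$volume_range) != 2L || cfg$volume_range[1] < 1L ||
      cfg$volume_range[2] < cfg$volume_range[1])
    stop("volume_range must be (min, max) with min >= 1")
  if (length(cfg$groups) == 0L) stop("at least one group is required")
  for (g in cfg$groups) {
    if (!all(c("name", "p_mort", "p_readm", "los_meanlog", "los_sdlog") %in%
             names(g)))
      stop("incomplete group specification: ", deparse(g$name))
    if (g$p_mort <= 0 || g$p_mort >= 1 || g$p_readm <= 0 || g$p_readm >= 1)
      stop("baseline probabilities must lie strictly in (0, 1)")
    if (g$los_sdlog <= 0) stop("los_sdlog must be positive")
  }
  for (nm in outcome_names()) {
    if (is.na(cfg$tau2[nm])) stop("tau2 must be named for each outcome")
    if (cfg$tau2[nm] < 0) stop("tau2 components must be >= 0")
    if (is.na(cfg$year_trend[nm])) stop("year_trend must be named for each outcome")
  }
  R <- cfg$effect_corr
  if (!is.matrix(R) || any(dim(R) != 3L))
    stop("effect_corr must be a 3x3 matrix")
  if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8)
    stop("effect_corr must be symmetric with unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("effect_corr must be positive semi-definite")
  cm <- cfg$casemix
  if (abs(sum(cm$age_probs) - 1) > 1e-8 || length(cm$age_probs) != 5L)
    stop("age_probs must be 5 probabilities summing to 1")
  invisible(cfg)
}

#' Ready-made simulation scenarios
#'
#' Presets mirror the strata of a large multi-hospital administrative cohort:
#' an all-patients mix and three clinical focus areas (stroke, colorectal
#' surgery, heart failure), plus structural scenarios used for validation.
#' Baseline outcome rates follow typical large-academic-hospital values:
#' overall mortality 3.1%, readmission among survivors 7.8%; stroke mortality
#' 13.6% with deaths occurring early (short LOS); colorectal mortality 5.0%,
#' readmission 10.6%, long mean LOS; heart failure mortality 6.7%,
#' readmission 16.9%.
#'
#' Available presets:
#' \describe{
#'   \item{`null`}{no hospital effects, no couplings, no case-mix effects;
#'     every hospital shares one generative law.}
#'   \item{`all_patients`}{three broad groups around a 3.1% mortality /
#'     7.8% readmission mix; positive patient-level LOS-mortality and
#'     LOS-readmission couplings (log 1.45 and log 1.37); correlated
#'     mortality and long-LOS hospital effects, readmission independent.}
#'   \item{`stroke_like`}{high mortality (13.6%), deaths re-drawn from a
#'     short-LOS distribution, correlated mortality/long-LOS hospital
#'     effects: reproduces the patient-versus-hospital-level sign reversal.}
#'   \item{`colorectal_like`}{surgical group with the longest LOS.}
#'   \item{`heart_failure_like`}{high readmission stratum (16.9%).}
#'   \item{`coupled`}{as `all_patients` but without patient-level couplings;
#'     isolates the hospital-level correlation structure.}
#'   \item{`shared_effect`}{one latent hospital effect driving all three
#'     outcomes (correlation 0.95 between all pairs, equal tau^2): the
#'     scenario under which an ordinal composite should rank hospitals at
#'     least as reliably as any single outcome.}
#'   \item{`improvement`}{as `all_patients` plus a downward calendar-time
#'     trend on mortality and long LOS.}
#' }
#'
#' @param name preset name (see Details).
#' @return a [scenario_config()] object.
#' @export
scenario_presets <- function(name) {
  valid <- c("null", "all_patients", "stroke_like", "colorectal_like",
             "heart_failure_like", "coupled", "shared_effect", "improvement")
  if (length(name) != 1L || !name %in% valid)
    stop("unknown preset ", deparse(name), "; valid presets: ",
         paste(valid, collapse = ", "))

  corr_ml <- matrix(c(1, 0, 0.7,
                      0, 1, 0,
                      0.7, 0, 1), 3, 3)
  all_groups <- list(
    group_spec("medical",  0.031, 0.078, 6.7),
    group_spec("surgical", 0.020, 0.060, 5.5, weight = 0.6),
    group_spec("cardio",   0.067, 0.169, 8.8, weight = 0.4))
  cm_eff <- c(age = 0.35, sex = 0.10, unplanned = 0.40, transfer_in = 0.25,
              urgent_prior = 0.20, elixhauser = 0.20)

  switch(name,
    null = scenario_config(
      groups = list(group_spec("general", 0.031, 0.078, 6.7)),
      tau2 = c(mortality = 0, readmission = 0, long_los = 0)),
    all_patients = scenario_config(
      groups = all_groups,
      tau2 = c(mortality = 0.05, readmission = 0.02, long_los = 0.05),
      effect_corr = corr_ml,
      coupling_mort_los = log(1.45),
      coupling_readm_los = log(1.37),
      casemix = default_casemix(effects = cm_eff)),
    stroke_like = scenario_config(
      groups = list(group_spec("stroke", 0.136, 0.073, 12, los_sdlog = 1.1)),
      tau2 = c(mortality = 0.05, readmission = 0.02, long_los = 0.05),
      effect_corr = matrix(c(1, 0, 0.8,
                             0, 1, 0,
                             0.8, 0, 1), 3, 3),
      early_death_short_los = TRUE,
      casemix = default_casemix(effects = cm_eff)),
    colorectal_like = scenario_config(
      groups = list(group_spec("colorectal", 0.050, 0.106, 14.2)),
      tau2 = c(mortality = 0.05, readmission = 0.02, long_los = 0.05),
      effect_corr = corr_ml,
      coupling_mort_los = log(1.31),
      coupling_readm_los = log(1.34),
      casemix = default_casemix(effects = cm_eff)),
    heart_failure_like = scenario_config(
      groups = list(group_spec("heart_failure", 0.067, 0.169, 8.8)),
      tau2 = c(mortality = 0.05, readmission = 0.02, long_los = 0.05),
      effect_corr = corr_ml,
      coupling_mort_los = log(1.38),
      coupling_readm_los = log(1.17),
      casemix = default_casemix(effects = cm_eff)),
    coupled = scenario_config(
      groups = all_groups,
      tau2 = c(mortality = 0.06, readmission = 0.02, long_los = 0.06),
      effect_corr = matrix(c(1, 0, 0.9,
                             0, 1, 0,
                             0.9, 0, 1), 3, 3),
      casemix = default_casemix(effects = cm_eff)),
    shared_effect = scenario_config(
      groups = all_groups,
      tau2 = c(mortality = 0.1, readmission = 0.1, long_los = 0.1),
      effect_corr = matrix(0.95, 3, 3) + diag(0.05, 3),
      casemix = default_casemix(effects = cm_eff)),
    improvement = scenario_config(
      groups = all_groups,
      tau2 = c(mortality = 0.05, readmission = 0.02, long_los = 0.05),
      effect_corr = corr_ml,
      coupling_mort_los = log(1.45),
      coupling_readm_los = log(1.37),
      year_trend = c(mortality = -0.06, readmission = 0, long_los = -0.04),
      casemix = default_casemix(effects = cm_eff))
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat("  hospitals:", x$n_hospitals, " volume:", x$volume_range[1], "-",
      x$volume_range[2], "\n")
  cat("  groups:", paste(vapply(x$groups, `[[`, "", "name"), collapse = ", "),
      "\n")
  cat("  tau2:", paste(sprintf("%s=%.3g", names(x$tau2), x$tau2),
                       collapse = " "), "\n")
  cat("  couplings: mort~LOS", sprintf("%.3f", x$coupling_mort_los),
      " readm~LOS", sprintf("%.3f", x$coupling_readm_los),
      if (x$early_death_short_los) " [early-death short LOS]" else "", "\n")
  invisible(x)
}
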