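# Conversion between a log-odds-scale hospital/covariate effect on "long LOS"
# and a shift of the log-normal LOS location.  For X ~ logN(mu, s), the
# derivative of logit P(X > q75) with respect to mu equals
# dnorm(z75)/(0.75*0.25)/s = 1.695/s, so a meanlog shift of s*0.59*eta moves
# the log-odds of exceeding a fixed upper-quartile cutoff by ~eta.
LOS_LOGODDS_TO_MEANLOG <- 0.59

#' Draw planted hospital effects
#'
#' Hospital effects on mortality, readmission and long LOS are drawn from a
#' trivariate normal with variances `config$tau2` and correlation
#' `config$effect_corr`, then centred so each column has exact mean zero
#' (centring does not change the sample variance).
#'
#' @param config a [scenario_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return a data.frame with columns `hospital_id`, `eta_mort`, `eta_readm`,
#'   `eta_los`.
#' @export
generate_hospital_effects <- function(config, seed = config$seed) {
  validate_config(config)
  set.seed(seed)
  H <- config$n_hospitals
  sds <- sqrt(config$tau2[outcome_names()])
  Sigma <- diag(sds) %*% config$effect_corr %*% diag(sds)
  # PSD square root via eigendecomposition (chol fails for singular corr)
  ev <- eigen(Sigma, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 3) %*% t(ev$vectors)
  eta <- matrix(stats::rnorm(H * 3), H, 3) %*% rt
  if (H > 1L) eta <- sweep(eta, 2, colMeans(eta))
  eta[, sds == 0] <- 0
  data.frame(hospital_id = hospital_ids(H),
             eta_mort = eta[, 1], eta_readm = eta[, 2], eta_los = eta[, 3],
             stringsAsFactors = FALSE)
}

hospital_ids <- function(H) sprintf("H%02d", seq_len(H))

#' Generate a synthetic admission cohort
#'
#' Produces admission-level records with known (planted) hospital effects.
#' For every hospital, a volume is drawn uniformly on `volume_range`; then,
#' per admission: a diagnosis/procedure group, a discharge year, case-mix
#' covariates, a log-normal LOS whose location carries the hospital long-LOS
#' effect and (scaled) case-mix effects, in-hospital death from a logistic
#' model combining the group baseline, centred case-mix effects, the
#' hospital mortality effect, calendar trend, and the patient-level
#' LOS-quartile coupling, and - for survivors only - a 30-day unplanned
#' readmission from the analogous model.  When
#' `config$early_death_short_los` is set, deaths have their LOS re-drawn
#' from a short-stay distribution, so that at the patient level long LOS
#' associates with survival even when hospitals with high mortality also
#' keep survivors longer.
#'
#' Randomness is split per hospital: the master seed produces one sub-seed
#' per hospital (plus one for the effect draw), so cohorts are reproducible
#' and hospital blocks are independent.
#'
#' @param config a [scenario_config()].
#' @param seed integer master seed; defaults to `config$seed`.
#' @param effects optional data.frame with columns `hospital_id`,
#'   `eta_mort`, `eta_readm`, `eta_los` (as returned by
#'   [generate_hospital_effects()]) to plant *fixed* hospital effects
#'   instead of drawing them; used for parameter-recovery studies.
#' @return an object of class `admission_cohort`: a list with `admissions`
#'   (data.frame, one row per admission), `effects` (planted hospital
#'   effects) and `config`.
#' @export
generate_cohort <- function(config, seed = config$seed, effects = NULL) {
  validate_config(config)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, config$n_hospitals + 1L)
  if (is.null(effects)) {
    effects <- generate_hospital_effects(config, seed = sub_seeds[1])
  } else {
    stopifnot(is.data.frame(effects),
              all(c("eta_mort", "eta_readm", "eta_los") %in% names(effects)),
              nrow(effects) == config$n_hospitals)
  }

  gw <- vapply(config$groups, function(g) g$weight %||% 1, 0)
  gnames <- vapply(config$groups, `[[`, "", "name")
  cm <- config$casemix
  age_mean <- sum(cm$age_probs * (0:4))
  y0 <- min(config$years)

  blocks <- vector("list", config$n_hospitals)
  for (h in seq_len(config$n_hospitals)) {
    set.seed(sub_seeds[h + 1L])
    n <- if (config$volume_range[1] == config$volume_range[2])
      config$volume_range[1] else
      sample(config$volume_range[1]:config$volume_range[2], 1L)

    gi <- sample.int(length(config$groups), n, replace = TRUE, prob = gw)
    year <- config$years[sample.int(length(config$years), n, replace = TRUE)]
    age <- sample.int(5L, n, replace = TRUE, prob = cm$age_probs) - 1L
    sex <- stats::rbinom(n, 1L, cm$sex_p)
    unpl <- stats::rbinom(n, 1L, cm$unplanned_p)
    transf <- stats::rbinom(n, 1L, cm$transfer_p)
    urg <- stats::rbinom(n, 1L, cm$urgent_p)
    elix <- pmin(stats::rpois(n, cm$elix_mean), 12L)

    ef <- cm$effects
    lp_cm <- ef[["age"]] * (age - age_mean) +
      ef[["sex"]] * (sex - cm$sex_p) +
      ef[["unplanned"]] * (unpl - cm$unplanned_p) +
      ef[["transfer_in"]] * (transf - cm$transfer_p) +
      ef[["urgent_prior"]] * (urg - cm$urgent_p) +
      ef[["elixhauser"]] * (elix - cm$elix_mean)

    mu_g <- vapply(config$groups, `[[`, 0, "los_meanlog")[gi]
    sd_g <- vapply(config$groups, `[[`, 0, "los_sdlog")[gi]
    k_g <- sd_g * LOS_LOGODDS_TO_MEANLOG
    trend_los <- config$year_trend[["long_los"]] * (year - y0)
    meanlog <- mu_g + k_g * (effects$eta_los[h] + lp_cm + trend_los)
    los <- stats::rlnorm(n, meanlog, sd_g)
    # latent quartile indicator against the group's baseline distribution
    long_true <- los > stats::qlnorm(0.75, mu_g, sd_g)

    lp_mort <- stats::qlogis(vapply(config$groups, `[[`, 0, "p_mort")[gi]) +
      lp_cm + config$year_trend[["mortality"]] * (year - y0) +
      effects$eta_mort[h] + config$coupling_mort_los * long_true
    died <- stats::rbinom(n, 1L, stats::plogis(lp_mort))

    if (config$early_death_short_los && any(died == 1L)) {
      i <- died == 1L
      los[i] <- stats::rlnorm(sum(i),
                              mu_g[i] + config$short_los_shift +
                                k_g[i] * effects$eta_los[h],
                              sd_g[i])
    }

    lp_readm <- stats::qlogis(vapply(config$groups, `[[`, 0, "p_readm")[gi]) +
      lp_cm + config$year_trend[["readmission"]] * (year - y0) +
      effects$eta_readm[h] + config$coupling_readm_los * long_true
    readm <- ifelse(died == 1L, NA_integer_,
                    stats::rbinom(n, 1L, stats::plogis(lp_readm)))

    blocks[[h]] <- data.frame(
      hospital_id = hospital_ids(config$n_hospitals)[h],
      group = gnames[gi],
      year = year,
      age_group = age_band_labels()[age + 1L],
      sex = sex, unplanned = unpl, transfer_in = transf, urgent_prior = urg,
      elixhauser = elix,
      los_days = los,
      died = died,
      readmitted_30d = readm,
      stringsAsFactors = FALSE)
  }

  adm <- do.call(rbind, blocks)
  rownames(adm) <- NULL
  adm$hospital_id <- factor(adm$hospital_id,
                            levels = hospital_ids(config$n_hospitals))
  adm$group <- factor(adm$group, levels = gnames)
  adm$age_group <- factor(adm$age_group, levels = age_band_labels(),
                          ordered = TRUE)
  structure(list(admissions = adm, effects = effects, config = config,
                 seed = as.integer(seed)),
            class = "admission_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.admission_cohort <- function(x, ...) {
  a <- x$admissions
  cat("<admission_cohort> ", nrow(a), " admissions, ",
      nlevels(a$hospital_id), " hospitals, ", nlevels(a$group),
      " group(s)\n", sep = "")
  cat(sprintf("  crude mortality %.2f%%, readmission (survivors) %.2f%%, mean LOS %.1f d\n",
              100 * mean(a$died),
              100 * mean(a$readmitted_30d[a$died == 0]),
              mean(a$los_days)))
  invisible(x)
}

#' Write / read a cohort as plain text
#'
#' The admission table is written as CSV with a fixed column order;
#' the planted truth (hospital effects and a config echo) goes to an
#' accompanying JSON file.
#'
#' @param cohort an `admission_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "admission_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "admissions.csv")
  js <- file.path(dir, "truth.json")
  utils::write.csv(cohort$admissions, csv, row.names = FALSE, na = "")
  cfg <- cohort$config
  cfg$effect_corr <- unclass(cfg$effect_corr)
  jsonlite::write_json(
    list(effects = cohort$effects, config = unclass(cfg), seed = cohort$seed),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, truth = js))
}

#' @rdname write_cohort
#' @param path path to an `admissions.csv` written by [write_cohort()] or a
#'   conforming CSV with the same columns.
#' @export
read_cohort_csv <- function(path) {
  adm <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hospital_id", "group", "year", "age_group", "sex", "unplanned",
            "transfer_in", "urgent_prior", "elixhauser", "los_days", "died",
            "readmitted_30d")
  miss <- setdiff(need, names(adm))
  if (length(miss)) stop("cohort CSV lacks columns: ",
                         paste(miss, collapse = ", "))
  adm$hospital_id <- factor(adm$hospital_id)
  adm$group <- factor(adm$group)
  lev <- intersect(age_band_labels(), unique(adm$age_group))
  adm$age_group <- factor(adm$age_group,
                          levels = if (length(lev)) lev else
                            sort(unique(adm$age_group)),
                          ordered = TRUE)
  if (any(adm$los_days <= 0)) stop("los_days must be positive")
  if (any(adm$died == 1L & !is.na(adm$readmitted_30d)))
    stop("readmitted_30d must be missing for in-hospital deaths")
  adm
}
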