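default_ordinal_covariates <- function(records) {
  cand <- c("age_group", "sex", "unplanned", "transfer_in", "urgent_prior",
            "elixhauser", "year", "group")
  cand[vapply(cand, function(v) {
    !is.null(records[[v]]) && length(unique(records[[v]])) > 1L
  }, TRUE)]
}

#' Crude composite distribution per hospital
#'
#' @param records admission data.frame with a `composite_level` column.
#' @return data.frame, one row per hospital: `hospital_id`, `n` and the
#'   proportions `p1`..`p5` of the five composite levels (rows sum to 1).
#'   Hospitals without admissions are excluded with a warning.
#' @export
composite_distribution_table <- function(records) {
  if (is.null(records$composite_level))
    stop("records need a 'composite_level' column")
  hosp <- factor(records$hospital_id)
  empty <- levels(hosp)[tabulate(hosp, nlevels(hosp)) == 0L]
  if (length(empty))
    warning("excluding hospital(s) without admissions: ",
            paste(empty, collapse = ", "))
  tab <- table(hosp, factor(records$composite_level, levels = 1:5))
  keep <- rowSums(tab) > 0
  pr <- prop.table(tab[keep, , drop = FALSE], margin = 1)
  out <- data.frame(hospital_id = rownames(pr),
                    n = as.integer(rowSums(tab[keep, , drop = FALSE])),
                    stringsAsFactors = FALSE)
  for (k in 1:5) out[[paste0("p", k)]] <- as.numeric(pr[, k])
  rownames(out) <- NULL
  out
}

#' Compare two discharge periods on the composite outcome
#'
#' Splits the cohort into period A (`year <= split_year`) and period B
#' (later years), compares the proportion of admissions achieving the best
#' composite level (alive, normal LOS, no readmission) with a two-proportion
#' chi-square test (no continuity correction), breaks the proportions down
#' per group, and optionally re-estimates the between-hospital variance of
#' the composite per period.
#'
#' @param records admission data.frame with a `composite_level` column.
#' @param split_year last year of period A.
#' @param tau2 logical; also estimate tau^2 of the composite per period?
#' @param covariates covariates for the per-period ordinal fits.
#' @return list of class `period_comparison`: `proportion_best_a`,
#'   `proportion_best_b`, `p_value`, `n_a`, `n_b`, `by_group` (data.frame),
#'   and `tau2_a`/`tau2_b` when requested.
#' @export
compare_periods <- function(records, split_year, tau2 = TRUE,
                            covariates = NULL) {
  if (is.null(records$composite_level))
    stop("records need a 'composite_level' column")
  a <- records[records$year <= split_year, , drop = FALSE]
  b <- records[records$year > split_year, , drop = FALSE]
  if (!nrow(a) || !nrow(b))
    stop("both periods must be non-empty (split_year = ", split_year, ")")
  xa <- sum(a$composite_level == 1L); xb <- sum(b$composite_level == 1L)
  pt <- suppressWarnings(stats::prop.test(c(xa, xb), c(nrow(a), nrow(b)),
                                          correct = FALSE))
  by_group <- do.call(rbind, lapply(levels(factor(records$group)), function(g) {
    ga <- a$composite_level[a$group == g]; gb <- b$composite_level[b$group == g]
    data.frame(group = g,
               proportion_best_a = mean(ga == 1L),
               proportion_best_b = mean(gb == 1L),
               n_a = length(ga), n_b = length(gb),
               stringsAsFactors = FALSE)
  }))
  out <- list(proportion_best_a = xa / nrow(a),
              proportion_best_b = xb / nrow(b),
              p_value = pt$p.value, n_a = nrow(a), n_b = nrow(b),
              by_group = by_group)
  if (tau2) {
    t2 <- function(d) {
      fit <- fit_ordinal_model(d, covariates = covariates)
      h <- fit$hospitals
      estimate_tau2_moments(h$beta[!h$reference], h$se[!h$reference])
    }
    out$tau2_a <- t2(a)
    out$tau2_b <- t2(b)
  }
  structure(out, class = "period_comparison")
}

#' @export
print.period_comparison <- function(x, ...) {
  cat(sprintf("best composite level: %.2f%% (period A, n=%d) vs %.2f%% (period B, n=%d), p = %.3g\n",
              100 * x$proportion_best_a, x$n_a,
              100 * x$proportion_best_b, x$n_b, x$p_value))
  if (!is.null(x$tau2_a))
    cat(sprintf("composite tau2: %.4f (A) vs %.4f (B)\n", x$tau2_a, x$tau2_b))
  invisible(x)
}

#' Run the full hospital-comparison analysis
#'
#' Orchestrates the whole method on a scenario configuration (which is first
#' simulated) or an existing admission table: long-LOS flagging, per-group
#' case-mix models with backward elimination, per-hospital standardized
#' ratios for the three outcomes, patient-level odds ratios of long LOS on
#' mortality and readmission, hospital-level Pearson correlations, the
#' 5-level ordinal composite with its proportional-odds fit and
#' standardized composite rates, rankability of each outcome and of the
#' composite, the crude composite distribution per hospital, and a
#' two-period comparison.
#'
#' @param x a [scenario_config()], an `admission_cohort`, or an admission
#'   data.frame (e.g. from [read_cohort_csv()]).
#' @param seed seed used when `x` is a configuration.
#' @param percentile long-LOS percentile (75 or 90).
#' @param split_year last year of the earlier period for the time
#'   comparison; default the median year.  `NA` skips the comparison.
#' @param tau2_method passed to [rankability_analysis()].
#' @param period_tau2 logical; estimate per-period composite tau^2?
#' @return list of class `report_bundle` with elements `ratios` (per
#'   hospital x outcome), `ratio_summary` (median/IQR per outcome),
#'   `patient_or` (4-row table), `correlations` (pairwise, incl. the
#'   composite), `composite_fit`, `composite_rates`, `rankability`,
#'   `composite_distribution`, `period_comparison`, `long_los_rule`,
#'   `models`, `admissions`, `provenance`.
#' @export
run_full_analysis <- function(x, seed = NULL, percentile = 75,
                              split_year = NULL,
                              tau2_method = "auto", period_tau2 = TRUE) {
  cfg <- NULL
  if (inherits(x, "scenario_config")) {
    cfg <- x
    x <- generate_cohort(cfg, seed = seed %||% cfg$seed)
  }
  if (inherits(x, "admission_cohort")) {
    cfg <- cfg %||% x$config
    seed <- seed %||% x$seed
    adm <- x$admissions
  } else adm <- x

  rule <- long_los_flags(adm, percentile)
  adm$long_los <- rule$flags
  adm$composite_level <- assign_composite_level(
    adm$died, adm$long_los,
    ifelse(adm$died == 1L, FALSE, adm$readmitted_30d))

  models <- fit_casemix_models(adm)
  ratios <- do.call(rbind, lapply(outcome_names(), function(o)
    hospital_standardized_ratios(adm, models, o)))
  ratio_summary <- do.call(rbind, lapply(split(ratios, ratios$outcome),
    function(d) data.frame(
      outcome = d$outcome[1],
      observed_pct_median = stats::median(100 * d$observed / d$n),
      expected_pct_median = stats::median(100 * d$expected / d$n),
      ratio_median = stats::median(d$ratio),
      ratio_q1 = unname(stats::quantile(d$ratio, 0.25)),
      ratio_q3 = unname(stats::quantile(d$ratio, 0.75)),
      stringsAsFactors = FALSE)))
  rownames(ratio_summary) <- NULL

  patient_or <- do.call(rbind, lapply(c("mortality", "readmission"),
    function(o) do.call(rbind, lapply(c(FALSE, TRUE), function(adj) {
      or <- patient_level_or(adm, o, adjusted = adj)
      data.frame(outcome = o, adjusted = adj, or = or$or,
                 ci_low = or$ci[1], ci_high = or$ci[2], n = or$n,
                 stringsAsFactors = FALSE)
    }))))
  rownames(patient_or) <- NULL

  covs <- default_ordinal_covariates(adm)
  cfit <- fit_ordinal_model(adm, covariates = covs)
  crates <- standardized_composite_rate(cfit)

  rat <- function(o) ratios[ratios$outcome == o, ]
  comp_as_ratio <- data.frame(hospital_id = crates$hospital_id,
                              ratio = crates$rate, stringsAsFactors = FALSE)
  pairs <- list(
    c("mortality", "readmission"), c("mortality", "long_los"),
    c("readmission", "long_los"),
    c("composite", "mortality"), c("composite", "readmission"),
    c("composite", "long_los"))
  correlations <- do.call(rbind, lapply(pairs, function(p) {
    a <- if (p[1] == "composite") comp_as_ratio else rat(p[1])
    b <- if (p[2] == "composite") comp_as_ratio else rat(p[2])
    ct <- hospital_correlations(a, b)
    data.frame(outcome_a = p[1], outcome_b = p[2], r = ct$r, p = ct$p,
               n = ct$n, stringsAsFactors = FALSE)
  }))

  rk <- lapply(c(outcome_names(), "composite"), function(o)
    rankability_analysis(adm, o,
                         covariates = if (o == "composite") covs else NULL,
                         tau2_method = if (o == "composite") "auto"
                                       else tau2_method))
  rank_tab <- do.call(rbind, lapply(rk, function(r)
    data.frame(outcome = r$outcome, tau2 = r$tau2,
               median_sigma2 = r$median_sigma2,
               rankability_percent = r$rankability, method = r$method,
               stringsAsFactors = FALSE)))

  comp_dist <- composite_distribution_table(adm)

  years <- sort(unique(adm$year))
  if (is.null(split_year)) split_year <-
      if (length(years) > 1L) stats::median(years) else NA
  period <- if (!is.na(split_year) && length(years) > 1L)
    compare_periods(adm, split_year, tau2 = period_tau2, covariates = covs)
  else NULL

  structure(list(
    ratios = ratios, ratio_summary = ratio_summary, patient_or = patient_or,
    correlations = correlations, composite_fit = cfit,
    composite_rates = crates, rankability = rank_tab,
    composite_distribution = comp_dist, period_comparison = period,
    long_los_rule = rule, models = models, admissions = adm,
    provenance = list(seed = seed, percentile = percentile,
                      split_year = split_year,
                      n_admissions = nrow(adm),
                      n_hospitals = length(unique(adm$hospital_id)),
                      package_version =
                        as.character(utils::packageVersion("hospcomp")),
                      config = if (!is.null(cfg)) unclass(cfg))),
    class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", x$provenance$n_admissions, " admissions, ",
      x$provenance$n_hospitals, " hospitals\n", sep = "")
  cat("Standardized ratios (median [IQR]):\n")
  for (i in seq_len(nrow(x$ratio_summary)))
    cat(sprintf("  %-12s %5.1f [%5.1f-%5.1f]\n",
                x$ratio_summary$outcome[i], x$ratio_summary$ratio_median[i],
                x$ratio_summary$ratio_q1[i], x$ratio_summary$ratio_q3[i]))
  cat("Rankability (%):\n")
  for (i in seq_len(nrow(x$rankability)))
    cat(sprintf("  %-12s %5.1f (%s)\n", x$rankability$outcome[i],
                x$rankability$rankability_percent[i],
                x$rankability$method[i]))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the tabular surfaces as CSV files and a machine-readable
#' `summary.json` (all numbers at full precision, so reruns with the same
#' seed are byte-identical).
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  w(bundle$ratios, "ratios.csv")
  w(bundle$ratio_summary, "ratio_summary.csv")
  w(bundle$patient_or, "patient_or.csv")
  w(bundle$correlations, "correlations.csv")
  w(bundle$composite_rates, "composite_rates.csv")
  w(bundle$rankability, "rankability.csv")
  w(bundle$composite_distribution, "composite_distribution.csv")
  summary <- list(
    ratio_summary = bundle$ratio_summary,
    patient_or = bundle$patient_or,
    correlations = bundle$correlations,
    rankability = bundle$rankability,
    composite_rates = bundle$composite_rates,
    period_comparison = if (!is.null(bundle$period_comparison))
      unclass(bundle$period_comparison),
    provenance = bundle$provenance)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
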