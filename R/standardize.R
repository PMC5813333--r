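#' Flag long length-of-stay admissions
#'
#' Long LOS is a LOS strictly greater than the group-specific upper
#' percentile of the pooled (all hospitals, all years) LOS distribution.
#' The default is the 75th percentile (upper-quartile LOS); the 90th
#' (upper-decile LOS) is available as a sensitivity definition.  Cutoffs use
#' the nearest-rank convention: the `ceiling(p/100 * n)`-th order statistic.
#'
#' @param records admission data.frame with `group` and `los_days`.
#' @param percentile 75 or 90.
#' @return a list of class `long_los_rule`: `flags` (logical per record),
#'   `percentile`, `cutoffs` (named, days, per group) and `low_confidence`
#'   (groups with fewer than 4 records).
#' @export
long_los_flags <- function(records, percentile = 75) {
  if (!percentile %in% c(75, 90))
    stop("percentile must be 75 or 90")
  stopifnot(all(records$los_days > 0))
  grp <- factor(records$group)
  cutoffs <- vapply(split(records$los_days, grp), function(x) {
    sort(x)[ceiling(percentile / 100 * length(x))]
  }, 0)
  sizes <- table(grp)
  flags <- records$los_days > cutoffs[as.character(grp)]
  structure(list(flags = unname(flags), percentile = percentile,
                 cutoffs = cutoffs,
                 low_confidence = names(sizes)[sizes < 4L]),
            class = "long_los_rule")
}

#' Standardized outcome ratio
#'
#' The indirectly standardized ratio 100 x observed / expected; 100 means
#' "as expected given case-mix".
#'
#' @param observed observed event count(s).
#' @param expected expected event count(s) from case-mix models; must be
#'   strictly positive.
#' @return numeric ratio(s).
#' @export
standardized_ratio <- function(observed, expected) {
  if (any(expected <= 0))
    stop("standardized ratio undefined: expected count must be > 0")
  if (any(observed < 0)) stop("observed count must be >= 0")
  100 * observed / expected
}

#' Per-hospital standardized ratios for one outcome
#'
#' Sums expected probabilities per hospital to the expected count, counts
#' observed events and forms 100 x O/E.  Mortality is computed over all
#' admissions; readmission and long LOS over survivors.
#'
#' @param records admission data.frame (with a `long_los` column for the
#'   long-LOS outcome).
#' @param models output of [fit_casemix_models()] (or a list
#'   `models[[group]]` for this outcome).
#' @param outcome one of `"mortality"`, `"readmission"`, `"long_los"`.
#' @return data.frame `hospital_id`, `outcome`, `n`, `observed`, `expected`,
#'   `ratio`, plus attribute `denominator_population`.
#' @export
hospital_standardized_ratios <- function(records, models, outcome) {
  outcome <- match.arg(outcome, outcome_names())
  if (!is.null(models[[outcome]])) models <- models[[outcome]]
  od <- outcome_data(records, outcome)
  data <- od$data
  data$.y <- od$y
  data$.exp <- NA_real_
  for (g in levels(factor(data$group))) {
    i <- data$group == g
    m <- models[[g]]
    if (is.null(m)) stop("no case-mix model for group ", deparse(g))
    data$.exp[i] <- predict_expected(m, data[i, , drop = FALSE])
  }
  obs <- tapply(data$.y, data$hospital_id, sum)
  exp_ <- tapply(data$.exp, data$hospital_id, sum)
  n <- tapply(rep(1L, nrow(data)), data$hospital_id, sum)
  keep <- !is.na(obs) & !is.na(exp_)
  out <- data.frame(hospital_id = names(obs)[keep], outcome = outcome,
                    n = as.integer(n[keep]),
                    observed = as.integer(obs[keep]),
                    expected = as.numeric(exp_[keep]),
                    stringsAsFactors = FALSE)
  out$ratio <- standardized_ratio(out$observed, out$expected)
  attr(out, "denominator_population") <-
    if (outcome == "mortality") "all" else "survivors"
  rownames(out) <- NULL
  out
}

#' Patient-level association of long LOS with mortality or readmission
#'
#' Logistic regression of the outcome on the upper-quartile-LOS indicator,
#' either unadjusted or adjusted for hospital (fixed effect) and case-mix
#' covariates.  Readmission models are restricted to survivors.
#'
#' @param records admission data.frame with a logical `long_los` column.
#' @param outcome `"mortality"` or `"readmission"`.
#' @param adjusted logical; adjust for hospital + case-mix?
#' @param conf_level confidence level of the Wald interval.
#' @return a list of class `patient_level_or`: `outcome`, `adjusted`, `or`,
#'   `ci` (length 2), `log_or`, `se`, `n`.
#' @export
patient_level_or <- function(records, outcome = c("mortality", "readmission"),
                             adjusted = FALSE, conf_level = 0.95) {
  outcome <- match.arg(outcome)
  if (is.null(records$long_los))
    stop("records need a 'long_los' column (see long_los_flags())")
  od <- outcome_data(records, outcome)
  data <- od$data
  data$.y <- od$y
  data$long_los <- as.integer(data$long_los)
  if (!adjusted) {
    tab <- table(exposure = data$long_los, event = data$.y)
    if (any(dim(tab) != 2L) || any(tab == 0))
      stop("zero cell in the exposure x outcome table; odds ratio ",
           "undefined without a continuity correction (caller's choice)")
    fml <- .y ~ long_los
  } else {
    terms <- c("long_los", "hospital_id",
               candidate_terms(transform(data, year = factor(year)))$mains)
    fml <- stats::reformulate(unique(terms), response = ".y")
    data$year <- factor(data$year)
  }
  fit <- stats::glm(fml, family = stats::binomial(), data = data)
  b <- stats::coef(fit)[["long_los"]]
  se <- sqrt(stats::vcov(fit)["long_los", "long_los"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(outcome = outcome, adjusted = adjusted,
                 or = exp(b), ci = exp(b + c(-1, 1) * z * se),
                 log_or = b, se = se, n = nrow(data)),
            class = "patient_level_or")
}

#' @export
print.patient_level_or <- function(x, ...) {
  cat(sprintf("%s OR (long LOS, %s): %.3f (%.3f-%.3f), n = %d\n",
              if (x$adjusted) "Adjusted" else "Unadjusted",
              x$outcome, x$or, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Pearson correlation of two sets of hospital-level standardized ratios
#'
#' @param ratios_a,ratios_b data.frames from
#'   [hospital_standardized_ratios()] (or numeric vectors in matching
#'   hospital order).
#' @return list with `r`, `p` (two-sided, t-distribution with n-2 df) and
#'   `n` (hospitals).
#' @export
hospital_correlations <- function(ratios_a, ratios_b) {
  get_xy <- function(a, b) {
    if (is.data.frame(a) && is.data.frame(b)) {
      m <- merge(a[, c("hospital_id", "ratio")],
                 b[, c("hospital_id", "ratio")], by = "hospital_id")
      if (nrow(m) < length(union(a$hospital_id, b$hospital_id)))
        stop("hospital sets differ between the two ratio tables")
      list(x = m$ratio.x, y = m$ratio.y)
    } else list(x = as.numeric(a), y = as.numeric(b))
  }
  xy <- get_xy(ratios_a, ratios_b)
  if (length(xy$x) < 3L) stop("need at least 3 hospitals")
  if (stats::sd(xy$x) == 0 || stats::sd(xy$y) == 0)
    stop("correlation undefined: zero variance in standardized ratios")
  ct <- stats::cor.test(xy$x, xy$y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(xy$x))
}
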