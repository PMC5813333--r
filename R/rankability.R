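#' Between-hospital variance from a random-intercept model
#'
#' Estimates tau^2, the variance of the hospital random effects on the
#' log-odds scale, for a binary outcome via a logistic random-intercept
#' model.  Without case-mix covariates the data are aggregated to
#' hospital-level binomial counts and fitted with adaptive Gauss-Hermite
#' quadrature; with covariates a patient-level fit (Laplace approximation)
#' is used.  For the ordinal composite no random-intercept fitter is used;
#' tau^2 comes from the method-of-moments estimator applied to the
#' fixed-effect hospital coefficients (see [estimate_tau2_moments()]).
#' Non-convergence of the quadrature route falls back to the moments
#' estimator with a warning.
#'
#' @param records admission data.frame (with `long_los` /
#'   `composite_level` columns where needed).
#' @param outcome `"mortality"`, `"readmission"`, `"long_los"` or
#'   `"composite"`.
#' @param covariates optional case-mix covariate names to adjust for.
#' @param nAGQ quadrature points for the aggregated binomial fit.
#' @return list with `tau2` and `method` (`"quadrature"` or `"moments"`).
#' @export
estimate_tau2_random_effects <- function(records, outcome,
                                         covariates = NULL, nAGQ = 15L) {
  if (length(unique(records$hospital_id)) < 2L)
    stop("tau2 undefined with a single hospital")
  if (outcome == "composite") {
    fit <- fit_ordinal_model(records, covariates = covariates)
    h <- fit$hospitals
    return(list(tau2 = estimate_tau2_moments(h$beta[!h$reference],
                                             h$se[!h$reference]),
                method = "moments"))
  }
  od <- outcome_data(records, outcome)
  data <- od$data; data$.y <- od$y
  res <- tryCatch({
    if (is.null(covariates)) {
      agg <- stats::aggregate(.y ~ hospital_id, data,
                              FUN = function(v) c(ev = sum(v), n = length(v)))
      agg <- data.frame(hospital_id = agg$hospital_id,
                        ev = agg$.y[, "ev"], n = agg$.y[, "n"])
      m <- lme4::glmer(cbind(ev, n - ev) ~ 1 + (1 | hospital_id),
                       data = agg, family = stats::binomial(), nAGQ = nAGQ)
    } else {
      data$year <- factor(data$year)
      fml <- stats::reformulate(c(covariates, "(1 | hospital_id)"),
                                response = ".y")
      m <- lme4::glmer(fml, data = data, family = stats::binomial(), nAGQ = 1L)
    }
    as.numeric(lme4::VarCorr(m)$hospital_id[1, 1])
  }, error = function(e) e, warning = function(w) w)
  if (is.numeric(res))
    return(list(tau2 = res, method = "quadrature"))
  warning("random-intercept fit failed (", conditionMessage(res),
          "); falling back to the moments estimator")
  ff <- fixed_hospital_fit(records, outcome, covariates)
  list(tau2 = estimate_tau2_moments(ff$beta, ff$se), method = "moments")
}

#' Method-of-moments between-hospital variance
#'
#' DerSimonian-Laird-type estimator applied to the (centred) fixed-effect
#' hospital coefficients with their squared standard errors as within-
#' hospital variances; negative estimates are truncated at 0.  Entries with
#' non-positive SE (e.g. the reference hospital, whose SE is 0 by coding)
#' are excluded.
#'
#' @param hospital_betas fixed-effect hospital estimates (log-odds scale).
#' @param hospital_ses their standard errors.
#' @return non-negative tau^2 estimate.
#' @export
estimate_tau2_moments <- function(hospital_betas, hospital_ses) {
  keep <- is.finite(hospital_betas) & is.finite(hospital_ses) &
    hospital_ses > 0
  b <- hospital_betas[keep]; s <- hospital_ses[keep]
  if (length(b) < 2L)
    stop("need >= 2 hospitals with finite, positive SEs")
  w <- 1 / s^2
  mu <- sum(w * b) / sum(w)
  Q <- sum(w * (b - mu)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  max(0, (Q - (length(b) - 1)) / denom)
}

#' Median squared standard error of the fixed-effect hospital estimates
#'
#' The reference hospital's SE (identically zero by coding) is excluded:
#' it is an artifact of the parameterization, not an uncertainty estimate.
#'
#' @param ses standard errors of the per-hospital fixed effects, or an
#'   `ordinal_fit` object.
#' @return median of the squared SEs.
#' @export
median_sigma2 <- function(ses) {
  if (inherits(ses, "ordinal_fit")) ses <- ses$hospitals$se
  ses <- ses[is.finite(ses) & ses > 0]
  if (!length(ses)) stop("no positive finite SEs supplied")
  stats::median(ses^2)
}

#' Rankability of a hospital comparison
#'
#' The percentage of observed between-hospital variation attributable to
#' true differences rather than estimation noise:
#' `100 * tau2 / (tau2 + median_sigma2)`.
#'
#' @param tau2 between-hospital variance (log-odds^2), >= 0.
#' @param median_sigma2 median squared SE of the fixed-effect hospital
#'   estimates, > 0.
#' @return percentage in \[0, 100\].
#' @export
rankability <- function(tau2, median_sigma2) {
  if (tau2 < 0) stop("tau2 must be >= 0")
  if (median_sigma2 <= 0) stop("median_sigma2 must be > 0")
  100 * tau2 / (tau2 + median_sigma2)
}

# fixed-effect hospital fit (binary outcomes) returning non-reference
# hospital coefficients and SEs; reference = largest-volume hospital
fixed_hospital_fit <- function(records, outcome, covariates = NULL) {
  od <- outcome_data(records, outcome)
  data <- od$data; data$.y <- od$y
  data$hospital_id <- factor(data$hospital_id)
  ref <- names(which.max(table(data$hospital_id)))
  data$hospital_id <- stats::relevel(data$hospital_id, ref = ref)
  if (!is.null(covariates)) data$year <- factor(data$year)
  fml <- stats::reformulate(c("hospital_id", covariates), response = ".y")
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = data, model = FALSE))
  cf <- stats::coef(fit)
  is_h <- grepl("^hospital_id", names(cf)) & !is.na(cf)
  se <- sqrt(diag(stats::vcov(fit)))[names(cf)[is_h]]
  list(beta = unname(cf[is_h]), se = unname(se), reference = ref)
}

#' Full rankability analysis for one outcome
#'
#' Combines the two rankability ingredients: tau^2 from a random-intercept
#' fit (or the moments estimator for the ordinal composite) and the median
#' squared SE from the corresponding fixed-effect fit.
#'
#' @inheritParams estimate_tau2_random_effects
#' @param tau2_method `"auto"` (quadrature for binary outcomes, moments for
#'   the composite) or `"moments"` to force the moments estimator for all.
#' @return list of class `rankability_result`: `outcome`, `tau2`,
#'   `median_sigma2`, `rankability` (percent), `method`.
#' @export
rankability_analysis <- function(records, outcome, covariates = NULL,
                                 tau2_method = c("auto", "moments"),
                                 nAGQ = 15L) {
  tau2_method <- match.arg(tau2_method)
  if (outcome == "composite") {
    fit <- fit_ordinal_model(records, covariates = covariates)
    h <- fit$hospitals
    tau2 <- estimate_tau2_moments(h$beta[!h$reference], h$se[!h$reference])
    ms2 <- median_sigma2(h$se[!h$reference])
    method <- "moments"
  } else {
    ff <- fixed_hospital_fit(records, outcome, covariates)
    ms2 <- median_sigma2(ff$se)
    if (tau2_method == "moments") {
      tau2 <- estimate_tau2_moments(ff$beta, ff$se)
      method <- "moments"
    } else {
      est <- estimate_tau2_random_effects(records, outcome, covariates,
                                          nAGQ = nAGQ)
      tau2 <- est$tau2
      method <- est$method
    }
  }
  structure(list(outcome = outcome, tau2 = tau2, median_sigma2 = ms2,
                 rankability = rankability(tau2, ms2), method = method),
            class = "rankability_result")
}

#' @export
print.rankability_result <- function(x, ...) {
  cat(sprintf("<rankability> %s: tau2 = %.4f, median sigma2 = %.4f -> %.1f%% (%s)\n",
              x$outcome, x$tau2, x$median_sigma2, x$rankability, x$method))
  invisible(x)
}
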