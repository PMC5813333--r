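#' Assign the 5-level ordinal composite outcome
#'
#' Levels order admissions from best to worst: 1 alive, no long LOS, no
#' readmission; 2 alive, long LOS, no readmission; 3 alive, no long LOS,
#' readmission; 4 alive, long LOS, readmission; 5 in-hospital death
#' (regardless of LOS or readmission).  A readmission after discharge is
#' ranked worse than a prolonged stay.
#'
#' @param died logical/0-1 vector.
#' @param long_los logical/0-1 vector (ignored for deaths).
#' @param readmitted logical/0-1 vector; may be `NA` for deaths (ignored),
#'   must be non-missing for survivors.
#' @return integer vector of levels 1-5.
#' @export
assign_composite_level <- function(died, long_los, readmitted) {
  died <- as.logical(died); long_los <- as.logical(long_los)
  readmitted <- as.logical(readmitted)
  if (any(is.na(died))) stop("died must be non-missing")
  alive <- !died
  if (any(is.na(readmitted[alive])))
    stop("readmitted must be non-missing for survivors")
  if (any(is.na(long_los[alive])))
    stop("long_los must be non-missing for survivors")
  lv <- rep(5L, length(died))
  lv[alive] <- 1L + long_los[alive] + 2L * readmitted[alive]
  lv
}

#' Cumulative-logit (proportional-odds) log-likelihood
#'
#' Parameterized so that `logit P(Y <= k) = thresholds[k] - eta`: a larger
#' linear predictor `eta` means higher odds of a *worse* (higher) level.
#' Exposed as a pure function so that fitters and independent optimizers
#' can share one likelihood.
#'
#' @param thresholds strictly increasing cut-points (length K-1).
#' @param eta linear predictor per observation.
#' @param levels integer outcomes in 1..K, same length as `eta`.
#' @return the log-likelihood value.
#' @export
proportional_odds_loglik <- function(thresholds, eta, levels) {
  K <- length(thresholds) + 1L
  if (K > 2L && any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  levels <- as.integer(levels)
  if (any(levels < 1L | levels > K)) stop("levels out of range 1..K")
  cuts <- c(-Inf, thresholds, Inf)
  upper <- stats::plogis(cuts[levels + 1L] - eta)
  lower <- stats::plogis(cuts[levels] - eta)
  sum(log(pmax(upper - lower, 1e-300)))
}

#' Fit the proportional-odds model with hospital fixed effects
#'
#' Maximum-likelihood cumulative-logit fit of the composite level on
#' hospital (fixed effects) plus case-mix covariates.  The reference
#' hospital (coefficient fixed at 0, SE 0) is by default the hospital with
#' the most admissions, a numerically convenient choice that the subsequent
#' coefficient-centring makes immaterial.  A positive hospital coefficient
#' means higher odds of a worse composite level.  Fits that do not converge
#' (e.g. a hospital with all-best or all-worst outcomes) are retried with a
#' small L2 penalty on the coefficients and flagged.
#'
#' @param records admission data.frame.
#' @param levels integer composite levels (1-5), one per record; defaults to
#'   a `composite_level` column of `records`.
#' @param covariates character vector of case-mix covariate names to adjust
#'   for (present in `records`); `NULL` for hospital-only.
#' @param ref reference hospital id; default the largest-volume hospital.
#' @param ridge_lambda penalty of the non-convergence fallback.
#' @return an object of class `ordinal_fit`: `thresholds` (increasing
#'   cut-points), `casemix_coefficients`, `hospitals` (data.frame
#'   `hospital_id`, `beta`, `se`, `reference`), `loglik`, `n`,
#'   `convergence` (list with `converged`, `method`).
#' @export
fit_ordinal_model <- function(records, levels = records$composite_level,
                              covariates = NULL, ref = NULL,
                              ridge_lambda = 1e-4) {
  if (is.null(levels)) stop("composite levels are required")
  hosp <- factor(records$hospital_id)
  if (nlevels(hosp) < 2L) stop("need at least 2 hospitals")
  if (length(unique(levels)) < 2L) stop("need at least 2 distinct levels")
  if (is.null(ref)) ref <- names(which.max(table(hosp)))
  hosp <- stats::relevel(factor(hosp, levels = levels(hosp)), ref = ref)

  data <- data.frame(.lvl = factor(levels, ordered = TRUE), hospital = hosp)
  for (v in covariates) {
    col <- records[[v]]
    if (is.null(col)) stop("covariate not found: ", v)
    data[[v]] <- if (v %in% c("year", "group")) factor(col)
      else if (v == "age_group") factor(col, ordered = FALSE) else col
  }
  fml <- stats::reformulate(c("hospital", covariates), response = ".lvl")

  fit <- tryCatch(
    suppressWarnings(MASS::polr(fml, data = data, Hess = TRUE,
                                model = FALSE)),
    error = function(e) e)
  ok <- inherits(fit, "polr") && fit$convergence == 0 &&
    all(is.finite(stats::coef(fit))) && max(abs(stats::coef(fit))) < 15

  if (ok) {
    V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
    ok <- !is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)
  }
  if (ok) {
    cf <- stats::coef(fit)
    se <- sqrt(diag(V))[names(cf)]
    return(build_ordinal_fit(fit$zeta, cf, se, hosp, ref,
                             loglik = -fit$deviance / 2, n = nrow(data),
                             method = "polr", converged = TRUE))
  }

  # penalized fallback sharing proportional_odds_loglik()
  mm <- stats::model.matrix(fml, data)[, -1, drop = FALSE]
  pen_fit <- fit_po_penalized(mm, as.integer(data$.lvl), ridge_lambda)
  build_ordinal_fit(pen_fit$thresholds, pen_fit$beta, pen_fit$se, hosp, ref,
                    loglik = pen_fit$loglik, n = nrow(data),
                    method = "penalized", converged = pen_fit$converged)
}

build_ordinal_fit <- function(zeta, cf, se, hosp, ref, loglik, n, method,
                              converged) {
  hn <- paste0("hospital", levels(hosp))
  is_h <- names(cf) %in% hn
  hb <- stats::setNames(rep(0, nlevels(hosp)), levels(hosp))
  hs <- hb
  got <- sub("^hospital", "", names(cf)[is_h])
  hb[got] <- cf[is_h]
  hs[got] <- se[is_h]
  hosp_tab <- data.frame(hospital_id = levels(hosp), beta = unname(hb),
                         se = unname(hs),
                         reference = levels(hosp) == ref,
                         stringsAsFactors = FALSE)
  hosp_tab <- hosp_tab[order(hosp_tab$hospital_id), ]
  rownames(hosp_tab) <- NULL
  structure(list(thresholds = unname(zeta),
                 casemix_coefficients = cf[!is_h],
                 hospitals = hosp_tab, loglik = loglik, n = n,
                 convergence = list(converged = converged, method = method)),
            class = "ordinal_fit")
}

# penalized cumulative-logit ML via BFGS on an unconstrained
# parameterization (first threshold + log-gaps), numerical Hessian for SEs
fit_po_penalized <- function(X, levels, lambda = 1e-4) {
  K <- max(levels)
  p <- ncol(X)
  unpack_th <- function(par) {
    if (K == 2L) par[1] else cumsum(c(par[1], exp(par[2:(K - 1)])))
  }
  negll <- function(par) {
    beta <- par[K:(K - 1 + p)]
    -proportional_odds_loglik(unpack_th(par), drop(X %*% beta), levels) +
      lambda * sum(beta^2)
  }
  th0 <- stats::qlogis(pmin(pmax(
    cumsum(prop.table(tabulate(levels, K)))[1:(K - 1)], 1e-4), 1 - 1e-4))
  start <- c(th0[1], if (K > 2L) log(pmax(diff(th0), 1e-3)), rep(0, p))
  opt <- stats::optim(start, negll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  th <- unpack_th(opt$par)
  beta <- stats::setNames(opt$par[K:(K - 1 + p)], colnames(X))
  V <- tryCatch(solve(opt$hessian), error = function(e) MASS::ginv(opt$hessian))
  se <- stats::setNames(sqrt(pmax(diag(V)[K:(K - 1 + p)], 0)), colnames(X))
  list(thresholds = th, beta = beta, se = se,
       loglik = -opt$value, converged = opt$convergence == 0)
}

#' Standardized composite rate per hospital
#'
#' Centres the fitted hospital coefficients on their unweighted mean (the
#' reference hospital's 0 included) and exponentiates:
#' `rate = 100 * exp(beta_h - mean(beta))`.  A rate above 100 means higher
#' odds of a worse composite outcome than the average hospital; the
#' geometric mean of `rate/100` over hospitals is exactly 1.
#'
#' @param fit an `ordinal_fit`.
#' @return data.frame `hospital_id`, `beta`, `rate`.
#' @export
standardized_composite_rate <- function(fit) {
  stopifnot(inherits(fit, "ordinal_fit"))
  b <- fit$hospitals$beta
  data.frame(hospital_id = fit$hospitals$hospital_id,
             beta = b, rate = 100 * exp(b - mean(b)),
             stringsAsFactors = FALSE)
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat("<ordinal_fit> ", nrow(x$hospitals), " hospitals, n = ", x$n,
      ", method: ", x$convergence$method, "\n", sep = "")
  cat("  thresholds:", paste(sprintf("%.3f", x$thresholds), collapse = " "),
      "\n")
  cat("  hospital beta range:",
      sprintf("[%.3f, %.3f]", min(x$hospitals$beta), max(x$hospitals$beta)),
      "\n")
  invisible(x)
}

#' Serialize an ordinal fit to JSON
#' @param fit an `ordinal_fit`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
ordinal_fit_to_json <- function(fit, path) {
  jsonlite::write_json(
    list(thresholds = fit$thresholds,
         casemix_coefficients = as.list(fit$casemix_coefficients),
         hospitals = fit$hospitals, loglik = fit$loglik, n = fit$n,
         convergence = fit$convergence),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
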