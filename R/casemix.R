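#' Merge sparse age groups
#'
#' Iteratively combines age groups with too few events into the immediately
#' older group, a standard device to stabilise logistic case-mix models in
#' strata with rare outcomes.  At each step the *youngest* group with fewer
#' than `min_events` events is merged into its older neighbour (the oldest
#' group, having no older neighbour, merges downward); merging repeats until
#' every remaining group has at least `min_events` events or a single group
#' is left.
#'
#' @param age_group ordered factor of age bands.
#' @param events logical/0-1 outcome vector, same length.
#' @param min_events minimum events per merged group (default 10).
#' @return named character vector mapping each original age band to its
#'   merged label (constituent bands joined with `"+"`).
#' @export
merge_sparse_age_groups <- function(age_group, events, min_events = 10L) {
  stopifnot(is.factor(age_group), length(age_group) == length(events))
  lev <- levels(age_group)
  cnt <- tapply(as.numeric(events), factor(age_group, levels = lev), sum)
  cnt[is.na(cnt)] <- 0
  groups <- as.list(seq_along(lev))      # contiguous runs of level indices
  repeat {
    if (length(groups) == 1L) break
    sizes <- vapply(groups, function(g) sum(cnt[g]), 0)
    i <- which(sizes < min_events)[1]
    if (is.na(i)) break
    j <- if (i < length(groups)) i + 1L else i - 1L
    groups[[min(i, j)]] <- c(groups[[min(i, j)]], groups[[max(i, j)]])
    groups[[max(i, j)]] <- NULL
  }
  map <- character(length(lev))
  names(map) <- lev
  for (g in groups) {
    lab <- if (length(g) == 1L) lev[g] else paste(lev[sort(g)], collapse = "+")
    map[lev[sort(g)]] <- lab
  }
  map
}

# ---- internal helpers -------------------------------------------------------

# outcome vector + analysis subset for one outcome
outcome_data <- function(records, outcome) {
  outcome <- match.arg(outcome, outcome_names())
  if (outcome == "mortality") {
    list(data = records, y = as.integer(records$died))
  } else if (outcome == "readmission") {
    s <- records[records$died == 0, , drop = FALSE]
    list(data = s, y = as.integer(s$readmitted_30d))
  } else {
    if (is.null(records$long_los))
      stop("records need a 'long_los' column (see long_los_flags()) ",
           "to model long LOS")
    s <- records[records$died == 0, , drop = FALSE]
    list(data = s, y = as.integer(s$long_los))
  }
}

# candidate model terms present with >1 observed level/value
candidate_terms <- function(data) {
  mains <- c("age_group", "sex", "unplanned", "transfer_in", "urgent_prior",
             "elixhauser", "year", "group")
  keep <- vapply(mains, function(v) {
    !is.null(data[[v]]) && length(unique(data[[v]])) > 1L
  }, TRUE)
  mains <- mains[keep]
  inter <- character(0)
  if (all(c("age_group", "elixhauser") %in% mains))
    inter <- c(inter, "age_group:elixhauser")
  if (all(c("unplanned", "transfer_in") %in% mains))
    inter <- c(inter, "unplanned:transfer_in")
  list(mains = mains, interactions = inter)
}

interaction_components <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# blockwise Wald chi-square p-value per model term
wald_term_p <- function(fit) {
  labs <- attr(stats::terms(fit), "term.labels")
  if (!length(labs)) return(stats::setNames(numeric(0), character(0)))
  # glm (unlike lm) does not store the assign map; rebuild it
  asgn <- fit$assign %||% attr(stats::model.matrix(fit), "assign")
  keep <- !is.na(stats::coef(fit))
  V <- stats::vcov(fit)                  # non-aliased coefficients only
  asgn_kept <- asgn[keep]
  b <- stats::coef(fit)[keep]
  p <- stats::setNames(rep(NA_real_, length(labs)), labs)
  for (j in seq_along(labs)) {
    idx <- which(asgn_kept == j)
    if (!length(idx)) { p[j] <- 1; next }  # fully aliased: certainly removable
    bj <- b[idx]; Vj <- V[idx, idx, drop = FALSE]
    st <- tryCatch(drop(t(bj) %*% solve(Vj, bj)), error = function(e) NULL)
    df <- length(idx)
    if (is.null(st)) {
      Vi <- MASS::ginv(Vj)
      st <- drop(t(bj) %*% Vi %*% bj)
      df <- qr(Vj)$rank
    }
    p[j] <- stats::pchisq(st, df = max(df, 1L), lower.tail = FALSE)
  }
  p
}

glm_ok <- function(fit) {
  b <- stats::coef(fit)
  isTRUE(fit$converged) && all(is.finite(b[!is.na(b)])) &&
    max(abs(b[!is.na(b)])) < 15
}

# ridge-penalized logistic fit (Newton), fallback for separation
fit_ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 100L) {
  p <- ncol(X)
  pen <- rep(lambda, p)
  pen[colnames(X) == "(Intercept)"] <- 0
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + 2 * diag(pen, p)
    g <- crossprod(X, y - mu) - 2 * pen * beta
    step <- tryCatch(solve(H, g), error = function(e) MASS::ginv(H) %*% g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-9) break
  }
  list(coefficients = stats::setNames(drop(beta), colnames(X)),
       vcov = tryCatch(solve(H), error = function(e) MASS::ginv(H)),
       converged = max(abs(step)) < 1e-6)
}

strip_env <- function(trm) { environment(trm) <- baseenv(); trm }

new_casemix_model <- function(outcome, group, retained, coefficients, trm,
                              xlevels, contrasts, age_merge_map, diagnostics) {
  structure(list(outcome = outcome, group = group,
                 retained_terms = retained, coefficients = coefficients,
                 terms = trm, xlevels = xlevels, contrasts = contrasts,
                 age_merge_map = age_merge_map, diagnostics = diagnostics),
            class = "casemix_model")
}

intercept_only_model <- function(outcome, group, y, map, fallback, n) {
  ev <- sum(y)
  p0 <- if (ev == 0L || ev == length(y)) (ev + 0.5) / (length(y) + 1) else
    mean(y)
  new_casemix_model(outcome, group, character(0),
                    c("(Intercept)" = stats::qlogis(p0)),
                    NULL, NULL, NULL, map,
                    list(converged = TRUE, n = n, n_events = ev,
                         fallback = fallback, term_p = numeric(0)))
}

# ---- main fitting entry point ----------------------------------------------

#' Fit a per-group case-mix model with backward elimination
#'
#' Fits a logistic regression for one outcome within one diagnosis/procedure
#' group, starting from all case-mix variables (age group, sex, method of
#' admission, transfer-in, urgent prior admission, Elixhauser count, year,
#' and - for pooled data - group), plus two a-priori interaction candidates
#' (age x Elixhauser, admission method x transfer).  Terms are then removed
#' backwards one at a time: at each step the eligible term with the largest
#' blockwise Wald p-value is dropped if p >= `p_remove`, and the model is
#' refitted.  A main effect is eligible for removal only once no retained
#' interaction contains it; multi-level factors are kept or dropped as a
#' block.  Ties in p are broken by reverse-alphabetical term name.
#'
#' Age groups with fewer than `min_events` events are first merged via
#' [merge_sparse_age_groups()].  Groups with fewer than `min_n` admissions
#' or `min_events` total events receive an intercept-only model; separated /
#' non-converged fits are re-fitted with a small L2 penalty
#' (`ridge_lambda`), and as a last resort fall back to intercept-only.
#' Readmission and long-LOS models are fitted on survivors only.
#'
#' @param records admission data.frame (needs a `long_los` column for the
#'   long-LOS outcome; see [long_los_flags()]).
#' @param outcome one of `"mortality"`, `"readmission"`, `"long_los"`.
#' @param group optional group label; if supplied, `records` is subset to it.
#' @param p_remove Wald p-value threshold for removal (retain p < 0.1).
#' @param min_n,min_events sparse-group thresholds for intercept-only fits.
#' @param ridge_lambda L2 penalty of the separation fallback.
#' @return an object of class `casemix_model`.
#' @export
fit_casemix_model <- function(records, outcome, group = NULL,
                              p_remove = 0.1, min_n = 25L, min_events = 10L,
                              ridge_lambda = 1e-4) {
  outcome <- match.arg(outcome, outcome_names())
  if (!is.null(group)) {
    records <- records[records$group == group, , drop = FALSE]
    if (!nrow(records)) stop("no records in group ", deparse(group))
  } else {
    group <- if (!is.null(records$group) &&
                 length(unique(records$group)) == 1L)
      as.character(records$group[1]) else "(pooled)"
  }
  od <- outcome_data(records, outcome)
  data <- od$data; y <- od$y
  n <- length(y); ev <- sum(y)

  map <- merge_sparse_age_groups(data$age_group, y, min_events)
  if (n < min_n || ev < min_events || ev == n)
    return(intercept_only_model(outcome, group, y, map, "sparse", n))

  data$age_group <- factor(unname(map[as.character(data$age_group)]),
                           levels = unique(unname(map)))
  if (!is.null(data$year)) data$year <- factor(data$year)
  data$.y <- y

  cand <- candidate_terms(data)
  current <- c(cand$mains, cand$interactions)
  if (!length(current))
    return(intercept_only_model(outcome, group, y, map, "no_covariates", n))

  fit <- NULL
  repeat {
    fml <- stats::reformulate(current, response = ".y")
    fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                       data = data, model = FALSE,
                                       x = FALSE, y = FALSE))
    if (!glm_ok(fit)) break
    pvals <- wald_term_p(fit)
    inters <- current[grepl(":", current, fixed = TRUE)]
    in_inter <- unique(unlist(lapply(inters, interaction_components)))
    eligible <- vapply(current, function(t) {
      grepl(":", t, fixed = TRUE) || !(t %in% in_inter)
    }, TRUE)
    drop_cand <- names(pvals)[eligible & pvals >= p_remove]
    if (!length(drop_cand)) break
    pd <- pvals[drop_cand]
    worst <- drop_cand[pd >= max(pd) - 1e-12]
    worst <- sort(worst, decreasing = TRUE)[1]  # reverse-alphabetical tie-break
    current <- setdiff(current, worst)
    if (!length(current)) {
      fit <- NULL
      break
    }
  }

  if (is.null(fit))  # everything eliminated
    return(intercept_only_model(outcome, group, y, map, "none", n))

  if (glm_ok(fit)) {
    cf <- stats::coef(fit)
    cf[is.na(cf)] <- 0
    return(new_casemix_model(
      outcome, group, current, cf, strip_env(stats::terms(fit)),
      fit$xlevels, fit$contrasts, map,
      list(converged = TRUE, n = n, n_events = ev, fallback = "none",
           term_p = wald_term_p(fit))))
  }

  # separation / non-convergence: penalized refit of the current model
  fml <- stats::reformulate(current, response = ".y")
  mf <- stats::model.frame(fml, data)
  X <- stats::model.matrix(fml, mf)
  rf <- fit_ridge_logistic(X, y, lambda = ridge_lambda)
  if (rf$converged) {
    trm <- strip_env(attr(mf, "terms"))
    return(new_casemix_model(
      outcome, group, current, rf$coefficients, trm,
      stats::.getXlevels(trm, mf), attr(X, "contrasts"), map,
      list(converged = TRUE, n = n, n_events = ev, fallback = "ridge",
           term_p = numeric(0))))
  }
  intercept_only_model(outcome, group, y, map, "intercept_only", n)
}

#' Expected outcome probabilities from a fitted case-mix model
#'
#' Applies the model's age-group merge map, rebuilds the design matrix and
#' returns the inverse-logit of the linear predictor per record.  Factor
#' levels never seen during fitting raise an error naming the offending
#' level (no silent imputation).
#'
#' @param model a `casemix_model`.
#' @param records admission records containing the retained covariates.
#' @return numeric vector of expected probabilities, one per record row.
#' @export
predict_expected <- function(model, records) {
  stopifnot(inherits(model, "casemix_model"))
  if (is.null(model$terms))
    return(rep(stats::plogis(model$coefficients[["(Intercept)"]]),
               nrow(records)))
  data <- records
  data$age_group <- factor(
    unname(model$age_merge_map[as.character(records$age_group)]),
    levels = model$xlevels$age_group %||% unique(unname(model$age_merge_map)))
  if (!is.null(data$year)) data$year <- factor(data$year)
  for (v in names(model$xlevels)) {
    bad <- setdiff(unique(as.character(data[[v]])), model$xlevels[[v]])
    if (length(bad))
      stop("unseen level(s) in '", v, "': ", paste(bad, collapse = ", "))
    data[[v]] <- factor(as.character(data[[v]]), levels = model$xlevels[[v]])
  }
  trm <- stats::delete.response(model$terms)
  mf <- stats::model.frame(trm, data, xlev = model$xlevels)
  mm <- stats::model.matrix(trm, mf, contrasts.arg = model$contrasts)
  beta <- model$coefficients[colnames(mm)]
  beta[is.na(beta)] <- 0
  stats::plogis(drop(mm %*% beta))
}

#' Fit case-mix models for every group and outcome
#'
#' Convenience wrapper looping [fit_casemix_model()] over all groups present
#' in `records` for the requested outcomes.
#'
#' @inheritParams fit_casemix_model
#' @param outcomes outcomes to model.
#' @return nested list `models[[outcome]][[group]]` of `casemix_model`s.
#' @export
fit_casemix_models <- function(records, outcomes = outcome_names(), ...) {
  grps <- levels(factor(records$group))
  out <- lapply(outcomes, function(o) {
    ms <- lapply(grps, function(g) fit_casemix_model(records, o, group = g, ...))
    stats::setNames(ms, grps)
  })
  stats::setNames(out, outcomes)
}

#' @export
print.casemix_model <- function(x, ...) {
  cat("<casemix_model> outcome:", x$outcome, " group:", x$group, "\n")
  cat("  n =", x$diagnostics$n, " events =", x$diagnostics$n_events,
      " fallback:", x$diagnostics$fallback, "\n")
  cat("  retained:", if (length(x$retained_terms))
    paste(x$retained_terms, collapse = ", ") else "(intercept only)", "\n")
  invisible(x)
}

#' Serialize case-mix models to JSON
#'
#' @param models output of [fit_casemix_models()] (or a single model).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
casemix_models_to_json <- function(models, path) {
  if (inherits(models, "casemix_model")) models <- list(models)
  ser <- rapply(models, how = "replace", classes = "casemix_model",
                function(m) list(
                  outcome = m$outcome, group = m$group,
                  retained_terms = m$retained_terms,
                  coefficients = as.list(m$coefficients),
                  age_merge_map = as.list(m$age_merge_map),
                  diagnostics = m$diagnostics[c("converged", "n", "n_events",
                                                "fallback")]))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
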