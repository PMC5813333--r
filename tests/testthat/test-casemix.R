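age_factor <- function(counts_per_band, events_per_band) {
  lev <- c("18-39", "40-54", "55-64", "65-74", "75+")[seq_along(counts_per_band)]
  age <- factor(rep(lev, counts_per_band), levels = lev, ordered = TRUE)
  ev <- unlist(mapply(function(n, e) c(rep(1L, e), rep(0L, n - e)),
                      counts_per_band, events_per_band, SIMPLIFY = FALSE))
  list(age = age, events = ev)
}

test_that("sparse age groups merge iteratively into the older neighbour", {
  # no band below threshold: identity map
  x <- age_factor(c(50, 50, 50), c(12, 11, 10))
  expect_identical(unname(merge_sparse_age_groups(x$age, x$events)),
                   c("18-39", "40-54", "55-64"))

  # [3,4,10]: 1 merges into 2 -> [7,10]; merged (7) into 3 -> single group
  x <- age_factor(c(50, 50, 50), c(3, 4, 10))
  m <- merge_sparse_age_groups(x$age, x$events)
  expect_length(unique(m), 1L)
  expect_identical(unname(m[1]), "18-39+40-54+55-64")

  # [12, 5]: oldest band is sparse, merges downward
  x <- age_factor(c(50, 50), c(12, 5))
  m <- merge_sparse_age_groups(x$age, x$events)
  expect_length(unique(m), 1L)

  # zero events everywhere: forced collapse to a single group
  x <- age_factor(c(30, 30, 30, 30, 30), c(0, 0, 0, 0, 0))
  expect_length(unique(merge_sparse_age_groups(x$age, x$events)), 1L)

  # partial merge: [3, 12, 40] -> first two combine, third stays
  x <- age_factor(c(50, 50, 50), c(3, 12, 40))
  m <- merge_sparse_age_groups(x$age, x$events)
  expect_identical(unname(m), c("18-39+40-54", "18-39+40-54", "55-64"))
})

test_that("records without covariate variation give the ML intercept", {
  set.seed(1)
  rec <- make_records(400, died = rbinom(400, 1, 0.2), long_los = FALSE)
  m <- fit_casemix_model(rec, "mortality")
  expect_identical(m$retained_terms, character(0))
  expect_equal(unname(m$coefficients["(Intercept)"]),
               qlogis(mean(rec$died)), tolerance = 1e-12)
  expect_equal(predict_expected(m, rec), rep(mean(rec$died), 400))
})

test_that("logistic coefficients match an independent IRLS fit to 1e-6", {
  set.seed(42)
  n <- 200
  rec <- make_records(n, died = 0L, long_los = FALSE)
  rec$sex <- rbinom(n, 1, 0.5)
  rec$unplanned <- rbinom(n, 1, 0.6)
  rec$elixhauser <- rpois(n, 1.5)
  eta <- -1 + 0.8 * rec$sex + 0.5 * rec$unplanned - 0.3 * rec$elixhauser
  rec$died <- rbinom(n, 1, plogis(eta))
  # p_remove > 1 keeps every candidate term: the full-model fit is compared
  m <- fit_casemix_model(rec, "mortality", p_remove = 1.01)
  expect_setequal(m$retained_terms, c("sex", "unplanned", "elixhauser"))
  X <- cbind("(Intercept)" = 1, sex = rec$sex, unplanned = rec$unplanned,
             elixhauser = rec$elixhauser)
  oracle <- irls_logistic(X, rec$died)
  expect_equal(m$coefficients[names(oracle)], oracle, tolerance = 1e-6)
})

test_that("in-sample expected events equal observed events for every model", {
  cfg <- scenario_presets("all_patients")
  cfg$n_hospitals <- 6L; cfg$volume_range <- c(900L, 900L)
  co <- generate_cohort(cfg, seed = 8)
  adm <- co$admissions
  adm$long_los <- long_los_flags(adm)$flags
  models <- fit_casemix_models(adm)
  for (o in c("mortality", "readmission", "long_los")) {
    for (g in names(models[[o]])) {
      m <- models[[o]][[g]]
      if (m$diagnostics$fallback == "ridge") next
      sub <- adm[adm$group == g, ]
      if (o != "mortality") sub <- sub[sub$died == 0, ]
      obs <- switch(o, mortality = sum(sub$died),
                    readmission = sum(sub$readmitted_30d),
                    long_los = sum(sub$long_los))
      if (obs == 0 || obs == nrow(sub)) next
      expect_equal(sum(predict_expected(m, sub)), obs,
                   tolerance = 1e-6, label = paste(o, g, "sum expected"))
    }
  }
})

test_that("backward elimination keeps null terms at about the retention level and always finds real effects", {
  reps <- 15L
  n_h <- 4L; vol <- c(1500L, 1500L)
  frac_null <- numeric(reps)
  age_kept <- logical(reps)
  for (r in seq_len(reps)) {
    co <- generate_cohort(effect_config(
      n_hospitals = n_h, volume = vol,
      tau2 = c(mortality = 0, readmission = 0, long_los = 0),
      seed = 100 + r))
    m0 <- fit_casemix_model(co$admissions, "mortality")
    # candidates: 6 case-mix mains + year + 2 interactions
    frac_null[r] <- length(m0$retained_terms) / 9

    co2 <- generate_cohort(effect_config(
      n_hospitals = n_h, volume = vol,
      tau2 = c(mortality = 0, readmission = 0, long_los = 0),
      cm_effects = c(age = 1.0, sex = 0, unplanned = 0, transfer_in = 0,
                     urgent_prior = 0, elixhauser = 0),
      seed = 200 + r))
    m1 <- fit_casemix_model(co2$admissions, "mortality")
    age_kept[r] <- "age_group" %in% m1$retained_terms

    # elimination monotonicity + hierarchy on every final model: every
    # *eligible* term (not shielded by a retained interaction) has p < 0.1
    for (m in list(m0, m1)) {
      if (m$diagnostics$fallback != "none") next
      inter <- grep(":", m$retained_terms, value = TRUE, fixed = TRUE)
      shielded <- unique(unlist(strsplit(inter, ":")))
      pfin <- m$diagnostics$term_p
      eligible <- setdiff(names(pfin), shielded)
      if (length(eligible))
        expect_true(all(pfin[eligible] < 0.1))
      for (i in inter)
        expect_true(all(strsplit(i, ":")[[1]] %in% m$retained_terms))
    }
  }
  expect_gt(mean(frac_null), 0.02)
  expect_lt(mean(frac_null), 0.25)
  expect_gte(sum(age_kept), reps - 1L)
})

test_that("predictions are invariant to record order and reject unseen levels", {
  co <- generate_cohort(effect_config(
    n_hospitals = 3L, volume = c(800L, 800L),
    cm_effects = c(age = 0.3, sex = 0.1, unplanned = 0.4, transfer_in = 0.2,
                   urgent_prior = 0.2, elixhauser = 0.2), seed = 13))
  adm <- co$admissions
  m <- fit_casemix_model(adm, "mortality")
  perm <- sample(nrow(adm))
  p1 <- predict_expected(m, adm)
  p2 <- predict_expected(m, adm[perm, ])
  expect_equal(p2, p1[perm], tolerance = 1e-12)

  if ("year" %in% m$retained_terms) {
    bad <- adm[1:5, ]; bad$year <- 1999L
    expect_error(predict_expected(m, bad), "unseen level.*1999")
  }
  expect_true(all(p1 > 0 & p1 < 1))
})

test_that("sparse groups and zero-event strata fall back to flagged intercept-only fits", {
  set.seed(3)
  rec <- make_records(20, died = c(rep(1L, 3), rep(0L, 17)), long_los = FALSE)
  rec$sex <- rbinom(20, 1, 0.5)
  m <- fit_casemix_model(rec, "mortality")     # n < 25
  expect_identical(m$diagnostics$fallback, "sparse")
  expect_identical(m$retained_terms, character(0))

  rec2 <- make_records(200, died = 0L, long_los = FALSE)
  rec2$sex <- rbinom(200, 1, 0.5)
  m2 <- fit_casemix_model(rec2, "mortality")   # zero events
  expect_identical(m2$diagnostics$fallback, "sparse")
  p <- predict_expected(m2, rec2)
  expect_true(all(p > 0 & p < 1))
})
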