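test_that("composite levels order outcomes from event-free survival to death", {
  expect_identical(assign_composite_level(FALSE, FALSE, FALSE), 1L)
  expect_identical(assign_composite_level(FALSE, TRUE, FALSE), 2L)
  expect_identical(assign_composite_level(FALSE, FALSE, TRUE), 3L)
  expect_identical(assign_composite_level(FALSE, TRUE, TRUE), 4L)
  expect_identical(assign_composite_level(TRUE, TRUE, NA), 5L)
  expect_identical(assign_composite_level(TRUE, FALSE, NA), 5L)
  expect_identical(
    assign_composite_level(c(0, 0, 1), c(1, 0, 1), c(0, 1, NA)),
    c(2L, 3L, 5L))
  expect_error(assign_composite_level(FALSE, FALSE, NA), "non-missing")
  expect_error(assign_composite_level(NA, FALSE, FALSE), "non-missing")
})

test_that("the cumulative-logit likelihood matches an independent implementation", {
  expect_equal(proportional_odds_loglik(0, 0, 1L), log(0.5), tolerance = 1e-12)
  expect_error(proportional_odds_loglik(c(1, 0.5), 0, 1L),
               "strictly increasing")
  expect_error(proportional_odds_loglik(c(0, 1), 0, 5L), "out of range")

  # shifting all thresholds moves the likelihood when data are off-centre
  y <- c(1L, 1L, 2L, 3L)
  l0 <- proportional_odds_loglik(c(-0.5, 0.5), rep(0, 4), y)
  l1 <- proportional_odds_loglik(c(0.5, 1.5), rep(0, 4), y)
  expect_false(isTRUE(all.equal(l0, l1)))

  set.seed(9)
  for (r in 1:20) {
    K <- sample(3:5, 1)
    th <- sort(rnorm(K - 1, sd = 1.5))
    n <- 30
    eta <- rnorm(n)
    yy <- sample.int(K, n, replace = TRUE)
    expect_equal(proportional_odds_loglik(th, eta, yy),
                 po_loglik_oracle(th, eta, yy), tolerance = 1e-10)
  }
})

tiny_po_instance <- function() {
  # 2 hospitals, 30 records, 3 occupied levels
  lv <- c(1, 1, 1, 1, 1, 1, 2, 2, 2, 3, 3, 1, 1, 2, 3,
          1, 1, 2, 2, 2, 3, 3, 3, 3, 1, 2, 3, 3, 2, 1)
  make_records(30, died = 0L, long_los = FALSE, readmitted = 0L,
               hospital = rep(c("H01", "H02"), each = 15)) |>
    transform(composite_level = lv)
}

test_that("the proportional-odds fit agrees with a brute-force likelihood optimization", {
  rec <- tiny_po_instance()
  fit <- fit_ordinal_model(rec, ref = "H01")
  oracle <- po_fit_oracle(rec$composite_level,
                          as.integer(rec$hospital_id == "H02"))
  expect_equal(fit$thresholds, oracle$thresholds, tolerance = 1e-4)
  expect_equal(fit$hospitals$beta[fit$hospitals$hospital_id == "H02"],
               oracle$beta, tolerance = 1e-4)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
})

test_that("the fitted parameters are a local likelihood optimum", {
  rec <- tiny_po_instance()
  fit <- fit_ordinal_model(rec, ref = "H01")
  eta_of <- function(beta) beta * (rec$hospital_id == "H02")
  b <- fit$hospitals$beta[fit$hospitals$hospital_id == "H02"]
  ll_hat <- proportional_odds_loglik(fit$thresholds, eta_of(b),
                                     rec$composite_level)
  set.seed(11)
  for (i in 1:100) {
    th <- fit$thresholds + rnorm(2, sd = 0.05)
    if (diff(th) <= 0) next
    ll <- proportional_odds_loglik(th, eta_of(b + rnorm(1, sd = 0.05)),
                                   rec$composite_level)
    expect_lte(ll, ll_hat + 1e-9)
  }
})

test_that("standardized composite rates centre the coefficients geometrically", {
  fit <- structure(list(hospitals = data.frame(
    hospital_id = c("A", "B"), beta = c(0, log(4)), se = c(0, 0.1),
    reference = c(TRUE, FALSE))), class = "ordinal_fit")
  r <- standardized_composite_rate(fit)
  expect_equal(r$rate, c(50, 200), tolerance = 1e-12)

  fit$hospitals <- data.frame(hospital_id = c("A", "B", "C"),
                              beta = c(0.3, 0.3, 0.3), se = 0.1,
                              reference = c(TRUE, FALSE, FALSE))
  expect_equal(standardized_composite_rate(fit)$rate, rep(100, 3))

  rec <- tiny_po_instance()
  rr <- standardized_composite_rate(fit_ordinal_model(rec))
  expect_equal(exp(mean(log(rr$rate / 100))), 1, tolerance = 1e-12)
})

test_that("the reference hospital choice does not change standardized rates", {
  set.seed(23)
  co <- generate_cohort(effect_config(n_hospitals = 5L,
                                      volume = c(400L, 400L)), seed = 23)
  adm <- co$admissions
  adm$long_los <- long_los_flags(adm)$flags
  adm$composite_level <- assign_composite_level(
    adm$died, adm$long_los, ifelse(adm$died == 1, FALSE, adm$readmitted_30d))
  r1 <- standardized_composite_rate(fit_ordinal_model(adm, ref = "H01"))
  r2 <- standardized_composite_rate(fit_ordinal_model(adm, ref = "H04"))
  expect_equal(r1$rate, r2$rate, tolerance = 1e-4)
})

test_that("two hospitals with one generative law have near-equal coefficients", {
  co <- generate_cohort(null_config(n_hospitals = 2L,
                                    volume = c(4000L, 4000L)), seed = 29)
  adm <- co$admissions
  adm$long_los <- long_los_flags(adm)$flags
  adm$composite_level <- assign_composite_level(
    adm$died, adm$long_los, ifelse(adm$died == 1, FALSE, adm$readmitted_30d))
  fit <- fit_ordinal_model(adm)
  expect_lt(abs(diff(fit$hospitals$beta)), 0.2)
  expect_true(all(diff(fit$thresholds) > 0))
  expect_identical(sum(fit$hospitals$reference), 1L)
  expect_equal(fit$hospitals$se[fit$hospitals$reference], 0)
})

test_that("ordinal fit validates its inputs", {
  rec <- tiny_po_instance()
  one <- rec[rec$hospital_id == "H01", ]
  expect_error(fit_ordinal_model(one), "at least 2 hospitals")
  flat <- rec; flat$composite_level <- 1L
  expect_error(fit_ordinal_model(flat), "2 distinct levels")
})
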