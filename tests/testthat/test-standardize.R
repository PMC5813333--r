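los_records <- function(los, group = "g") {
  rec <- make_records(length(los), died = 0L, long_los = FALSE,
                      readmitted = 0L, group = group)
  rec$los_days <- los
  rec
}

test_that("long-LOS cutoffs follow the nearest-rank convention with strict exceedance", {
  r <- long_los_flags(los_records(1:8), percentile = 75)
  expect_equal(unname(r$cutoffs["g"]), 6)       # ceil(0.75*8) = 6th order stat
  expect_identical(which(r$flags), 7:8)
  expect_equal(mean(r$flags), 0.25)

  r90 <- long_los_flags(los_records(seq(2, 20, 2)), percentile = 90)
  expect_equal(unname(r90$cutoffs["g"]), 18)    # ceil(0.9*10) = 9th order stat
  expect_identical(which(r90$flags), 10L)

  req <- long_los_flags(los_records(rep(3.5, 50)))
  expect_false(any(req$flags))                  # strict >: ties never flagged

  expect_error(long_los_flags(los_records(1:8), percentile = 80),
               "75 or 90")
  small <- long_los_flags(los_records(c(1, 2, 3)))
  expect_identical(small$low_confidence, "g")
})

test_that("cutoffs are per group and raising the percentile never adds flags", {
  set.seed(21)
  rec <- rbind(los_records(rlnorm(400, 1.5, 0.9), "a"),
               los_records(rlnorm(300, 2.5, 0.7), "b"))
  rec$group <- factor(rec$group)
  f75 <- long_los_flags(rec, 75)
  f90 <- long_los_flags(rec, 90)
  expect_true(all(which(f90$flags) %in% which(f75$flags)))
  expect_gt(f90$cutoffs["a"], f75$cutoffs["a"])
  # group cutoffs computed on the pooled within-group distribution
  expect_equal(unname(f75$cutoffs["b"]),
               sort(rec$los_days[rec$group == "b"])[ceiling(0.75 * 300)])
})

test_that("standardized ratios are 100*O/E with guarded domains", {
  expect_equal(standardized_ratio(50, 50), 100)
  expect_equal(standardized_ratio(0, 12.3), 0)
  expect_equal(standardized_ratio(15, 10), 150)
  expect_equal(standardized_ratio(c(1, 2), c(2, 2)), c(50, 100))
  expect_error(standardized_ratio(3, 0), "> 0")
  expect_error(standardized_ratio(-1, 5), ">= 0")
})

test_that("the whole population is standardized to exactly 100", {
  cfg <- effect_config(n_hospitals = 8L, volume = c(600L, 600L),
                       cm_effects = c(age = 0.3, sex = 0.1, unplanned = 0.4,
                                      transfer_in = 0.2, urgent_prior = 0.2,
                                      elixhauser = 0.2))
  co <- generate_cohort(cfg, seed = 31)
  adm <- co$admissions
  adm$long_los <- long_los_flags(adm)$flags
  models <- fit_casemix_models(adm)
  for (o in c("mortality", "readmission", "long_los")) {
    tab <- hospital_standardized_ratios(adm, models, o)
    expect_equal(standardized_ratio(sum(tab$observed), sum(tab$expected)),
                 100, tolerance = 1e-6)
    expect_true(all(tab$ratio >= 0))
  }
  expect_identical(
    attr(hospital_standardized_ratios(adm, models, "mortality"),
         "denominator_population"), "all")
  expect_identical(
    attr(hospital_standardized_ratios(adm, models, "readmission"),
         "denominator_population"), "survivors")
})

test_that("the unadjusted odds ratio reproduces the closed-form 2x2 value", {
  rec <- rbind(
    make_records(20, died = 1L, long_los = TRUE),
    make_records(80, died = 0L, long_los = TRUE, readmitted = 0L),
    make_records(10, died = 1L, long_los = FALSE),
    make_records(90, died = 0L, long_los = FALSE, readmitted = 0L))
  or <- patient_level_or(rec, "mortality", adjusted = FALSE)
  expect_equal(or$or, (20 * 90) / (80 * 10), tolerance = 1e-6)  # 2.25
  expect_true(or$ci[1] < or$or && or$or < or$ci[2])

  rec0 <- rbind(make_records(50, died = 0L, long_los = TRUE, readmitted = 0L),
                make_records(50, died = 1L, long_los = FALSE))
  expect_error(patient_level_or(rec0, "mortality"), "zero cell")
})

test_that("the null coupling is covered by the Wald interval at the nominal rate", {
  hits <- 0L
  reps <- 20L
  for (r in seq_len(reps)) {
    co <- generate_cohort(null_config(n_hospitals = 5L,
                                      volume = c(1000L, 1000L)),
                          seed = 300 + r)
    adm <- co$admissions
    adm$long_los <- long_los_flags(adm)$flags
    or <- patient_level_or(adm, "mortality", adjusted = FALSE)
    hits <- hits + (or$ci[1] <= 1 && 1 <= or$ci[2])
  }
  expect_gte(hits, 16L)  # ~95% coverage; P(X<16 | p=.95, n=20) ~ 3e-4
})

test_that("the adjusted model recovers a planted LOS-mortality coupling despite hospital confounding", {
  cfg <- scenario_presets("all_patients")
  cfg$n_hospitals <- 12L
  cfg$volume_range <- c(2500L, 2500L)
  co <- generate_cohort(cfg, seed = 17)
  adm <- co$admissions
  adm$long_los <- long_los_flags(adm)$flags
  adj <- patient_level_or(adm, "mortality", adjusted = TRUE)
  # planted log-OR is log(1.45); allow a 99% interval around the estimate
  z99 <- qnorm(0.995)
  expect_gt(log(1.45), adj$log_or - z99 * adj$se)
  expect_lt(log(1.45), adj$log_or + z99 * adj$se)
  # positive hospital-level mortality/LOS correlation inflates the
  # unadjusted estimate relative to the centre-adjusted one
  unadj <- patient_level_or(adm, "mortality", adjusted = FALSE)
  expect_gt(unadj$or, adj$or)
})

test_that("hospital correlations are Pearson with t-based p-values and guarded inputs", {
  a <- data.frame(hospital_id = sprintf("H%02d", 1:10), ratio = seq(80, 125, 5))
  b <- a; b$ratio <- 2 * a$ratio + 5
  expect_equal(hospital_correlations(a, b)$r, 1, tolerance = 1e-12)
  bneg <- a; bneg$ratio <- -a$ratio
  expect_equal(hospital_correlations(a, bneg)$r, -1, tolerance = 1e-12)

  set.seed(5)
  x <- rnorm(26); y <- rnorm(26)
  ct <- hospital_correlations(x, y)
  ref <- cor.test(x, y)
  expect_equal(ct$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ct$p, ref$p.value, tolerance = 1e-12)

  flat <- a; flat$ratio <- 100
  expect_error(hospital_correlations(a, flat), "zero variance")
  expect_error(hospital_correlations(a[1:2, ], b[1:2, ]), "at least 3")
  expect_error(hospital_correlations(a, b[1:8, ]), "hospital sets differ")
})
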