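test_that("20-2-20 staging counts strict-inequality factors", {
  st <- stage_20_2_20(c(2.5, 1.0, 2.0, 3.0), c(25, 10, 10, 30),
                      c(15, 10, 10, 25))
  expect_equal(as.character(st$stage), c("high", "low", "low", "high"))
  expect_equal(st$factors, c(2, 0, 0, 3))
  one <- stage_20_2_20(2.1, 10, 10)
  expect_equal(as.character(one$stage), "intermediate")
  miss <- stage_20_2_20(NA, 25, 25)
  expect_true(is.na(miss$stage))
  expect_error(stage_20_2_20(-1, 10, 10), "non-negative")
})

test_that("evolving-biomarker rules reproduce their boundary cases", {
  mp <- function(v, m = c(0, 10)) data.frame(month = m, value = v)
  # +60% and +0.6 at month 10 -> eMP
  expect_true(detect_evolving_biomarkers(mp(c(1.0, 1.6)))$emp)
  # +30% but +0.3 < 0.5 absolute -> no
  expect_false(detect_evolving_biomarkers(mp(c(1.0, 1.3), c(0, 6)))$emp)
  # +0.6 but +15% < 25% relative -> no
  expect_false(detect_evolving_biomarkers(mp(c(4.0, 4.6), c(0, 9)))$emp)
  # hemoglobin drop of 0.6 -> eHb
  fl <- detect_evolving_biomarkers(hb_series = mp(c(12.0, 11.4), c(0, 8)))
  expect_true(fl$ehb)
  expect_false(detect_evolving_biomarkers(hb_series = mp(c(12.0, 11.6), c(0, 8)))$ehb)
  # exactly-12-month reading counts; later ones do not
  expect_true(detect_evolving_biomarkers(mp(c(1.0, 1.6), c(0, 12)))$emp)
  expect_false(detect_evolving_biomarkers(mp(c(1.0, 1.6), c(0, 13)))$emp)
  # exact 0.5 boundaries are inclusive
  expect_true(detect_evolving_biomarkers(mp(c(1.0, 1.5)))$emp)
  expect_true(detect_evolving_biomarkers(hb_series = mp(c(12.0, 11.5)))$ehb)
  expect_error(detect_evolving_biomarkers(data.frame(month = 3, value = 1)),
               "baseline")
  expect_warning(
    z <- detect_evolving_biomarkers(mp(c(0, 0.6))), "absolute rule")
  expect_true(z$emp)
})

test_that("KM estimator matches empirical survival and handles censoring", {
  km <- km_fit(1:5, rep(TRUE, 5))
  expect_equal(km$curves$survival, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$medians$median, 3)

  allc <- km_fit(1:4, rep(FALSE, 4))
  expect_true(all(allc$curves$survival == 1) || nrow(allc$curves) == 0)
  expect_true(is.na(allc$medians$median))
  # reverse KM on fully-censored data is the empirical median of follow-up
  expect_equal(allc$median_followup, 2.5)

  set.seed(40)
  times <- rexp(60, 0.2)
  km2 <- km_fit(times, rep(TRUE, 60))
  for (i in seq_len(nrow(km2$curves))) {
    expect_equal(km2$curves$survival[i],
                 empirical_survival(times, km2$curves$time[i]))
  }
  expect_true(all(diff(km2$curves$survival) <= 0))
  expect_error(km_fit(c(0, 1), c(TRUE, TRUE)), "positive")
})

test_that("log-rank test matches its hand-computed example and null identity", {
  null <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(TRUE, 6), rep(1:2, each = 3))
  expect_equal(null$chisq, 0, tolerance = 1e-12)
  expect_equal(null$p, 1, tolerance = 1e-12)

  # groups (1,2) vs (3,4), all events: O-E = 7/6, V = 17/36 -> chisq = 49/17
  lr <- logrank_test(c(1, 2, 3, 4), rep(TRUE, 4), c("a", "a", "b", "b"))
  expect_equal(lr$chisq, 49 / 17, tolerance = 1e-8)
  expect_equal(lr$df, 1)

  swap <- logrank_test(c(1, 2, 3, 4), rep(TRUE, 4), c("b", "b", "a", "a"))
  expect_equal(swap$chisq, lr$chisq)
  expect_error(logrank_test(1:3, rep(TRUE, 3), rep("a", 3)), "2 groups")
})

test_that("Cox fit is unbiased on null data and validates covariates", {
  set.seed(41)
  times <- rexp(1000, 0.1)
  grp <- rep(0:1, 500)
  fit <- cox_fit(data.frame(grp = grp), times, rep(TRUE, 1000))
  expect_gt(fit$table$hr, 0.8)
  expect_lt(fit$table$hr, 1.25)
  expect_error(cox_fit(data.frame(z = rep(1, 10)), rexp(10), rep(TRUE, 10)),
               "constant")
})

test_that("Cox recovers a planted two-group log-hazard ratio", {
  set.seed(42)
  n <- 1000
  grp <- rep(0:1, n / 2)
  times <- rexp(n, rate = 0.05 * 4.5^grp)
  fit <- cox_fit(data.frame(grp = grp), times, rep(TRUE, n))
  expect_lt(abs(fit$table$coef - log(4.5)), 0.2)
})

test_that("nested Cox model comparison behaves at its degenerate point", {
  set.seed(43)
  n <- 120
  x <- rnorm(n); times <- rexp(n, 0.1 * exp(0.5 * x)); ev <- rep(TRUE, n)
  base <- cox_fit(data.frame(x = x), times, ev)
  same <- compare_cox_models(base, base)
  expect_equal(same$lr_chisq, 0)
  expect_equal(same$df, 0)
  ext <- cox_fit(data.frame(x = x, noise = rnorm(n)), times, ev)
  cmp <- compare_cox_models(base, ext)
  expect_equal(cmp$df, 1)
  expect_gte(cmp$lr_chisq, 0)
})

test_that("concordance index matches pair enumeration and its invariances", {
  expect_equal(c_index(c(3, 2, 1), 1:3, rep(TRUE, 3))$c, 1)
  expect_equal(c_index(c(1, 2, 3), 1:3, rep(TRUE, 3))$c, 0)
  # one tied pair contributes 0.5: C = 2.5/3
  tied <- c_index(c(2, 2, 1), 1:3, rep(TRUE, 3))
  expect_equal(tied$c, 2.5 / 3, tolerance = 1e-12)
  # invariant under strictly monotone transformation of the scores
  set.seed(44)
  sc <- rnorm(50); tm <- rexp(50); ev <- rbinom(50, 1, 0.7) == 1
  expect_equal(c_index(sc, tm, ev)$c, c_index(exp(sc), tm, ev)$c)
  expect_error(c_index(c(Inf, 1), c(1, 2), c(TRUE, TRUE)), "finite")
  expect_error(c_index(c(1, 2), c(1, 2), c(FALSE, FALSE)), "usable")
})

test_that("biomarker association reproduces the cross-product odds ratio", {
  flags <- c(rep(TRUE, 20), rep(FALSE, 30), rep(TRUE, 5), rep(FALSE, 95))
  risk <- c(rep("high", 50), rep("low", 100))
  out <- biomarker_association(flags, risk)
  expect_equal(out$odds_ratio, (20 * 95) / (30 * 5), tolerance = 1e-12)
  expect_lt(out$p, 0.01)
  null <- biomarker_association(rep(c(TRUE, FALSE), 50),
                                rep(c("high", "high", "low", "low"), 25))
  expect_equal(null$odds_ratio, 1)
  logi <- biomarker_association(flags, risk, method = "logistic")
  expect_equal(logi$odds_ratio, (20 * 95) / (30 * 5), tolerance = 1e-6)
  expect_error(biomarker_association(rep(TRUE, 10), rep(c("high", "low"), 5)),
               "degenerate")
})

test_that("LR statistic for a pure-noise extension is null-distributed", {
  set.seed(45)
  pvals <- vapply(1:500, function(r) {
    n <- 100
    x <- rnorm(n)
    tm <- rexp(n, 0.1 * exp(0.4 * x))
    base <- cox_fit(data.frame(x = x), tm, rep(TRUE, n))
    ext <- cox_fit(data.frame(x = x, noise = rnorm(n)), tm, rep(TRUE, n))
    compare_cox_models(base, ext)$p
  }, 1)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("genetic risk adds concordance beyond clinical stage when it drives hazard", {
  better <- vapply(1:10, function(s) {
    co <- generate_cohort(cohort_config(seed = 400 + s))
    cl <- co$clinical
    st <- stage_20_2_20(cl$m_protein_baseline, cl$flc_ratio, cl$bmpc_percent)
    base <- cox_fit(data.frame(stage = st$stage), cl$ttp_months, cl$progressed)
    ext <- cox_fit(data.frame(stage = st$stage,
                              risk = factor(cl$risk_group,
                                            levels = c("low", "intermediate",
                                                       "high"))),
                   cl$ttp_months, cl$progressed)
    compare_cox_models(base, ext)$delta_c > 0
  }, logical(1))
  expect_gte(sum(better), 9)
})
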