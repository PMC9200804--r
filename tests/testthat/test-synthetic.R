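test_that("cohort generation is bit-identical under a fixed seed", {
  a <- generate_cohort(cohort_config(n_patients = 40, seed = 3))
  b <- generate_cohort(cohort_config(n_patients = 40, seed = 3))
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$true_labels, b$true_labels)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$series, b$series)
  c_ <- generate_cohort(cohort_config(n_patients = 40, seed = 4))
  expect_false(identical(a$matrix$values, c_$matrix$values))
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(mixing_proportions = c(0.5, 0.4, 0.05, 0.02, 0.02, 0.02)),
               "sum to 1")
  expect_error(cohort_config(p_signature = 1.2), "rates")
  expect_error(cohort_config(survival_medians_years = c(low = -1, intermediate = 5,
                                                        high = 2)), "> 0")
  expect_error(cohort_config(n_subtypes = 2,
                             signature_map = list(A = "F1", B = "F2"),
                             feature_catalog = c("F1")), "not in catalog")
})

test_that("signature and hyperdiploidy prevalences match their Bernoulli rates", {
  co <- generate_cohort(cohort_config(n_patients = 5000, seed = 21))
  X <- co$matrix$values
  # a signature feature in its own subtype: rate 0.7
  in_hl1 <- co$true_labels == "HL1"
  obs <- sum(X[in_hl1, "NRAS"])
  ci <- stats::binom.test(obs, sum(in_hl1), conf.level = 0.99)$conf.int
  expect_true(ci[1] <= 0.7 && 0.7 <= ci[2])
  # background rate elsewhere
  obs_bg <- sum(X[!in_hl1, "NRAS"])
  ci_bg <- stats::binom.test(obs_bg, sum(!in_hl1), conf.level = 0.99)$conf.int
  expect_true(ci_bg[1] <= 0.05 && 0.05 <= ci_bg[2])
  # HL2-analog hyperdiploidy prevalence ~ 0.69
  in_hl2 <- co$true_labels == "HL2"
  obs_h <- sum(X[in_hl2, "HYPERDIPLOIDY"])
  ci_h <- stats::binom.test(obs_h, sum(in_hl2), conf.level = 0.99)$conf.int
  expect_true(ci_h[1] <= 0.69 && 0.69 <= ci_h[2])
  # translocations are sparse outside their subtype
  out_tl2 <- co$true_labels != "TL2"
  expect_lt(mean(X[out_tl2, "t(11;14)"]), 0.02)
})

test_that("noise-free configuration collapses subtypes to identical rows", {
  cfg <- cohort_config(n_patients = 30, p_signature = 1, p_background = 0,
                       p_background_tra = 0,
                       hyperdiploid_rates = c(HL1 = 1, HL2 = 1, TL1 = 0,
                                              HL3 = 1, TL2 = 0, HL4 = 1),
                       seed = 5)
  co <- generate_cohort(cfg)
  for (s in unique(co$true_labels)) {
    rows <- co$matrix$values[co$true_labels == s, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(col) length(unique(col)) == 1)))
  }
})

test_that("survival generator hits its censoring and rate contracts", {
  cfg0 <- cohort_config(n_patients = 300, censoring_rate = 0, seed = 6)
  co <- generate_cohort(cfg0)
  expect_true(all(co$clinical$progressed))

  cfg <- cohort_config(n_patients = 5000, seed = 7)
  labels <- generate_cohort(cfg)$true_labels
  surv <- generate_survival(labels, config = cfg)
  cens <- mean(!surv$progressed)
  expect_lt(abs(cens - 0.34), 0.03)
  expect_error(generate_survival(c(ZZ = "unknown"), config = cfg), "unmapped")
})

test_that("survival times recover the planted medians without censoring", {
  cfg <- cohort_config(n_patients = 6000, censoring_rate = 0, seed = 8)
  labels <- generate_cohort(cfg)$true_labels
  surv <- generate_survival(labels, config = cfg)
  km <- km_fit(surv$ttp_months, surv$progressed, surv$risk_group)
  med <- setNames(km$medians$median, km$medians$group) / 12
  expect_lt(abs(med[["high"]] - 2.6) / 2.6, 0.1)
  expect_lt(abs(med[["intermediate"]] - 5.2) / 5.2, 0.1)
  expect_lt(abs(med[["low"]] - 11) / 11, 0.15)
})

test_that("designated evolving patients satisfy the eMP/eHb rules, others never", {
  cfg <- cohort_config(n_patients = 400, seed = 9)
  labels <- generate_cohort(cfg)$true_labels
  evo <- generate_evolving_flags(labels, config = cfg)
  det <- detect_evolving_cohort(evo$series)
  m <- merge(evo$flags, det, by = "patient_id")
  expect_identical(m$emp.x, m$emp.y)
  expect_identical(m$ehb.x, m$ehb.y)
})

test_that("a unit odds multiplier equalizes evolving prevalence across risk", {
  cfg <- cohort_config(n_patients = 5000, evolving_odds = c(emp = 1, ehb = 1),
                       base_evolving_prob = 0.2, seed = 10)
  labels <- generate_cohort(cfg)$true_labels
  evo <- generate_evolving_flags(labels, config = cfg)
  high <- evo$flags$risk_group == "high"
  p_high <- mean(evo$flags$emp[high]); p_oth <- mean(evo$flags$emp[!high])
  se <- sqrt(0.2 * 0.8 * (1 / sum(high) + 1 / sum(!high)))
  expect_lt(abs(p_high - p_oth), 2.576 * se)
})

test_that("written cohorts are read back identically by the package readers", {
  co <- generate_cohort(cohort_config(n_patients = 25, seed = 11))
  dir <- tempfile()
  paths <- write_cohort(co, dir)
  X2 <- read_alteration_matrix(paths[["matrix"]])
  expect_identical(X2$values, co$matrix$values)
  cl <- read_clinical_table(paths[["clinical"]])
  expect_equal(cl$ttp_months, co$clinical$ttp_months)
  sr <- read_biomarker_series(paths[["series"]])
  expect_equal(nrow(sr), nrow(co$series))
})
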