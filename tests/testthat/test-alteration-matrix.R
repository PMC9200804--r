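test_that("write/read roundtrip is the identity on valid matrices", {
  vals <- matrix(c(1, 0, 1, 0, 1, 0, 1, 1, 0), 3,
                 dimnames = list(c("A", "B", "C"), c("NRAS", "del16q", "t(11;14)")))
  X <- alteration_matrix(vals)
  path <- tempfile(fileext = ".tsv")
  write_alteration_matrix(X, path)
  X2 <- read_alteration_matrix(path)
  expect_identical(X2$values, X$values)
  expect_identical(X2$patient_ids, X$patient_ids)
  expect_identical(X2$feature_ids, X$feature_ids)
  # csv dialect too
  pcsv <- tempfile(fileext = ".csv")
  write_alteration_matrix(X, pcsv)
  expect_identical(read_alteration_matrix(pcsv)$values, X$values)
})

test_that("validation errors name the offending cells and ids", {
  vals <- matrix(c(1, 0, 2, 0), 2, dimnames = list(c("A", "B"), c("F1", "F2")))
  expect_error(alteration_matrix(vals), "patient 'A', feature 'F2'")
  expect_error(alteration_matrix(vals), "2")
  dup <- matrix(0:1, 2, 2, dimnames = list(c("A", "A"), c("F1", "F2")))
  expect_error(alteration_matrix(dup), "duplicate patient id\\(s\\): A")
  expect_error(
    alteration_matrix(matrix(1, 1, 2, dimnames = list("A", c("F1", "F2")))),
    "at least 2 patients")
  na_vals <- matrix(c(1, NA, 0, 1), 2, dimnames = list(c("A", "B"), c("F1", "F2")))
  expect_error(alteration_matrix(na_vals), "non-binary")
})

test_that("binarize_calls matches the presence/absence definition", {
  cat3 <- c("NRAS", "del16q", "t(11;14)")
  X <- binarize_calls(snv_calls = list(A = "NRAS"),
                      cna_calls = list(A = "del16q"),
                      patient_ids = c("A", "B"), feature_catalog = cat3)
  expect_equal(unname(X$values["A", ]), c(1L, 1L, 0L))
  expect_equal(unname(X$values["B", ]), c(0L, 0L, 0L))   # all-zero row kept
  expect_identical(attr(X, "all_zero_patients"), "B")
  expect_identical(unname(X$feature_class), c("SNV", "CNA", "TRANSLOCATION"))
})

test_that("binarize_calls is idempotent and order-invariant", {
  cat3 <- c("NRAS", "KRAS", "del16q")
  a <- binarize_calls(snv_calls = list(A = c("NRAS", "NRAS", "KRAS"), B = "KRAS"),
                      feature_catalog = cat3)
  b <- binarize_calls(snv_calls = list(A = c("KRAS", "NRAS"), B = "KRAS"),
                      feature_catalog = cat3)
  expect_identical(a$values, b$values)
  expect_true(all(a$values %in% 0:1))
})

test_that("uncataloged calls error in strict mode, warn-and-skip otherwise", {
  expect_error(
    binarize_calls(snv_calls = list(A = "BRAF", B = "NRAS"),
                   feature_catalog = c("NRAS", "KRAS")),
    "BRAF")
  expect_warning(
    X <- binarize_calls(snv_calls = list(A = "BRAF", B = "NRAS"),
                        feature_catalog = c("NRAS", "KRAS"), strict = FALSE),
    "BRAF")
  expect_equal(sum(X$values["A", ]), 0L)
  expect_error(binarize_calls(snv_calls = list(A = "NRAS"),
                              feature_catalog = character(0)), "non-empty")
})

test_that("ploidy flags follow the >48 / <45 chromosome thresholds", {
  fl <- derive_ploidy_flags(c(49, 44, 46, 45, 48))
  expect_equal(fl$hyperdiploid, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(fl$hypodiploid, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  # never both
  fl_all <- derive_ploidy_flags(1:120)
  expect_false(any(fl_all$hyperdiploid & fl_all$hypodiploid))
  expect_error(derive_ploidy_flags(0), "positive")
  expect_error(derive_ploidy_flags(46.5), "integers")
})

test_that("MAF and GISTIC readers produce call lists for binarize_calls", {
  maf <- tempfile(fileext = ".maf")
  writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
               "NRAS\tS1\tMissense_Mutation",
               "KRAS\tS1\tMissense_Mutation",
               "NRAS\tS2\tNonsense_Mutation"), maf)
  calls <- read_maf_calls(maf)
  expect_setequal(calls$S1, c("NRAS", "KRAS"))
  expect_equal(calls$S2, "NRAS")

  gistic <- tempfile(fileext = ".tsv")
  writeLines(c("sample\t1q\t16q", "S1\t2\t-1", "S2\t0\t0"), gistic)
  g <- read_gistic_calls(gistic)
  expect_setequal(g$S1, c("gain1q", "del16q"))
  expect_length(g$S2, 0)
  expect_equal(read_gistic_calls(gistic, direction = "gain")$S1, "gain1q")

  X <- binarize_calls(snv_calls = calls, cna_calls = g,
                      feature_catalog = c("NRAS", "KRAS", "gain1q", "del16q"))
  expect_equal(unname(X$values["S1", ]), c(1L, 1L, 1L, 1L))
  expect_equal(unname(X$values["S2", ]), c(1L, 0L, 0L, 0L))
})

test_that("clinical and series readers validate their contracts", {
  cl <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,m_protein_baseline,ttp_months,progressed",
               "P1,1.2,24,TRUE", "P2,2.5,10,FALSE"), cl)
  d <- read_clinical_table(cl)
  expect_type(d$progressed, "logical")
  writeLines(c("patient_id,m_protein_baseline,ttp_months,progressed",
               "P1,1.2,-3,TRUE"), cl)
  expect_error(read_clinical_table(cl), "positive")

  sr <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,marker,month,value",
               "P1,mp,0,1.0", "P1,mp,6,1.4", "P1,hb,0,13.0"), sr)
  s <- read_biomarker_series(sr)
  expect_equal(nrow(s), 3)
  writeLines(c("patient_id,marker,month,value",
               "P1,mp,6,1.0", "P1,mp,6,1.4"), sr)
  expect_error(read_biomarker_series(sr), "duplicate")
})
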