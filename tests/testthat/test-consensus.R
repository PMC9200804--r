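test_that("Dice dissimilarity matches its set formula", {
  expect_equal(dice_dissimilarity(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(dice_dissimilarity(c(1, 0, 0), c(0, 1, 0)), 1)
  expect_equal(dice_dissimilarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(dice_dissimilarity(c(0, 0), c(0, 0)), 0)
  expect_error(dice_dissimilarity(c(1, 0), c(1, 0, 1)), "equal length")

  set.seed(5)
  for (rep in 1:20) {
    L <- sample(2:10, 1)
    a <- rbinom(L, 1, 0.5); b <- rbinom(L, 1, 0.5)
    expect_equal(dice_dissimilarity(a, b), dice_oracle(a, b))
  }
  # matrix form agrees with the scalar form pairwise
  set.seed(6)
  X <- matrix(rbinom(40, 1, 0.4), 8, 5)
  D <- dice_dist(X)
  expect_true(isSymmetric(D))
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(D[i, j], dice_dissimilarity(X[i, ], X[j, ]))
  }
})

test_that("consensus matrix obeys its definition and determinism contracts", {
  pl <- make_planted(n_per = 3, K = 2, f_per = 3, seed = 4)
  cons <- build_consensus(pl$X, K = 2, n_runs = 10, seed = 1)
  C <- cons$consensus
  expect_true(all(diag(C) == 1))
  expect_true(isSymmetric(C))
  expect_true(all(C >= 0 & C <= 1))
  # noiseless 2-block cohort: every restart recovers the same partition
  expect_true(all(C %in% c(0, 1)))
  expect_true(all(C[pl$truth == 1, pl$truth == 1] == 1))
  expect_true(all(C[pl$truth == 1, pl$truth == 2] == 0))

  again <- build_consensus(pl$X, K = 2, n_runs = 10, seed = 1)
  expect_identical(C, again$consensus)
  expect_error(build_consensus(pl$X, K = 2, n_runs = 1), "n_runs")
})

test_that("consensus cut recovers blocks and handles degenerate K", {
  pl <- make_planted(n_per = 4, K = 2, f_per = 3, seed = 8)
  cons <- build_consensus(pl$X, K = 2, n_runs = 10, seed = 2)
  lab <- cut_consensus(cons, 2)
  expect_identical(ari(lab, pl$truth), 1)

  expect_equal(unname(cut_consensus(cons, 1)), rep(1L, 8))
  C <- diag(8)          # all-distinct rows
  expect_equal(sort(unique(cut_consensus(C, 8))), 1:8)
  expect_error(cut_consensus(C, 9), "exceed")
})

test_that("cut labels are canonical by decreasing size and order-invariant", {
  pl <- make_planted(n_per = 3, K = 3, f_per = 4, seed = 3)
  X <- rbind(pl$X, pl$X[pl$truth == 1, ])   # make cluster 1 the largest
  rownames(X) <- sprintf("Q%02d", seq_len(nrow(X)))
  truth <- c(pl$truth, rep(1, 3))
  cons <- build_consensus(X, K = 3, n_runs = 10, seed = 5)
  lab <- cut_consensus(cons, 3)
  sizes <- as.integer(table(lab))
  expect_identical(sizes, sort(sizes, decreasing = TRUE))
  expect_equal(sizes[1], 6L)

  perm <- sample(nrow(X))
  cons_p <- build_consensus(X[perm, ], K = 3, n_runs = 10, seed = 5)
  lab_p <- cut_consensus(cons_p, 3)
  expect_identical(ari(lab_p, truth[perm]), 1)
})

test_that("K-L divergence is non-negative and zero at exact reconstruction", {
  pl <- make_planted(n_per = 4, K = 3, f_per = 4, seed = 9)
  fit <- bmf_fit(pl$X, K = 3, seed = 1)
  expect_gte(kl_divergence(pl$X, fit), 0)
  set.seed(10)
  Xr <- matrix(rbinom(50, 1, 0.5), 5, 10)
  Xr[1, 1] <- 1L
  f2 <- bmf_fit(Xr, K = 2, seed = 1)
  expect_gte(kl_divergence(Xr, f2), 0)
})

test_that("diagnostics hit their exact values on noiseless planted cohorts", {
  pl <- make_planted(n_per = 5, K = 3, f_per = 4, seed = 12)
  diag3 <- k_diagnostics(pl$X, K_range = 3, n_runs = 5, seed = 3)
  row <- diag3$summary[diag3$summary$K == 3, ]
  expect_equal(row$variance_explained, 1)
  expect_equal(row$residual, 0)
  expect_lt(row$kl, 1e-6)
  # identical within, distinct between -> silhouette exactly 1
  expect_equal(row$silhouette, 1)
})

test_that("select_k picks the largest K-L drop among high-silhouette K", {
  fake <- structure(list(
    summary = data.frame(K = 2:8, size = 214,
                         silhouette = c(0.62, 0.63, 0.64, 0.63, 0.65, 0.61, 0.60),
                         residual = 0, variance_explained = 1,
                         kl = c(900, 700, 540, 420, 180, 165, 160)),
    full_size = 214),
    class = "k_diagnostics")
  sel <- select_k(fake)
  expect_equal(sel$K, 6)          # largest drop 5 -> 6, silhouette flat
  expect_true(all(c("K", "kl", "kl_drop", "silhouette") %in% names(sel$rationale)))

  single <- structure(list(
    summary = data.frame(K = 4, size = 100, silhouette = 0.5, residual = 1,
                         variance_explained = 0.9, kl = 10),
    full_size = 100), class = "k_diagnostics")
  expect_equal(select_k(single)$K, 4)
})

test_that("downsampled diagnostics run and report per-size variability", {
  pl <- make_planted(n_per = 10, K = 3, f_per = 4, p_sig = 0.8, p_bg = 0.05,
                     seed = 21)
  d <- k_diagnostics(pl$X, K_range = 2:4, n_runs = 5,
                     downsample_sizes = c(15, 24), n_downsamples = 3, seed = 2)
  expect_setequal(unique(d$summary$size), c(15, 24, 30))
  expect_true(all(is.finite(d$summary$kl)))
  sub <- d$summary[d$summary$size == 15, ]
  expect_true(all(c("silhouette_var", "kl_var") %in% names(sub)))
  expect_error(k_diagnostics(pl$X, K_range = 2:4, downsample_sizes = 4),
               "at least")
})

test_that("bmf_subtype recovers planted subtypes end-to-end", {
  pl <- make_planted(n_per = 10, K = 3, f_per = 5, p_sig = 0.8, p_bg = 0.05,
                     seed = 30)
  fit <- bmf_subtype(pl$X, K = 3, n_runs = 20, seed = 7)
  expect_s3_class(fit, "bmf_subtype")
  expect_gte(ari(fit$labels, pl$truth), 0.9)
  s <- summary(fit)
  expect_length(s$top_enriched, 3)
  expect_output(print(fit), "consensus clusters")
})

test_that("diagnostic variability stabilizes with downsample size", {
  co <- generate_cohort(cohort_config(seed = 51))
  d <- k_diagnostics(co$matrix, K_range = 6, n_runs = 10,
                     downsample_sizes = c(50, 100), n_downsamples = 8,
                     seed = 51)
  sm <- d$summary
  v50 <- sm[sm$size == 50, ]; v100 <- sm[sm$size == 100, ]
  expect_lt(v100$silhouette_var, v50$silhouette_var)
})
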