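# Independent oracles, kept deliberately naive so they share no code path
# with the implementation they check.

# upper hypergeometric tail by direct enumeration over the support
fisher_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  m <- a + c          # feature carriers in the population
  k <- a + b          # cluster size (draws)
  ks <- max(a, max(0, k - (N - m))):min(k, m)
  sum(exp(lchoose(m, ks) + lchoose(N - m, k - ks) - lchoose(N, k)))
}

# BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Dice dissimilarity via explicit set operations on support indices
dice_oracle <- function(a, b) {
  A <- which(a == 1); B <- which(b == 1)
  if (length(A) + length(B) == 0) return(0)
  1 - 2 * length(intersect(A, B)) / (length(A) + length(B))
}

# exact BMF optimum by exhaustive search: enumerate every binary H; given H
# the optimal binary W decomposes row-wise over the 2^K membership patterns
bmf_bruteforce_residual <- function(X, K) {
  n <- nrow(X); f <- ncol(X)
  w_opts <- as.matrix(expand.grid(rep(list(0:1), K)))   # 2^K memberships
  h_all <- as.matrix(expand.grid(rep(list(0:1), K * f)))
  best <- Inf
  for (i in seq_len(nrow(h_all))) {
    H <- matrix(h_all[i, ], K, f)
    recon_opts <- (w_opts %*% H) >= 0.5                  # 2^K x f
    res <- 0
    for (r in seq_len(n)) {
      res <- res + min(rowSums(recon_opts != matrix(X[r, ], nrow(w_opts), f,
                                                    byrow = TRUE)))
    }
    if (res < best) best <- res
  }
  best
}

# empirical survival function (no censoring): S(t) = mean(times > t)
empirical_survival <- function(times, t) mean(times > t)

# tiny planted binary cohort used across tests
make_planted <- function(n_per, K, f_per, p_sig = 1, p_bg = 0, seed = 1) {
  set.seed(seed)
  truth <- rep(seq_len(K), each = n_per)
  nf <- K * f_per
  P <- matrix(p_bg, length(truth), nf)
  for (k in seq_len(K)) {
    P[truth == k, ((k - 1) * f_per + 1):(k * f_per)] <- p_sig
  }
  X <- matrix(rbinom(length(P), 1, P), length(truth), nf,
              dimnames = list(sprintf("P%02d", seq_along(truth)),
                              sprintf("F%02d", seq_len(nf))))
  list(X = X, truth = truth)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
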