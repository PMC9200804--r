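#' Control parameters for binary matrix factorization
#'
#' The factorization minimizes `||X - WH||_F^2` plus a binariness penalty
#' `lambda * (||W*W - W||^2 + ||H*H - H||^2)` by multiplicative updates,
#' with `lambda` increased on a schedule so the continuous factors are
#' pushed towards {0,1} as the fit stabilizes, then thresholded.
#'
#' @param K factorization rank (number of subtypes), >= 1.
#' @param max_iter maximum multiplicative-update iterations.
#' @param tol relative objective change declaring convergence (checked once
#'   the penalty has reached its cap).
#' @param lambda0 initial penalty weight.
#' @param lambda_step multiplier applied to lambda every `lambda_every`
#'   iterations.
#' @param lambda_every iterations per fixed-lambda phase.
#' @param lambda_max cap on lambda.
#' @param threshold binarization cutoff for the continuous factors, in (0,1).
#' @return a list of class `bmf_config`.
#' @export
bmf_config <- function(K, max_iter = 500L, tol = 1e-6, lambda0 = 0.1,
                       lambda_step = 10, lambda_every = 50L,
                       lambda_max = 1e4, threshold = 0.5) {
  stopifnot(K >= 1, max_iter >= 1, tol > 0, lambda0 > 0, lambda_step > 1,
            lambda_every >= 1, lambda_max >= lambda0,
            threshold > 0, threshold < 1)
  structure(list(K = as.integer(K), max_iter = as.integer(max_iter), tol = tol,
                 lambda0 = lambda0, lambda_step = lambda_step,
                 lambda_every = as.integer(lambda_every),
                 lambda_max = lambda_max, threshold = threshold),
            class = "bmf_config")
}

bmf_objective <- function(X, W, H, lambda) {
  R <- X - W %*% H
  sum(R * R) + lambda * (sum((W * W - W)^2) + sum((H * H - H)^2))
}

#' Fit a binary matrix factorization
#'
#' Approximates a binary patients x features matrix `X` by the product of a
#' binary membership matrix `W` (patients x K) and a binary signature matrix
#' `H` (K x features). Continuous non-negative factors are optimized by
#' multiplicative updates under an increasing binariness penalty (see
#' [bmf_config()]), then thresholded; the reconstruction is re-binarized as
#' `WH >= 0.5`, which for binary factors makes the residual an exact Hamming
#' count of mismatched cells.
#'
#' @param X an [alteration_matrix()] or a binary matrix.
#' @param K rank, or a full [bmf_config()] via `config`.
#' @param seed integer seed for the random uniform initialization.
#' @param config optional [bmf_config()]; overrides `K`.
#' @param objective_trace if `TRUE`, keep the per-iteration continuous
#'   objective and lambda values (used to audit monotonicity).
#' @return object of class `bmf_fit`: binary `W`, `H`; continuous `W_cont`,
#'   `H_cont`; integer `residual` (Hamming mismatches); `variance_explained`
#'   = 1 - residual/sum(X); `n_iter`; `converged`; `seed`; `config`; and
#'   `trace` (data.frame iter/lambda/objective) when requested.
#' @examples
#' X <- rbind(c(1,1,0,0), c(1,1,0,0), c(0,0,1,1))
#' fit <- bmf_fit(X, K = 2, seed = 1)
#' fit$residual  # 0: exact block factorization
#' @export
bmf_fit <- function(X, K = NULL, seed = 1L, config = NULL,
                    objective_trace = FALSE) {
  Xm <- if (inherits(X, "alteration_matrix")) X$values else as.matrix(X)
  if (!all(Xm %in% c(0, 1))) stop("X must be binary")
  storage.mode(Xm) <- "double"
  if (is.null(config)) {
    if (is.null(K)) stop("supply K or a bmf_config")
    config <- bmf_config(K)
  }
  K <- config$K
  n <- nrow(Xm); f <- ncol(Xm)
  if (K > min(n, f)) stop(sprintf("K = %d exceeds matrix dimensions %d x %d", K, n, f))
  if (all(Xm == 0)) stop("X is all-zero: factorization is degenerate")

  set.seed(seed)
  W <- matrix(stats::runif(n * K, 0.1, 0.9), n, K)
  H <- matrix(stats::runif(K * f, 0.1, 0.9), K, f)
  eps <- 1e-12

  obj_trace <- if (objective_trace) numeric(config$max_iter) else NULL
  lam_trace <- if (objective_trace) numeric(config$max_iter) else NULL
  prev_obj <- Inf
  prev_lambda <- -1
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    lambda <- min(config$lambda0 * config$lambda_step^((iter - 1L) %/% config$lambda_every),
                  config$lambda_max)
    # multiplicative updates for ||X-WH||^2 + lambda(||W^2-W||^2 + ||H^2-H||^2)
    W <- W * (Xm %*% t(H) + 3 * lambda * W^2) /
      pmax(W %*% tcrossprod(H) + 2 * lambda * W^3 + lambda * W, eps)
    H <- H * (crossprod(W, Xm) + 3 * lambda * H^2) /
      pmax(crossprod(W) %*% H + 2 * lambda * H^3 + lambda * H, eps)
    obj <- bmf_objective(Xm, W, H, lambda)
    if (objective_trace) { obj_trace[iter] <- obj; lam_trace[iter] <- lambda }
    # convergence is only declared once the penalty has stopped moving, so the
    # relative change is never measured across a lambda jump
    if (lambda >= config$lambda_max && lambda == prev_lambda && is.finite(prev_obj)) {
      rel <- abs(prev_obj - obj) / max(prev_obj, eps)
      if (rel < config$tol) { converged <- TRUE; break }
    }
    prev_obj <- obj
    prev_lambda <- lambda
  }

  Wb <- matrix(as.integer(W >= config$threshold), n, K)
  Hb <- matrix(as.integer(H >= config$threshold), K, f)
  recon <- (Wb %*% Hb) >= 0.5
  residual <- sum(recon != (Xm == 1))
  out <- structure(
    list(W = Wb, H = Hb, W_cont = W, H_cont = H,
         residual = as.integer(residual),
         variance_explained = 1 - residual / sum(Xm),
         n_iter = iter, converged = converged, seed = seed, config = config),
    class = "bmf_fit"
  )
  if (objective_trace) {
    out$trace <- data.frame(iter = seq_len(iter),
                            lambda = lam_trace[seq_len(iter)],
                            objective = obj_trace[seq_len(iter)])
  }
  if (inherits(X, "alteration_matrix")) {
    rownames(out$W) <- rownames(out$W_cont) <- X$patient_ids
    colnames(out$H) <- colnames(out$H_cont) <- X$feature_ids
  }
  out
}

#' @export
print.bmf_fit <- function(x, ...) {
  cat(sprintf("bmf_fit: K = %d, residual = %d, variance explained = %.3f\n",
              x$config$K, x$residual, x$variance_explained))
  cat(sprintf("  %d iterations (%s), seed %d\n", x$n_iter,
              if (x$converged) "converged" else "max_iter reached", x$seed))
  invisible(x)
}

#' Cluster labels from BMF factors
#'
#' Each patient is assigned the cluster with the maximal continuous
#' (pre-threshold) loading; ties break to the lowest cluster index. Patients
#' whose continuous loading row is entirely zero are assigned to the
#' signature row of `H` nearest to their raw profile in Hamming distance and
#' flagged in the `fallback` attribute.
#'
#' @param fit a [bmf_fit()] object, or a matrix of loadings.
#' @param X raw binary profiles, required only for the all-zero fallback
#'   when `fit` is a bare matrix (otherwise unused).
#' @return integer labels in 1..K (named by patient when available), with
#'   attribute `fallback` listing patients assigned by Hamming distance.
#' @export
assign_from_factors <- function(fit, X = NULL) {
  if (inherits(fit, "bmf_fit")) {
    W <- fit$W_cont; H <- fit$H
  } else {
    W <- as.matrix(fit); H <- NULL
  }
  labels <- integer(nrow(W))
  fallback <- integer(0)
  zero_rows <- rowSums(W) == 0
  if (any(!zero_rows)) {
    labels[!zero_rows] <- max.col(W[!zero_rows, , drop = FALSE], ties.method = "first")
  }
  if (any(zero_rows)) {
    if (is.null(H)) {
      if (is.null(X)) stop("all-zero loading rows need H (via a bmf_fit) or X")
      stop("cannot resolve all-zero loading rows without factor signatures")
    }
    Xm <- if (inherits(X, "alteration_matrix")) X$values else X
    for (i in which(zero_rows)) {
      prof <- if (!is.null(Xm)) Xm[i, ] else rep(0, ncol(H))
      d <- colSums(abs(t(H) - prof))
      labels[i] <- which.min(d)  # which.min takes the lowest index on ties
    }
    fallback <- which(zero_rows)
  }
  if (!is.null(rownames(W))) names(labels) <- rownames(W)
  attr(labels, "fallback") <- fallback
  labels
}

#' Export BMF factor matrices as annotated TSV
#'
#' Writes `W` (patients x K) and `H` (K x features) with `#`-prefixed
#' metadata lines recording the seed, K and residual.
#'
#' @param fit a [bmf_fit()].
#' @param w_path,h_path output paths.
#' @return invisibly, the two paths.
#' @export
write_bmf_factors <- function(fit, w_path, h_path) {
  stopifnot(inherits(fit, "bmf_fit"))
  hdr <- sprintf("# seed=%d K=%d residual=%d", fit$seed, fit$config$K, fit$residual)
  for (part in list(list(m = fit$W, p = w_path), list(m = t(fit$H), p = h_path))) {
    con <- file(part$p, "w")
    writeLines(hdr, con)
    utils::write.table(part$m, con, sep = "\t", quote = FALSE,
                       col.names = NA)
    close(con)
  }
  invisible(c(w_path, h_path))
}
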