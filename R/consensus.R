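#' Dice dissimilarity between binary profiles
#'
#' `1 - 2|a AND b| / (|a| + |b|)`, the dissimilarity the silhouette
#' diagnostics use on raw alteration profiles. Defined as 0 when both
#' vectors are all-zero (two all-negative patients are not evidence of
#' difference).
#'
#' @param a,b binary vectors of equal length.
#' @return value in [0, 1].
#' @export
dice_dissimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) stop("vectors must be binary")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(0)
  1 - 2 * sum(a & b) / (sa + sb)
}

#' Pairwise Dice dissimilarity matrix
#'
#' @param X an [alteration_matrix()] or binary matrix (patients as rows).
#' @return symmetric n x n matrix of Dice dissimilarities, zero diagonal.
#' @export
dice_dist <- function(X) {
  Xm <- if (inherits(X, "alteration_matrix")) X$values else as.matrix(X)
  storage.mode(Xm) <- "double"
  inter <- tcrossprod(Xm)
  sizes <- rowSums(Xm)
  denom <- outer(sizes, sizes, "+")
  D <- 1 - 2 * inter / denom
  D[denom == 0] <- 0          # both profiles all-zero
  diag(D) <- 0
  dimnames(D) <- list(rownames(Xm), rownames(Xm))
  D
}

#' Consensus matrix over repeated BMF restarts
#'
#' Runs [bmf_fit()] `n_runs` times from independent seeded random
#' initializations, labels patients with [assign_from_factors()], and
#' records for every patient pair the fraction of runs in which they landed
#' in the same cluster. The best-residual run is kept for the K-L and
#' residual diagnostics.
#'
#' @param X an [alteration_matrix()] or binary matrix.
#' @param K rank passed to [bmf_config()] (or supply `config`).
#' @param n_runs number of restarts, >= 2.
#' @param seed master seed; per-run seeds are drawn from it.
#' @param config optional [bmf_config()].
#' @return object of class `consensus_result`: `consensus` (n x n, symmetric,
#'   unit diagonal), `labels_runs` (n x n_runs matrix), `best_fit`
#'   ([bmf_fit()] with the lowest residual), `K`, `n_runs`, `seed`.
#' @export
build_consensus <- function(X, K = NULL, n_runs = 100L, seed = 1L, config = NULL) {
  if (n_runs < 2L) stop("consensus over a single run is undefined; n_runs >= 2")
  Xm <- if (inherits(X, "alteration_matrix")) X$values else as.matrix(X)
  n <- nrow(Xm)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  co <- matrix(0, n, n)
  labels_runs <- matrix(NA_integer_, n, n_runs)
  best_fit <- NULL
  for (r in seq_len(n_runs)) {
    fit <- bmf_fit(X, K = K, seed = run_seeds[r], config = config)
    lab <- assign_from_factors(fit)
    labels_runs[, r] <- lab
    co <- co + outer(lab, lab, "==")
    if (is.null(best_fit) || fit$residual < best_fit$residual) best_fit <- fit
  }
  consensus <- co / n_runs
  dimnames(consensus) <- list(rownames(Xm), rownames(Xm))
  structure(list(consensus = consensus, labels_runs = labels_runs,
                 best_fit = best_fit, K = best_fit$config$K,
                 n_runs = as.integer(n_runs), seed = seed),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d patients, K = %d, %d runs\n",
              nrow(x$consensus), x$K, x$n_runs))
  cat(sprintf("  best run residual = %d (variance explained %.3f)\n",
              x$best_fit$residual, x$best_fit$variance_explained))
  invisible(x)
}

#' Cut a consensus matrix into K clusters
#'
#' Hierarchical clustering of the consensus-matrix rows with Euclidean
#' distance and Ward linkage, cut at K. Cluster ids are canonicalized to
#' 1..K by decreasing cluster size (ties keep the lower original id), so
#' labels are stable across runs and reports.
#'
#' @param consensus a `consensus_result` or a square co-clustering matrix.
#' @param K number of clusters, 1 <= K <= n.
#' @return integer labels in 1..K, named by patient when available.
#' @export
cut_consensus <- function(consensus, K) {
  C <- if (inherits(consensus, "consensus_result")) consensus$consensus else as.matrix(consensus)
  n <- nrow(C)
  if (K > n) stop("K cannot exceed the number of patients")
  if (K == 1L) {
    lab <- rep(1L, n)
    names(lab) <- rownames(C)
    return(lab)
  }
  hc <- stats::hclust(stats::dist(C, method = "euclidean"), method = "ward.D2")
  raw <- stats::cutree(hc, k = K)
  relabel_by_size(raw)
}

relabel_by_size <- function(raw) {
  sizes <- tabulate(raw)
  ord <- order(-sizes, seq_along(sizes))
  map <- integer(length(sizes)); map[ord] <- seq_along(sizes)
  out <- map[raw]
  names(out) <- names(raw)
  out
}

#' Generalized Kullback-Leibler divergence of a factorization fit
#'
#' `D(X || WH) = sum( x log(x/y) - x + y )` over cells, with `0 log 0 := 0`
#' and the reconstruction clamped at 1e-12. Computed on the continuous
#' (pre-threshold) reconstruction, where it is finite and informative; a
#' binarized reconstruction would put zero mass on observed cells.
#'
#' @param X binary matrix.
#' @param fit a [bmf_fit()].
#' @return non-negative scalar.
#' @export
kl_divergence <- function(X, fit) {
  Xm <- if (inherits(X, "alteration_matrix")) X$values else as.matrix(X)
  Y <- pmax(fit$W_cont %*% fit$H_cont, 1e-12)
  xlogx <- ifelse(Xm > 0, Xm * log(Xm / Y), 0)
  sum(xlogx - Xm + Y)
}

#' K-selection diagnostics over a range of ranks
#'
#' For each K (and, optionally, each random downsample of the cohort) this
#' builds a consensus over BMF restarts, cuts it, and records: the mean
#' silhouette width of the cut computed on Dice dissimilarities of the raw
#' binary profiles, and the residual, variance explained and generalized
#' K-L divergence of the best-residual run. Downsampling (sampling patients
#' without replacement) probes how stable the diagnostics are at reduced
#' cohort size.
#'
#' @param X an [alteration_matrix()] or binary matrix.
#' @param K_range candidate ranks (default 2:10).
#' @param n_runs consensus restarts per fit (default 20 here; raise for
#'   final analyses).
#' @param downsample_sizes patient counts to subsample to; `NULL` means the
#'   full cohort only. Each size must exceed `max(K_range)`.
#' @param n_downsamples replicates per size (ignored for the full cohort,
#'   which is deterministic given the seed).
#' @param seed master seed.
#' @return object of class `k_diagnostics`: `table` (one row per K x size x
#'   replicate) and `summary` (mean and variance per K x size).
#' @export
k_diagnostics <- function(X, K_range = 2:10, n_runs = 20L,
                          downsample_sizes = NULL, n_downsamples = 5L,
                          seed = 1L) {
  Xm <- if (inherits(X, "alteration_matrix")) X$values else as.matrix(X)
  n <- nrow(Xm)
  if (length(K_range) < 1L) stop("K_range must be non-empty")
  sizes <- downsample_sizes
  if (!is.null(sizes) && any(sizes < max(K_range) + 1L)) {
    stop("every downsample size must be at least max(K_range) + 1")
  }
  if (!is.null(sizes) && any(sizes > n)) stop("downsample size exceeds cohort")
  plan <- rbind(
    data.frame(size = n, rep = 1L),
    if (!is.null(sizes)) expand.grid(size = sizes, rep = seq_len(n_downsamples))
  )
  set.seed(seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 nrow(plan) * length(K_range)),
                      nrow(plan), length(K_range))
  rows <- vector("list", nrow(plan) * length(K_range))
  ri <- 0L
  for (p in seq_len(nrow(plan))) {
    sz <- plan$size[p]
    idx <- if (sz == n) seq_len(n) else {
      set.seed(sub_seeds[p, 1L] %% 2147483646L + 1L)
      sample.int(n, sz)
    }
    Xs <- Xm[idx, , drop = FALSE]
    keep <- colSums(Xs) > 0L          # drop features absent from the subsample
    Xs <- Xs[, keep, drop = FALSE]
    D <- dice_dist(Xs)
    for (ki in seq_along(K_range)) {
      K <- K_range[ki]
      cons <- build_consensus(Xs, K = K, n_runs = n_runs, seed = sub_seeds[p, ki])
      lab <- cut_consensus(cons, K)
      sil <- mean(cluster::silhouette(lab, dmatrix = D)[, "sil_width"])
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        K = K, size = sz, rep = plan$rep[p],
        silhouette = sil,
        residual = cons$best_fit$residual,
        variance_explained = cons$best_fit$variance_explained,
        kl = kl_divergence(Xs, cons$best_fit)
      )
    }
  }
  tab <- do.call(rbind, rows)
  agg_mean <- stats::aggregate(tab[c("silhouette", "residual",
                                     "variance_explained", "kl")],
                               by = tab[c("K", "size")], FUN = mean)
  agg_var <- stats::aggregate(tab[c("silhouette", "residual",
                                    "variance_explained", "kl")],
                              by = tab[c("K", "size")], FUN = stats::var)
  names(agg_var)[-(1:2)] <- paste0(names(agg_var)[-(1:2)], "_var")
  summary <- merge(agg_mean, agg_var, by = c("K", "size"))
  summary <- summary[order(summary$size, summary$K), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(table = tab, summary = summary, K_range = K_range,
                 full_size = n, seed = seed),
            class = "k_diagnostics")
}

#' @export
print.k_diagnostics <- function(x, ...) {
  cat("k_diagnostics over K =", paste(range(x$K_range), collapse = ".."), "\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Choose the number of clusters from diagnostics
#'
#' Default rule: restrict to K whose mean silhouette (full-cohort) is at
#' least 90% of the maximum over the range, then pick the K with the largest
#' decrease in mean K-L divergence relative to K - 1. The silhouette screen
#' does the structural work -- over-split solutions fit ever better by K-L
#' but lose silhouette -- while the K-L drop locates where added components
#' stop explaining real signal. The full diagnostic table is returned so the
#' rule can be overridden by inspection.
#'
#' @param diagnostics a [k_diagnostics()] result.
#' @param sil_frac silhouette screen as a fraction of the maximum (0.9).
#' @return list with `K` (the selection), `rationale` (per-K table of mean
#'   K-L, K-L drop, silhouette, candidate flag).
#' @export
select_k <- function(diagnostics, sil_frac = 0.9) {
  stopifnot(inherits(diagnostics, "k_diagnostics"))
  s <- diagnostics$summary
  s <- s[s$size == diagnostics$full_size, , drop = FALSE]
  s <- s[order(s$K), , drop = FALSE]
  if (nrow(s) == 1L) {
    return(list(K = s$K, rationale = data.frame(
      K = s$K, kl = s$kl, kl_drop = NA_real_, silhouette = s$silhouette,
      candidate = TRUE)))
  }
  drop <- c(NA_real_, -diff(s$kl))
  cand <- s$silhouette >= sil_frac * max(s$silhouette)
  rationale <- data.frame(K = s$K, kl = s$kl, kl_drop = drop,
                          silhouette = s$silhouette, candidate = cand)
  usable <- which(cand & !is.na(drop))
  K_sel <- if (length(usable)) {
    s$K[usable[which.max(drop[usable])]]
  } else {
    s$K[which.max(s$silhouette)]   # degenerate: no candidate has a predecessor
  }
  list(K = K_sel, rationale = rationale)
}

#' Consensus BMF subtyping
#'
#' The package's main fitting function: repeated seeded binary matrix
#' factorizations of the patient x alteration matrix are aggregated into a
#' consensus co-clustering matrix, which is cut by Ward hierarchical
#' clustering (Euclidean distance) into K subtypes. Cluster ids are
#' canonicalized by decreasing size.
#'
#' @param X an [alteration_matrix()] (or binary matrix, patients as rows).
#' @param K number of subtypes; choose with [k_diagnostics()] + [select_k()].
#' @param n_runs consensus restarts (default 100).
#' @param seed master seed controlling all restarts.
#' @param config optional [bmf_config()] overriding the BMF controls.
#' @return object of class `bmf_subtype`: `labels` (named integer vector,
#'   1..K), `consensus` (the [build_consensus()] result), `K`, `n_runs`,
#'   `seed`, `cluster_sizes`, and `X` (the input matrix, for summaries).
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rbinom(60, 1, 0.8), 10), matrix(rbinom(60, 1, 0.1), 10))
#' rownames(X) <- paste0("P", 1:20); colnames(X) <- paste0("F", 1:6)
#' fit <- bmf_subtype(X, K = 2, n_runs = 10, seed = 1)
#' table(fit$labels)
#' @export
bmf_subtype <- function(X, K, n_runs = 100L, seed = 1L, config = NULL) {
  cons <- build_consensus(X, K = K, n_runs = n_runs, seed = seed, config = config)
  labels <- cut_consensus(cons, K)
  structure(list(labels = labels, consensus = cons, K = as.integer(K),
                 n_runs = as.integer(n_runs), seed = seed,
                 cluster_sizes = as.integer(table(labels)), X = X),
            class = "bmf_subtype")
}

#' @export
print.bmf_subtype <- function(x, ...) {
  cat(sprintf("bmf_subtype: %d patients in %d consensus clusters (%d runs, seed %d)\n",
              length(x$labels), x$K, x$n_runs, x$seed))
  cat("  cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.bmf_subtype <- function(object, q_threshold = 0.1, ...) {
  enr <- enrich_clusters(object$X, object$labels)
  top <- lapply(split(enr, enr$cluster), function(d) {
    d <- d[d$enriched, , drop = FALSE]
    utils::head(d$feature, 5L)
  })
  out <- list(K = object$K, cluster_sizes = object$cluster_sizes,
              top_enriched = top, enrichment = enr)
  class(out) <- "summary.bmf_subtype"
  out
}

#' @export
print.summary.bmf_subtype <- function(x, ...) {
  cat(sprintf("Consensus BMF subtyping, K = %d\n", x$K))
  for (k in seq_len(x$K)) {
    feats <- x$top_enriched[[as.character(k)]]
    cat(sprintf("  cluster %d (n = %d): %s\n", k, x$cluster_sizes[k],
                if (length(feats)) paste(feats, collapse = ", ") else "<none enriched>"))
  }
  invisible(x)
}

#' @export
plot.bmf_subtype <- function(x, ...) {
  ord <- order(x$labels)
  C <- x$consensus$consensus[ord, ord]
  graphics::image(seq_len(nrow(C)), seq_len(ncol(C)), C,
                  col = grDevices::grey.colors(64, start = 1, end = 0),
                  xlab = "patients (ordered by cluster)", ylab = "",
                  main = sprintf("Consensus matrix, K = %d", x$K), ...)
  invisible(x)
}
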