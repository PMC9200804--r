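#' One-sided (greater) Fisher exact p-value for a 2x2 table
#'
#' Upper hypergeometric tail `P(A >= a)` for the table
#' (a: in-cluster with feature, b: in-cluster without, c: out-of-cluster
#' with, d: out-of-cluster without): population `a+b+c+d`, successes `a+c`,
#' draws `a+b`. Tests positive association of the feature with the cluster.
#'
#' @param a,b,c,d non-negative integer counts; total >= 1.
#' @return p-value in (0, 1].
#' @export
fisher_one_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) < 1) stop("table total must be >= 1")
  # P(X >= a), X ~ Hypergeom(m = a + c, n = b + d, k = a + b)
  stats::phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i}( p_(j) * m / j )` capped at
#' 1, returned in the input order. Applied once per family; re-application
#' to its own output is not part of the contract.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return q-values of the same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Per-cluster feature enrichment by one-sided Fisher tests
#'
#' For every (cluster, feature) pair, tests whether the feature is
#' positively associated with the cluster (one-sided, "greater") and adjusts
#' p-values by Benjamini-Hochberg within each cluster (the family is the
#' features of one cluster; set `family = "global"` to adjust across all
#' pairs instead). Rows are ranked within cluster by ascending q then p.
#' A feature is called enriched when `q < q_threshold`.
#'
#' Odds ratios are the cross-product `(a d)/(b c)` with a Haldane-Anscombe
#' 0.5 correction to every cell when any cell is zero; the correction is
#' display-only and never touches the exact p-values.
#'
#' @param X an [alteration_matrix()] or binary matrix.
#' @param labels integer/factor cluster labels covering all patients.
#' @param q_threshold enrichment call threshold on the adjusted p (0.1).
#' @param family `"cluster"` (default) or `"global"` BH family.
#' @return data.frame of class `enrichment_table` with columns: cluster,
#'   feature, a, b, c, d, odds_ratio, p, q, enriched.
#' @export
enrich_clusters <- function(X, labels, q_threshold = 0.1,
                            family = c("cluster", "global")) {
  family <- match.arg(family)
  Xm <- if (inherits(X, "alteration_matrix")) X$values else as.matrix(X)
  if (length(labels) != nrow(Xm)) stop("labels must cover all patients")
  labs <- as.integer(factor(labels))
  clusters <- sort(unique(labs))
  n <- nrow(Xm)
  prev <- colSums(Xm)
  rows <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    k <- clusters[ci]
    in_k <- labs == k
    nk <- sum(in_k)
    a <- colSums(Xm[in_k, , drop = FALSE])
    b <- nk - a
    c_ <- prev - a
    d <- (n - nk) - c_
    if (nk < 2L) {
      warning(sprintf("cluster %d has fewer than 2 patients; p set to 1", k))
      p <- rep(1, ncol(Xm))
    } else {
      p <- stats::phyper(a - 1, m = a + c_, n = b + d, k = nk,
                         lower.tail = FALSE)
    }
    aa <- a; bb <- b; cc <- c_; dd <- d
    zero <- aa == 0 | bb == 0 | cc == 0 | dd == 0
    aa[zero] <- aa[zero] + 0.5; bb[zero] <- bb[zero] + 0.5
    cc[zero] <- cc[zero] + 0.5; dd[zero] <- dd[zero] + 0.5
    rows[[ci]] <- data.frame(
      cluster = k, feature = colnames(Xm), a = a, b = b, c = c_, d = d,
      odds_ratio = (aa * dd) / (bb * cc), p = p,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  tab <- do.call(rbind, rows)
  if (family == "cluster") {
    tab$q <- stats::ave(tab$p, tab$cluster, FUN = bh_adjust)
  } else {
    tab$q <- bh_adjust(tab$p)
  }
  tab$enriched <- tab$q < q_threshold
  tab <- tab[order(tab$cluster, tab$q, tab$p), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' Write an enrichment table as ranked TSV
#'
#' @param tab an [enrich_clusters()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
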