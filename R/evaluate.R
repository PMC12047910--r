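#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement under the permutation model, computed
#' from the contingency table:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}
#'                  {\tfrac12[\sum_i\binom{a_i}{2} +
#'                   \sum_j\binom{b_j}{2}] - E},\quad
#'   E = \frac{\sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}}{\binom{n}{2}}.}
#' Returns 1 for identical partitions and 0 in expectation under
#' independent labelings; by convention 1 when both margins are
#' degenerate (denominator zero).
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 elements")
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(as.numeric(tab)))
  sum_a <- sum(ch2(as.numeric(rowSums(tab))))
  sum_b <- sum(ch2(as.numeric(colSums(tab))))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Absolute error in the estimated number of clusters
#' @param K_hat,K_true positive integers.
#' @return `abs(K_hat - K_true)`.
#' @export
k_error <- function(K_hat, K_true) {
  stopifnot(K_hat >= 1, K_true >= 1)
  abs(K_hat - K_true)
}

#' One-vs-rest Wilcoxon marker-gene ranking
#'
#' For every cluster and gene, a two-sided Wilcoxon rank-sum test of
#' the cluster's rows against all other rows, with
#' Benjamini-Hochberg adjustment across genes within each cluster.
#' The log fold-change column is the difference of group means on the
#' provided (assumed log) scale. Within each cluster, genes are
#' ranked by ascending adjusted p-value, then descending absolute
#' fold-change, then gene order (so ranks are always `1..p` without
#' ties). Constant genes get p = 1 by convention, with a warning.
#'
#' @param expr an [expression_matrix()] (log-scale values).
#' @param labels cluster labels, one per row; every cluster needs at
#'   least 2 members.
#' @return a `data.frame` with columns cluster, gene_id, statistic
#'   (rank-sum W), lfc, p_value, p_adjusted, rank.
#' @export
rank_markers <- function(expr, labels) {
  X <- unclass_expr(expression_matrix(unclass_expr(expr)))
  if (length(labels) != nrow(X))
    stop("labels length must match the number of rows")
  cl <- sort(unique(labels))
  if (any(table(labels) < 2)) stop("every cluster needs at least 2 members")
  p <- ncol(X)
  n_const <- 0L
  out <- lapply(cl, function(k) {
    ink <- labels == k
    stat <- numeric(p); pv <- numeric(p); lfc <- numeric(p)
    for (g in seq_len(p)) {
      xg <- X[ink, g]; yg <- X[!ink, g]
      lfc[g] <- mean(xg) - mean(yg)
      if (max(X[, g]) == min(X[, g])) {
        n_const <<- n_const + 1L
        stat[g] <- NA_real_; pv[g] <- 1
      } else {
        wt <- suppressWarnings(stats::wilcox.test(xg, yg))
        stat[g] <- unname(wt$statistic)
        pv[g] <- wt$p.value
      }
    }
    padj <- stats::p.adjust(pv, method = "BH")
    ord <- order(padj, -abs(lfc), seq_len(p))
    rank <- integer(p); rank[ord] <- seq_len(p)
    data.frame(cluster = k, gene_id = colnames(X), statistic = stat,
               lfc = lfc, p_value = pv, p_adjusted = padj, rank = rank)
  })
  if (n_const > 0)
    warning(n_const, " constant gene test(s) set to p = 1")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Top marker genes per cluster
#' @param markers output of [rank_markers()].
#' @param n number of genes per cluster.
#' @return subset of `markers` with rank <= n, ordered by cluster then rank.
#' @export
top_markers <- function(markers, n = 10) {
  res <- markers[markers$rank <= n, ]
  res[order(res$cluster, res$rank), ]
}
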