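#' Build a k-nearest-neighbor spatial graph over spot coordinates
#'
#' Each spot's neighborhood is its `k` nearest spots by Euclidean
#' distance (self excluded; distance ties broken toward the lower row
#' index), then the graph is union-symmetrized so that
#' `i %in% nbrs[[j]]` iff `j %in% nbrs[[i]]`. The default `k = 5`
#' follows standard practice for spot-level spatial graphs.
#'
#' @param coords n x 2 numeric matrix of spot coordinates.
#' @param k number of nearest neighbors (default 5); must be `< n`.
#' @return a `spatial_graph` list: `neighbors` (list of sorted integer
#'   vectors), `k`, `symmetric = TRUE`, `n`.
#' @export
build_knn_graph <- function(coords, k = 5) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of spots")
  if (k < 1) stop("k must be positive")
  nbrs <- vector("list", n)
  # blockwise distance computation to keep memory at O(block * n)
  block <- max(1L, min(n, as.integer(2e7 / n)))
  cn2 <- rowSums(coords^2)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(cn2[idx], cn2, "+") - 2 * coords[idx, , drop = FALSE] %*% t(coords)
    for (j in seq_along(idx)) {
      i <- idx[j]
      di <- d2[j, ]
      di[i] <- Inf
      ord <- order(di, seq_len(n))  # ties toward lower row index
      nbrs[[i]] <- ord[seq_len(k)]
    }
  }
  # union-symmetrization
  from <- rep(seq_len(n), each = k)
  to <- unlist(nbrs)
  adj <- unique(data.frame(a = pmin(from, to), b = pmax(from, to)))
  sym <- vector("list", n)
  for (i in seq_len(n)) sym[[i]] <- integer(0)
  split_a <- split(adj$b, adj$a)
  split_b <- split(adj$a, adj$b)
  for (nm in names(split_a)) sym[[as.integer(nm)]] <-
    c(sym[[as.integer(nm)]], split_a[[nm]])
  for (nm in names(split_b)) sym[[as.integer(nm)]] <-
    c(sym[[as.integer(nm)]], split_b[[nm]])
  sym <- lapply(sym, function(v) sort(unique(v)))
  structure(list(neighbors = sym, k = k, symmetric = TRUE, n = n),
            class = "spatial_graph")
}

#' Count neighbors disagreeing with a candidate label
#'
#' The Potts conditional score for assigning class `k` to spot `i`
#' uses the unhalved disagreement count `#{j in N_i : z_j != k}`: the
#' 1/2 in the joint Potts density cancels because a symmetric graph
#' counts each pair twice.
#'
#' @param labels integer label vector.
#' @param graph a `spatial_graph`.
#' @param i spot index.
#' @param k candidate class.
#' @return integer disagreement count.
#' @export
potts_neighbor_disagreement <- function(labels, graph, i, k) {
  nb <- graph$neighbors[[i]]
  sum(labels[nb] != k)
}

graph_csr <- function(graph) {
  list(idx = as.integer(unlist(graph$neighbors) - 1L),
       ptr = as.integer(c(0L, cumsum(lengths(graph$neighbors)))))
}

# k-means++ seeding followed by stats::kmeans; best of `restarts` by
# within-cluster sum of squares. Shared initialization for all beta
# values so the line search is paired.
kmeanspp_labels <- function(V, K, restarts = 10) {
  n <- nrow(V)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- matrix(0, K, ncol(V))
    centers[1, ] <- V[sample.int(n, 1), ]
    d2 <- rowSums((V - matrix(centers[1, ], n, ncol(V), byrow = TRUE))^2)
    if (K > 1) for (k in 2:K) {
      pr <- d2 / sum(d2)
      centers[k, ] <- V[sample.int(n, 1, prob = pr), ]
      d2 <- pmin(d2, rowSums((V - matrix(centers[k, ], n, ncol(V),
                                         byrow = TRUE))^2))
    }
    km <- suppressWarnings(stats::kmeans(V, centers = centers,
                                         iter.max = 50))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best$cluster
}

#' Spatial Gaussian mixture clustering with a Potts label prior
#'
#' Clusters the rows of `V` (spot factors) with the model
#' \deqn{v_i \mid z_i = k \sim N(\mu_k, \Sigma_k),\qquad
#'   f(z) \propto \exp\{-\tfrac12 \sum_i \sum_{i' \in N_i}
#'   \beta (1 - I\{z_i = z_{i'}\})\},}
#' fitted by ICM-EM: iterated-conditional-modes label updates
#' alternating with moment M-steps. The smoothing parameter
#' \eqn{\beta} is chosen from `beta_grid` by maximizing the
#' conditional pseudo-likelihood (all \eqn{\beta} values start from
#' one shared k-means++ initialization, so the line search is paired).
#' \eqn{\beta = 0} reduces to a hard-EM Gaussian mixture without
#' spatial smoothing.
#'
#' @param V n x q numeric matrix of target factors.
#' @param graph a `spatial_graph` from [build_knn_graph()].
#' @param K number of clusters.
#' @param beta_grid candidate smoothing values in `[0, 1]` (default
#'   `seq(0, 1, by = 0.1)`).
#' @param max_iter maximum ICM-EM iterations per beta (default 50).
#' @param seed integer seed for the k-means++ initialization.
#' @param init_labels optional integer vector overriding the k-means++
#'   initialization (used for paired comparisons).
#' @param n_restarts number of independent initializations; the
#'   restart (and beta) with the best pseudo-likelihood wins. Default 1
#'   (a single shared initialization, so beta comparisons are paired);
#'   the pipeline uses 3 to damp local-optimum variance.
#' @return an `spgmm_fit` list: `labels`, `K`, `beta`, `means`, `covs`,
#'   `responsibilities`, `pseudo_loglik`, `joint_trace`, `beta_table`
#'   (pseudo-likelihood per candidate beta), `n_iter`, `converged`.
#' @export
fit_spgmm <- function(V, graph, K, beta_grid = seq(0, 1, by = 0.1),
                      max_iter = 50, seed = 1L, init_labels = NULL,
                      n_restarts = 1L) {
  V <- as.matrix(V)
  stopifnot(inherits(graph, "spatial_graph"), nrow(V) == graph$n)
  if (K < 1) stop("K must be at least 1")
  if (any(beta_grid < 0 | beta_grid > 1))
    stop("beta_grid values must lie in [0, 1]")
  if (length(beta_grid) == 0) stop("beta_grid must be non-empty")
  if (is.null(init_labels)) {
    inits <- lapply(seq_len(n_restarts), function(r) {
      set.seed(seed + 7919L * (r - 1L))
      if (K == 1) rep(1L, nrow(V)) else kmeanspp_labels(V, K)
    })
  } else {
    stopifnot(length(init_labels) == nrow(V))
    inits <- list(as.integer(init_labels))
  }
  csr <- graph_csr(graph)
  fits <- list(); betas <- numeric(0)
  for (init in inits) {
    fits <- c(fits, lapply(beta_grid, function(beta)
      icm_em_cpp(V, csr$idx, csr$ptr, K, beta, init,
                 max_iter, 10L, 1e-6, 1e-8)))
    betas <- c(betas, beta_grid)
  }
  pll <- vapply(fits, function(f) f$pseudo_loglik, numeric(1))
  best <- which.max(pll)
  f <- fits[[best]]
  init_labels <- inits[[ceiling(best / length(beta_grid))]]
  if (f$n_ridge > 0)
    warning("covariance ridge applied ", f$n_ridge, " time(s)")
  if (f$n_reseed > 0)
    warning("empty component re-seeded ", f$n_reseed, " time(s)")
  pll_by_beta <- vapply(beta_grid, function(b) max(pll[betas == b]),
                        numeric(1))
  structure(list(labels = as.integer(f$labels), K = K,
                 beta = betas[best], means = f$means, covs = f$covs,
                 responsibilities = f$responsibilities,
                 pseudo_loglik = f$pseudo_loglik,
                 joint_trace = as.numeric(f$joint_trace),
                 beta_table = data.frame(beta = beta_grid,
                                         pseudo_loglik = pll_by_beta),
                 n_iter = f$n_iter, converged = f$converged,
                 init_labels = as.integer(init_labels)),
            class = "spgmm_fit")
}

#' Select the number of clusters by a BIC-type criterion
#'
#' Fits [fit_spgmm()] for each `K` in `K_range` and scores
#' \eqn{-2 \cdot \mathrm{pseudoLL}(K) + \log(n_0) d_K} with
#' \eqn{d_K = Kq + Kq(q+1)/2} free parameters (means plus
#' covariances); returns the minimizer, breaking ties toward the
#' smaller `K`. A custom `criterion` function `(pseudo_loglik, K, n,
#' q) -> numeric` can be supplied.
#'
#' @inheritParams fit_spgmm
#' @param K_range integer vector of candidate cluster counts.
#' @param criterion optional replacement criterion function.
#' @return list with `K_hat`, `criterion_table` (K, criterion,
#'   pseudo_loglik, beta), and `fit` (the selected `spgmm_fit`).
#' @export
select_K <- function(V, graph, K_range = 2:8,
                     beta_grid = seq(0, 1, by = 0.1), max_iter = 50,
                     seed = 1L, criterion = NULL, n_restarts = 1L) {
  if (length(K_range) == 0 || min(K_range) < 1)
    stop("K_range must be non-empty with minimum at least 1")
  V <- as.matrix(V)
  q <- ncol(V); n <- nrow(V)
  if (is.null(criterion))
    criterion <- function(pll, K, n, q)
      -2 * pll + log(n) * (K * q + K * q * (q + 1) / 2)
  K_range <- sort(unique(as.integer(K_range)))
  rows <- list(); fits <- list()
  for (K in K_range) {
    f <- tryCatch(fit_spgmm(V, graph, K, beta_grid, max_iter, seed,
                            n_restarts = n_restarts),
                  error = function(e) {
                    warning("K = ", K, " failed: ", conditionMessage(e))
                    NULL
                  })
    if (is.null(f)) next
    rows[[as.character(K)]] <- data.frame(
      K = K, criterion = criterion(f$pseudo_loglik, K, n, q),
      pseudo_loglik = f$pseudo_loglik, beta = f$beta)
    fits[[as.character(K)]] <- f
  }
  if (length(rows) == 0) stop("all candidate K failed")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  K_hat <- tab$K[which.min(tab$criterion)]  # ties -> smaller K (sorted)
  list(K_hat = K_hat, criterion_table = tab,
       fit = fits[[as.character(K_hat)]])
}

#' @export
print.spgmm_fit <- function(x, ...) {
  cat("spgmm_fit: n0 =", length(x$labels), "spots, K =", x$K,
      ", beta =", x$beta, ", pseudo log-lik =",
      format(x$pseudo_loglik, digits = 6), "\n")
  invisible(x)
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("spatial_graph:", x$n, "spots, k =", x$k, "(symmetrized),",
      sum(lengths(x$neighbors)) / 2, "edges\n")
  invisible(x)
}
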