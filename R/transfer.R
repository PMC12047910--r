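#' Adaptive transfer of a source-learned loading to a target dataset
#'
#' Minimizes the biconvex objective
#' \deqn{\sum_{i=1}^{n_0} \|x_{tgt,i} - W v_i\|_2^2 +
#'       \lambda \|W - \hat W_0\|_F^2}
#' by alternating exact least squares, starting from \eqn{W = \hat W_0}:
#' the V-step solves \eqn{V = X W (W^T W)^{-1}} and the W-step
#' \eqn{W = (X^T V + \lambda \hat W_0)(V^T V + \lambda I_q)^{-1}}.
#' Each step is the exact coordinate minimizer, so the objective is
#' non-increasing. \eqn{\lambda = 0} is unpenalized low-rank
#' factorization; large \eqn{\lambda} pins \eqn{W} at \eqn{\hat W_0}.
#'
#' @param target target [expression_matrix()] (n0 x p), same gene space
#'   as the loading.
#' @param W0 p x q source loading matrix.
#' @param lam nonnegative penalty \eqn{\lambda}.
#' @param max_iter maximum alternations (default 200).
#' @param tol relative objective change for convergence (default 1e-6).
#' @return a `transfer_fit` list: `W` (p x q), `V` (n0 x q), `lam`,
#'   `objective_trace`, `n_iter`, `converged`.
#' @export
fit_transfer <- function(target, W0, lam, max_iter = 200, tol = 1e-6) {
  X <- unclass_expr(expression_matrix(unclass_expr(target)))
  W0 <- as.matrix(W0)
  if (ncol(X) != nrow(W0))
    stop("target has ", ncol(X), " genes but W0 has ", nrow(W0), " rows")
  if (lam < 0) stop("lam must be nonnegative")
  q <- ncol(W0)
  W <- W0
  obj <- function(W, V)
    sum((X - tcrossprod(V, W))^2) + lam * sum((W - W0)^2)
  trace <- numeric(0)
  converged <- FALSE
  V <- NULL
  for (iter in seq_len(max_iter)) {
    # V-step: one linear system for all rows
    G <- crossprod(W)
    G <- guard_spd(G)
    V <- t(solve(G, t(X %*% W)))
    # W-step
    H <- crossprod(V) + lam * diag(q)
    if (lam == 0) H <- guard_spd(H)
    W <- t(solve(H, t(crossprod(X, V) + lam * W0)))
    trace <- c(trace, obj(W, V))
    if (iter > 1 &&
        (trace[iter - 1] - trace[iter]) <=
          tol * (abs(trace[iter - 1]) + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  structure(list(W = W, V = V, lam = lam, objective_trace = trace,
                 n_iter = length(trace), converged = converged),
            class = "transfer_fit")
}

guard_spd <- function(G, ridge = 1e-8) {
  ev <- tryCatch(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
                 error = function(e) 0)
  if (ev < ridge) {
    warning("near-singular Gram matrix; adding ridge ", ridge)
    G <- G + ridge * diag(nrow(G))
  }
  G
}

#' Select the transfer penalty by two-fold reconstruction error
#'
#' The target rows are shuffled (by `seed`) and split into two equal
#' folds. For each candidate \eqn{\lambda}, [fit_transfer()] is run on
#' each fold and the *other* fold is reconstructed by least-squares
#' projection onto the fitted loading's span:
#' \eqn{\|X_B - X_B W_A (W_A^T W_A)^{-1} W_A^T\|_F^2} (and
#' symmetrically A from B); the CV error is the sum. Returns the grid
#' value minimizing CV error, breaking ties toward larger
#' \eqn{\lambda} (more transfer).
#'
#' @inheritParams fit_transfer
#' @param grid nonnegative candidate penalties; `NULL` uses the default
#'   scale-aware grid \eqn{\{0, 0.01, 0.1, 1, 10, 100\} \cdot
#'   n_0 p / (\|\hat W_0\|_F^2 + 1)}.
#' @param seed integer seed for the fold split.
#' @return list with `lam_star` and `cv_table` (data.frame of lambda,
#'   cv_error).
#' @export
select_lambda <- function(target, W0, grid = NULL, seed = 1L,
                          max_iter = 200, tol = 1e-6) {
  X <- unclass_expr(expression_matrix(unclass_expr(target)))
  W0 <- as.matrix(W0)
  n0 <- nrow(X)
  if (n0 < 4) stop("need at least 4 target rows for two-fold selection")
  if (is.null(grid))
    grid <- c(0, 0.01, 0.1, 1, 10, 100) * n0 * ncol(X) / (sum(W0^2) + 1)
  if (length(grid) == 0) stop("empty lambda grid")
  if (any(grid < 0)) stop("lambda grid must be nonnegative")
  set.seed(seed)
  perm <- sample.int(n0)
  half <- floor(n0 / 2)
  folds <- list(perm[seq_len(half)], perm[seq(half + 1, n0)])
  proj_err <- function(Xh, W) {
    G <- guard_spd(crossprod(W))
    sum((Xh - (Xh %*% W) %*% solve(G, t(W)))^2)
  }
  cv <- vapply(grid, function(lam) {
    WA <- fit_transfer(X[folds[[1]], , drop = FALSE], W0, lam,
                       max_iter = max_iter, tol = tol)$W
    WB <- fit_transfer(X[folds[[2]], , drop = FALSE], W0, lam,
                       max_iter = max_iter, tol = tol)$W
    proj_err(X[folds[[2]], , drop = FALSE], WA) +
      proj_err(X[folds[[1]], , drop = FALSE], WB)
  }, numeric(1))
  ord <- order(grid)
  grid_s <- grid[ord]; cv_s <- cv[ord]
  best <- max(which(cv_s <= min(cv_s) * (1 + 1e-12)))
  list(lam_star = grid_s[best],
       cv_table = data.frame(lambda = grid_s, cv_error = cv_s))
}

#' Rotate factors to their principal axes
#'
#' Centers the factor matrix and rotates it so the columns are
#' orthogonal with decreasing variance (the principal-component
#' convention). The factor basis coming out of penalized ALS is
#' arbitrary up to an invertible transform; downstream Gaussian
#' mixture fitting is basis-equivariant, but its k-means++
#' initialization is not, so a canonical well-conditioned orientation
#' makes clustering reproducible and geometry-friendly.
#'
#' @param V n x q factor matrix.
#' @return n x q rotated factor matrix.
#' @export
canonicalize_factors <- function(V) {
  stats::prcomp(as.matrix(V), center = TRUE, scale. = FALSE)$x
}

#' @export
print.transfer_fit <- function(x, ...) {
  cat("transfer_fit: n0 =", nrow(x$V), "spots, q =", ncol(x$W),
      "factors, lambda =", format(x$lam, digits = 4), ";",
      x$n_iter, "ALS iterations\n")
  invisible(x)
}
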