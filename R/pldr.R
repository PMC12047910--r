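#' Fit the supervised probabilistic linear dimension-reduction model
#'
#' Factor model for labeled source expression: for spot i of class k,
#' \deqn{x_i = W_0 u_i + \epsilon_i,\quad \epsilon_i \sim N(0, \Lambda),\quad
#'       u_i \mid z_i = k \sim N(\mu_k, \Sigma_k),}
#' with \eqn{W_0} a p x q loading matrix and \eqn{\Lambda} diagonal.
#' Labels are known, so the fit is maximum likelihood by EM with
#' closed-form steps: the E-step conditions each factor on its
#' observation (Gaussian conjugacy), the M-step updates \eqn{W_0},
#' \eqn{\Lambda} and the per-class factor moments from the posterior
#' first/second moments.
#'
#' After convergence the loading is rotated so that
#' \eqn{W_0^T \Lambda^{-1} W_0} is diagonal with decreasing entries
#' (factors and class moments are counter-rotated), giving a
#' reproducible representative of the rotation equivalence class.
#'
#' @param source a [labeled_source()].
#' @param q latent dimension (default 15). Must satisfy
#'   `q < min(n1, p)` and every class needs at least `q + 1` members.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood change for convergence.
#' @param seed integer seed (initialization is deterministic; kept for
#'   interface symmetry with the stochastic stages).
#' @return a `pldr_fit` list: `W0` (p x q), `Lambda` (length p),
#'   `class_means` (K x q), `class_covs` (q x q x K), `factors`
#'   (n1 x q posterior means), `loglik_trace`, `q`, `n_iter`,
#'   `converged`, `gene_ids`.
#' @export
fit_pldr <- function(source, q = 15, max_iter = 100, tol = 1e-6, seed = 1L) {
  stopifnot(inherits(source, "labeled_source"))
  X <- unclass_expr(source$expr)
  z <- source$labels
  n <- nrow(X); p <- ncol(X); K <- max(z)
  if (q >= min(n, p)) stop("q must be smaller than min(n1, p)")
  nk <- tabulate(z, K)
  if (any(nk < q + 1))
    stop("every class needs at least q + 1 = ", q + 1, " members; counts: ",
         paste(nk, collapse = ", "))
  set.seed(seed)

  # init: SVD of the centered matrix; loadings scaled by singular values
  xb <- colMeans(X)
  Xc <- sweep(X, 2, xb, "-")
  sv <- svd(Xc, nu = q, nv = q)
  W0 <- sv$v %*% diag(sv$d[seq_len(q)] / sqrt(n), q)
  U <- sqrt(n) * sv$u
  Lambda <- pmax(colMeans((Xc - U %*% t(W0))^2), 1e-6)
  mu <- matrix(0, K, q); Sig <- array(0, c(q, q, K))
  for (k in seq_len(K)) {
    Uk <- U[z == k, , drop = FALSE]
    mu[k, ] <- colMeans(Uk)
    Sig[, , k] <- stats::cov(Uk) * (nk[k] - 1) / nk[k]
    Sig[, , k] <- ridge_pd(Sig[, , k])
  }

  XtX_diag <- colSums(X^2)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  M <- matrix(0, n, q)
  for (iter in seq_len(max_iter)) {
    # E-step: per class, posterior cov A_k and means m_i
    Li <- 1 / Lambda
    WtLi <- t(W0 * Li)                       # q x p
    G <- WtLi %*% W0                         # W0' Lambda^-1 W0
    S <- matrix(0, q, q)                     # sum_i E[u_i u_i']
    Sk_post <- array(0, c(q, q, K))
    for (k in seq_len(K)) {
      idx <- which(z == k)
      Sig_inv <- chol2inv(chol(Sig[, , k]))
      A <- chol2inv(chol(G + Sig_inv))
      rhs <- X[idx, , drop = FALSE] %*% t(WtLi) +
        matrix(drop(Sig_inv %*% mu[k, ]), length(idx), q, byrow = TRUE)
      Mk <- rhs %*% A
      M[idx, ] <- Mk
      Sk_post[, , k] <- nk[k] * A + crossprod(Mk)
      S <- S + Sk_post[, , k]
    }
    # M-step
    XtM <- crossprod(X, M)                   # p x q
    W0 <- t(solve(S, t(XtM)))
    Lambda <- pmax((XtX_diag - 2 * rowSums(XtM * W0) +
                      rowSums((W0 %*% S) * W0)) / n, 1e-6)
    for (k in seq_len(K)) {
      idx <- which(z == k)
      mu[k, ] <- colMeans(M[idx, , drop = FALSE])
      Ck <- Sk_post[, , k] / nk[k] - tcrossprod(mu[k, ])
      Sig[, , k] <- ridge_pd((Ck + t(Ck)) / 2)
    }
    ll <- pldr_loglik_params(X, z, W0, Lambda, mu, Sig)
    if (is.finite(ll_old) && ll < ll_old &&
        ll_old - ll <= 1e-9 * (abs(ll_old) + 1)) {
      # numerically null step: the exact EM update cannot decrease the
      # likelihood, so a sub-fp-resolution dip means convergence; keep
      # the previous parameters
      W0 <- prev$W0; Lambda <- prev$Lambda; mu <- prev$mu; Sig <- prev$Sig
      converged <- TRUE
      break
    }
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-10)) {
      converged <- TRUE
      break
    }
    prev <- list(W0 = W0, Lambda = Lambda, mu = mu, Sig = Sig)
    ll_old <- ll
  }

  # final E-step factors at converged parameters
  Li <- 1 / Lambda
  WtLi <- t(W0 * Li)
  G <- WtLi %*% W0
  for (k in seq_len(K)) {
    idx <- which(z == k)
    Sig_inv <- chol2inv(chol(Sig[, , k]))
    A <- chol2inv(chol(G + Sig_inv))
    rhs <- X[idx, , drop = FALSE] %*% t(WtLi) +
      matrix(drop(Sig_inv %*% mu[k, ]), length(idx), q, byrow = TRUE)
    M[idx, ] <- rhs %*% A
  }

  # identifiability: rotate so W0' Lambda^-1 W0 is diagonal, decreasing
  G <- crossprod(W0 * sqrt(Li))
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  Q <- eg$vectors
  # fix signs: largest-magnitude loading entry of each column positive
  for (j in seq_len(q)) {
    wj <- W0 %*% Q[, j]
    if (wj[which.max(abs(wj))] < 0) Q[, j] <- -Q[, j]
  }
  W0 <- W0 %*% Q
  M <- M %*% Q
  mu <- mu %*% Q
  for (k in seq_len(K)) Sig[, , k] <- t(Q) %*% Sig[, , k] %*% Q

  structure(list(W0 = W0, Lambda = Lambda, class_means = mu,
                 class_covs = Sig, factors = M, loglik_trace = trace,
                 q = q, n_iter = length(trace), converged = converged,
                 gene_ids = colnames(X)),
            class = "pldr_fit")
}

ridge_pd <- function(S, min_eig = 1e-8, ridge = 1e-6) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < min_eig) {
    warning("covariance ridge-repaired (min eigenvalue ",
            format(min(ev), digits = 3), ")")
    S <- S + (ridge + max(0, -min(ev))) * diag(nrow(S))
  }
  S
}

pldr_loglik_params <- function(X, z, W0, Lambda, mu, Sig) {
  K <- max(z)
  ll <- 0
  for (k in seq_len(K)) {
    idx <- which(z == k)
    Vk <- W0 %*% Sig[, , k] %*% t(W0) + diag(Lambda, nrow = length(Lambda))
    ch <- tryCatch(chol(Vk), error = function(e)
      stop("singular marginal covariance for class ", k,
           " (condition number ", format(kappa(Vk), digits = 3), ")"))
    ctr <- sweep(X[idx, , drop = FALSE], 2, drop(W0 %*% mu[k, ]), "-")
    Y <- backsolve(ch, t(ctr), transpose = TRUE)
    ll <- ll - 0.5 * (length(idx) * (ncol(X) * log(2 * pi) +
                                       2 * sum(log(diag(ch)))) + sum(Y^2))
  }
  ll
}

#' Marginal log-likelihood of a fitted pLDR model
#'
#' Integrates the factors out: each row of class k contributes
#' \eqn{\log N(x_i;\, W_0\mu_k,\; W_0\Sigma_k W_0^T + \Lambda)}.
#'
#' @param fit a `pldr_fit`.
#' @param source the [labeled_source()] to evaluate on.
#' @return scalar log-likelihood.
#' @export
pldr_loglik <- function(fit, source) {
  stopifnot(inherits(fit, "pldr_fit"), inherits(source, "labeled_source"))
  X <- unclass_expr(source$expr)
  if (ncol(X) != nrow(fit$W0)) stop("gene dimension mismatch")
  pldr_loglik_params(X, source$labels, fit$W0, fit$Lambda,
                     fit$class_means, fit$class_covs)
}

#' @export
print.pldr_fit <- function(x, ...) {
  cat("pldr_fit: p =", nrow(x$W0), "genes, q =", x$q, "factors,",
      nrow(x$class_means), "classes;", x$n_iter, "EM iterations",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}
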