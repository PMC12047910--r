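# simulate directly from the factor model:
# x = W0 u + eps, u | z=k ~ N(mu_k, I), eps ~ N(0, noise^2 I)
sim_pldr <- function(n, p, q, K, noise = 0.3, sep = 3, seed = 1) {
  set.seed(seed)
  W <- qr.Q(qr(matrix(rnorm(p * q), p, q)))
  mu <- matrix(0, K, q)
  for (k in seq_len(K)) mu[k, (k - 1) %% q + 1] <- sep
  z <- rep_len(seq_len(K), n)
  U <- mu[z, , drop = FALSE] + matrix(rnorm(n * q), n, q)
  X <- U %*% t(W) + noise * matrix(rnorm(n * p), n, p)
  list(src = labeled_source(expression_matrix(X), z), W = W, U = U)
}

test_that("noiseless rank-q data is reconstructed almost exactly", {
  set.seed(3)
  n <- 200; p <- 15; q <- 3
  A <- matrix(rnorm(p * q), p, q)
  U <- matrix(rnorm(n * q), n, q)
  X <- U %*% t(A)
  fit <- fit_pldr(labeled_source(expression_matrix(X), rep(1L, n)), q = q)
  rel <- norm(X - fit$factors %*% t(fit$W0), "F") / norm(X, "F")
  expect_lt(rel, 1e-3)
  expect_lt(max(fit$Lambda), 1e-3)   # residual variances collapse to the floor
})

test_that("the loading subspace is recovered from model-simulated data", {
  d <- sim_pldr(n = 2000, p = 20, q = 2, K = 2, noise = 0.5, seed = 5)
  fit <- fit_pldr(d$src, q = 2)
  ang <- max_principal_angle(fit$W0, d$W)
  expect_lt(ang * 180 / pi, 5)
})

test_that("single-class fit approaches the principal subspace (pPCA limit)", {
  set.seed(11)
  n <- 3000; p <- 12; q <- 2
  W <- qr.Q(qr(matrix(rnorm(p * q), p, q))) %*% diag(c(4, 2.5))
  X <- matrix(rnorm(n * q), n, q) %*% t(W) + 0.5 * matrix(rnorm(n * p), n, p)
  fit <- fit_pldr(labeled_source(expression_matrix(X), rep(1L, n)), q = q)
  pc <- eigen(cov(X), symmetric = TRUE)$vectors[, 1:q]
  expect_lt(max_principal_angle(fit$W0, pc) * 180 / pi, 5)
})

test_that("EM log-likelihood traces are monotone across seeds", {
  for (s in 1:4) {
    d <- sim_pldr(n = 300, p = 25, q = 3, K = 3, seed = 100 + s)
    fit <- fit_pldr(d$src, q = 3)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("marginal log-likelihood matches closed forms and quadrature", {
  mkfit <- function(W0, Lambda, mu, Sig) {
    structure(list(W0 = W0, Lambda = Lambda, class_means = mu,
                   class_covs = Sig, q = ncol(W0)), class = "pldr_fit")
  }
  # p = q = 1, W0 = 1, Lambda = 1, mu = 0, Sigma = 1, x = 0:
  # marginal is N(0, 2)
  fit <- mkfit(matrix(1), 1, matrix(0, 1, 1), array(1, c(1, 1, 1)))
  src <- labeled_source(expression_matrix(matrix(0, 1, 1)), 1L)
  expect_equal(pldr_loglik(fit, src), -0.5 * log(4 * pi), tolerance = 1e-12)

  # moving mu toward the class sample mean increases the likelihood
  set.seed(2)
  x <- matrix(rnorm(50, mean = 2), 50, 1)
  src2 <- labeled_source(expression_matrix(x), rep(1L, 50))
  ll <- sapply(c(0, 1, mean(x)), function(m)
    pldr_loglik(mkfit(matrix(1), 1, matrix(m, 1, 1), array(1, c(1, 1, 1))),
                src2))
  expect_true(all(diff(ll) > 0))

  # quadrature oracle for the 1-D integral of N(x; W0 u, L) N(u; m, S)
  W0 <- matrix(1.7); L <- 0.6; m <- 0.4; S <- 1.3; xv <- 0.9
  grid <- seq(-12, 12, length.out = 20001)
  h <- grid[2] - grid[1]
  integrand <- dnorm(xv, mean = 1.7 * grid, sd = sqrt(L)) *
    dnorm(grid, mean = m, sd = sqrt(S))
  ll_quad <- log(sum(integrand) * h)
  fit3 <- mkfit(W0, L, matrix(m, 1, 1), array(S, c(1, 1, 1)))
  src3 <- labeled_source(expression_matrix(matrix(xv, 1, 1)), 1L)
  expect_equal(pldr_loglik(fit3, src3), ll_quad, tolerance = 1e-4)
})

test_that("the fitted subspace is seed- and row-order-invariant", {
  d <- sim_pldr(n = 800, p = 20, q = 3, K = 3, seed = 8)
  f1 <- fit_pldr(d$src, q = 3, seed = 1)
  f2 <- fit_pldr(d$src, q = 3, seed = 999)
  expect_lt(max_principal_angle(f1$W0, f2$W0), 1e-2)

  perm <- sample(nrow(d$src$expr))
  shuf <- labeled_source(expression_matrix(unclass(d$src$expr)[perm, ]),
                         d$src$labels[perm])
  f3 <- fit_pldr(shuf, q = 3, seed = 1)
  expect_lt(max_principal_angle(f1$W0, f3$W0), 1e-2)
})

test_that("doubling the data quadruples the fitted marginal covariance", {
  d <- sim_pldr(n = 600, p = 15, q = 2, K = 2, seed = 13)
  f1 <- fit_pldr(d$src, q = 2)
  X2 <- expression_matrix(2 * unclass(d$src$expr))
  f2 <- fit_pldr(labeled_source(X2, d$src$labels), q = 2)
  marg <- function(f, k) f$W0 %*% f$class_covs[, , k] %*% t(f$W0) + diag(f$Lambda)
  expect_equal(marg(f2, 1), 4 * marg(f1, 1), tolerance = 0.05)
})

test_that("argument errors are raised for infeasible q and small classes", {
  d <- sim_pldr(n = 14, p = 10, q = 2, K = 2, seed = 3)
  expect_error(fit_pldr(d$src, q = 10), "smaller than")
  expect_error(fit_pldr(d$src, q = 9), "q \\+ 1")
})
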