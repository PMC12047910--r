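lattice_coords <- function(h, w) {
  cbind(x = rep(seq_len(w), times = h), y = rep(seq_len(h), each = w))
}

# clustered factors on a Potts label field
sim_spatial_factors <- function(h = 12, w = 12, K = 4, q = 3, sep = 2,
                                beta_true = 1, seed = 1) {
  z <- as.integer(t(sample_potts(h, w, K, beta_true, seed = seed)))
  set.seed(seed + 1)
  mu <- matrix(0, K, q)
  for (k in seq_len(K)) mu[k, (k - 1) %% q + 1] <- sep * (-1)^((k - 1) %/% q)
  V <- mu[z, , drop = FALSE] + matrix(rnorm(length(z) * q), length(z), q)
  list(V = V, z = z, coords = lattice_coords(h, w))
}

test_that("knn graph construction matches hand-computed neighborhoods", {
  # 1-D points 0, 1, 3 with k = 1: nearest of 0 is 1, of 1 is 0, of 3 is 1;
  # symmetrization yields edges {1-2, 2-3}
  g <- build_knn_graph(cbind(c(0, 1, 3), 0), k = 1)
  expect_equal(g$neighbors, list(2L, c(1L, 3L), 2L))

  # interior node of a unit lattice with k = 4 gets its rook neighbors
  co <- lattice_coords(5, 5)
  g2 <- build_knn_graph(co, k = 4)
  center <- which(co[, 1] == 3 & co[, 2] == 3)
  rook <- which((abs(co[, 1] - 3) + abs(co[, 2] - 3)) == 1)
  expect_setequal(g2$neighbors[[center]], rook)

  # symmetry invariant: i in N(j) <=> j in N(i)
  for (i in seq_len(g2$n)) for (j in g2$neighbors[[i]])
    expect_true(i %in% g2$neighbors[[j]])

  expect_equal(formals(build_knn_graph)$k, 5)
  expect_error(build_knn_graph(co, k = 25), "smaller")
})

test_that("neighbor disagreement counts follow the Potts conditional", {
  co <- lattice_coords(4, 4)
  g <- build_knn_graph(co, k = 4)
  z <- rep(1L, 16)
  i <- which(co[, 1] == 2 & co[, 2] == 2)
  expect_equal(potts_neighbor_disagreement(z, g, i, 1), 0)
  expect_equal(potts_neighbor_disagreement(z, g, i, 2),
               length(g$neighbors[[i]]))
  # checkerboard 2-coloring: all rook neighbors disagree with own color
  zc <- as.integer(1 + (co[, 1] + co[, 2]) %% 2)
  rook_g <- build_knn_graph(co, k = 2)  # corner spots keep rook adjacency
  inner <- which(co[, 1] %in% 2:3 & co[, 2] %in% 2:3)
  g4 <- build_knn_graph(co, k = 4)
  for (i in inner) {
    nb <- g4$neighbors[[i]]
    rook_nb <- nb[abs(co[nb, 1] - co[i, 1]) + abs(co[nb, 2] - co[i, 2]) == 1]
    expect_equal(sum(zc[rook_nb] != zc[i]), length(rook_nb))
  }
})

test_that("beta = 0 reproduces plain hard-EM GMM labels exactly", {
  for (r in 1:5) {
    d <- sim_spatial_factors(10, 10, K = 3, q = 2, sep = 2.5, seed = 40 + r)
    g <- build_knn_graph(d$coords, k = 5)
    fit <- fit_spgmm(d$V, g, K = 3, beta_grid = 0, seed = r)
    ref <- ref_hard_em_gmm(d$V, fit$init_labels, K = 3)
    expect_identical(fit$labels, ref)
    expect_equal(fit$beta, 0)
  }
})

test_that("K = 1 yields a single component at the data centroid", {
  d <- sim_spatial_factors(6, 6, K = 2, q = 2, seed = 3)
  g <- build_knn_graph(d$coords, k = 5)
  fit <- fit_spgmm(d$V, g, K = 1, beta_grid = c(0, 0.5))
  expect_true(all(fit$labels == 1L))
  expect_equal(drop(fit$means), colMeans(d$V))
})

test_that("the ICM-EM joint objective is non-decreasing", {
  for (r in 1:3) {
    d <- sim_spatial_factors(12, 12, K = 4, q = 3, seed = 60 + r)
    g <- build_knn_graph(d$coords, k = 5)
    fit <- fit_spgmm(d$V, g, K = 4, beta_grid = c(0.5), seed = r)
    tr <- fit$joint_trace
    if (length(tr) > 1)
      expect_true(all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1)))
  }
})

test_that("responsibilities are row-stochastic and covariances PD", {
  d <- sim_spatial_factors(8, 8, K = 3, q = 2, seed = 17)
  g <- build_knn_graph(d$coords, k = 5)
  fit <- fit_spgmm(d$V, g, K = 3, beta_grid = c(0, 0.4, 0.8), seed = 2)
  expect_equal(rowSums(fit$responsibilities), rep(1, 64), tolerance = 1e-10)
  for (k in 1:3) {
    ev <- eigen(fit$covs[, , k], symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_equal(fit$covs[, , k], t(fit$covs[, , k]))
  }
  expect_true(fit$beta >= 0 && fit$beta <= 1)
})

test_that("neighbor agreement of the labeling increases with beta", {
  d <- sim_spatial_factors(12, 12, K = 4, q = 3, sep = 1.5, seed = 23)
  g <- build_knn_graph(d$coords, k = 5)
  grid <- seq(0, 1, by = 0.25)
  ag <- sapply(grid, function(b)
    neighbor_agreement(fit_spgmm(d$V, g, 4, beta_grid = b, seed = 5)$labels, g))
  # monotone up to at most one inversion
  expect_lte(sum(diff(ag) < -1e-12), 1)
  expect_gt(ag[length(ag)], ag[1] - 1e-12)
})

test_that("component order permutation leaves the partition unchanged", {
  d <- sim_spatial_factors(9, 9, K = 3, q = 2, seed = 31)
  g <- build_knn_graph(d$coords, k = 5)
  f1 <- fit_spgmm(d$V, g, K = 3, beta_grid = c(0, 0.5), seed = 4)
  perm <- c(3L, 1L, 2L)
  f2 <- fit_spgmm(d$V, g, K = 3, beta_grid = c(0, 0.5),
                  init_labels = perm[f1$init_labels])
  expect_equal(adjusted_rand_index(f1$labels, f2$labels), 1)
})

test_that("the BIC-type criterion recovers K on separated data", {
  d <- sim_spatial_factors(10, 10, K = 3, q = 2, sep = 6, seed = 77)
  g <- build_knn_graph(d$coords, k = 5)
  sel <- select_K(d$V, g, K_range = 2:5, beta_grid = c(0, 0.5, 1), seed = 1)
  expect_equal(sel$K_hat, 3)
  expect_equal(nrow(sel$criterion_table), 4)

  sel1 <- select_K(d$V, g, K_range = 3, beta_grid = 0.5)
  expect_equal(sel1$K_hat, 3)

  # replicating every spot at its position, with the replicated fit held
  # at the single-scale partition, preserves the criterion ordering:
  # the pseudo-likelihood doubles while the penalty grows only in log n
  n <- nrow(d$V)
  V2 <- rbind(d$V, d$V)
  co2 <- rbind(d$coords, d$coords + 0.25)
  g2 <- build_knn_graph(co2, k = 5)
  crit <- function(V, g, K, init) {
    f <- fit_spgmm(V, g, K, beta_grid = 0.5, init_labels = init)
    -2 * f$pseudo_loglik + log(nrow(V)) * (K * 2 + K * 3)
  }
  ord1 <- order(sapply(2:4, function(K) {
    i <- fit_spgmm(d$V, g, K, beta_grid = 0.5, seed = 1)$init_labels
    crit(d$V, g, K, i)
  }))
  ord2 <- order(sapply(2:4, function(K) {
    i <- fit_spgmm(d$V, g, K, beta_grid = 0.5, seed = 1)$init_labels
    crit(V2, g2, K, rep(i, 2))
  }))
  expect_equal(ord1, ord2)
})
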