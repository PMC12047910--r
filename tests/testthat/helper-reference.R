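# Independent reference implementations used as oracles.

# largest principal angle (radians) between the column spans of A and B
max_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(0, min(s))))
}

# plain hard-EM (classification EM) Gaussian mixture with equal weights,
# mirroring the spatial model at beta = 0: classify by max density, then
# moment updates, until the labels stop changing.
ref_hard_em_gmm <- function(V, init_labels, K, max_iter = 50) {
  labels <- as.integer(init_labels)
  n <- nrow(V); q <- ncol(V)
  moments <- function(labels) {
    mu <- matrix(0, K, q); Sig <- array(0, c(q, q, K))
    for (k in seq_len(K)) {
      Vk <- V[labels == k, , drop = FALSE]
      mu[k, ] <- colMeans(Vk)
      C <- if (nrow(Vk) > 1)
        crossprod(sweep(Vk, 2, mu[k, ])) / nrow(Vk) else diag(q)
      C <- (C + t(C)) / 2
      ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
      if (ev < 1e-8) C <- C + (1e-6 + max(0, -ev)) * diag(q)
      Sig[, , k] <- C
    }
    list(mu = mu, Sig = Sig)
  }
  log_dens <- function(mu, Sig) {
    L <- matrix(0, n, K)
    for (k in seq_len(K)) {
      R <- chol(Sig[, , k])
      D <- sweep(V, 2, mu[k, ])
      Y <- backsolve(R, t(D), transpose = TRUE)
      L[, k] <- -0.5 * q * log(2 * pi) - sum(log(diag(R))) -
        0.5 * colSums(Y^2)
    }
    L
  }
  for (iter in seq_len(max_iter)) {
    m <- moments(labels)
    L <- log_dens(m$mu, m$Sig)
    newz <- max.col(L, ties.method = "first")
    # guard: a class emptied by reclassification would diverge from the
    # compiled path; the test instances are chosen to avoid this
    if (identical(newz, labels)) break
    labels <- newz
  }
  labels
}

# direct ARI from the contingency-table formula (kept separate from the
# package implementation on purpose)
ref_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) choose(x, 2)
  sij <- sum(ch2(tab)); sa <- sum(ch2(rowSums(tab))); sb <- sum(ch2(colSums(tab)))
  e <- sa * sb / ch2(length(a))
  m <- (sa + sb) / 2
  if (m == e) return(1)
  (sij - e) / (m - e)
}

# mean fraction of graph-neighbor pairs with equal labels
neighbor_agreement <- function(labels, graph) {
  agree <- 0; tot <- 0
  for (i in seq_along(labels)) {
    nb <- graph$neighbors[[i]]
    agree <- agree + sum(labels[nb] == labels[i])
    tot <- tot + length(nb)
  }
  agree / tot
}

# exact Potts distribution on a small lattice by enumeration:
# P(z) propto exp(-beta * #disagreeing rook-adjacent pairs)
potts_exact_2x2 <- function(K, beta) {
  states <- as.matrix(expand.grid(rep(list(seq_len(K)), 4)))
  # sites in row-major order: 1=(1,1), 2=(1,2), 3=(2,1), 4=(2,2)
  edges <- rbind(c(1, 2), c(3, 4), c(1, 3), c(2, 4))
  w <- apply(states, 1, function(z)
    exp(-beta * sum(z[edges[, 1]] != z[edges[, 2]])))
  w / sum(w)
}

state_index_2x2 <- function(z, K) {
  1 + (z[1] - 1) + K * (z[2] - 1) + K^2 * (z[3] - 1) + K^3 * (z[4] - 1)
}

# tweak a run_config in place
modifyList_cfg <- function(cfg, ...) {
  out <- utils::modifyList(unclass(cfg), list(...))
  class(out) <- "run_config"
  out
}
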