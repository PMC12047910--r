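#' Sample labels from the Potts model on a lattice
#'
#' Gibbs sampler on the `height x width` rook-adjacency lattice with
#' full conditionals \eqn{P(z_i = k \mid rest) \propto
#' \exp(-\beta\, \#\{j \in N_i : z_j \ne k\})}, started from i.i.d.
#' uniform labels. `beta = 0` gives i.i.d. uniform labels; larger
#' `beta` gives spatially clumped label fields.
#'
#' @param height,width lattice dimensions.
#' @param K number of states.
#' @param beta inverse-temperature / smoothing parameter (>= 0).
#' @param sweeps number of full Gibbs sweeps (default 50).
#' @param seed integer seed.
#' @param nchains number of independent chains (default 1).
#' @return with `nchains = 1`, a `height x width` integer matrix of
#'   labels in `1..K`; otherwise an `nchains x (height*width)` matrix
#'   of end states (sites in row-major order).
#' @export
sample_potts <- function(height, width, K, beta, sweeps = 50, seed = 1L,
                         nchains = 1L) {
  stopifnot(height >= 1, width >= 1, K >= 1, beta >= 0, sweeps >= 1)
  set.seed(seed)
  out <- potts_gibbs_cpp(height, width, K, beta, as.integer(sweeps),
                         as.integer(nchains))
  if (nchains == 1L)
    matrix(out[1L, ], height, width, byrow = TRUE)
  else out
}

#' Configuration for the benchmark simulator
#'
#' Defaults describe the benchmark regime the package is validated
#' in: a 30 x 30 target lattice with K = 4 spatially clumped clusters
#' (Potts `beta_true = 1`), a labeled non-spatial source of
#' `n1 = 2500` cells, `p = 200` genes, `q = 10` latent factors,
#' cluster means separated by `effect_size = 3` (unit factor
#' covariance, so clusters overlap moderately), the marker design in
#' which genes 1, 2, 3 and 4-10 uniquely mark clusters 1-4, and no
#' additive target noise (`noise_e = 0`).
#'
#' @param height,width target lattice dimensions (n0 = height*width).
#' @param n1 source size.
#' @param p gene count.
#' @param q latent dimension.
#' @param K number of clusters (>= 2).
#' @param beta_true Potts smoothing for the target label field.
#' @param noise_e additive target noise scale `e` (entries of
#'   `e * N(0,1)` are added to the target expression).
#' @param marker_map list (length K) of disjoint gene-index sets; the
#'   genes that uniquely mark each cluster. Default: genes 1, 2, 3,
#'   4:10 for K = 4, otherwise gene k marks cluster k.
#' @param effect_size separation scale for both factor means and
#'   marker shifts.
#' @param resid_sd standard deviation of the per-gene residual noise
#'   \eqn{\epsilon} added to both source and target expression (the
#'   factor model's own residual term; default 0.5).
#' @param seed integer seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(height = 30, width = 30, n1 = 2500, p = 200,
                       q = 10, K = 4, beta_true = 1, noise_e = 0,
                       marker_map = NULL, effect_size = 3,
                       resid_sd = 0.5, seed = 1L) {
  if (is.null(marker_map)) {
    marker_map <- if (K == 4) list(1L, 2L, 3L, 4:10)
    else as.list(seq_len(K))
  }
  stopifnot(K >= 2, q >= K, p >= q, n1 > q, height >= 1, width >= 1,
            beta_true >= 0, noise_e >= 0, resid_sd >= 0,
            length(marker_map) == K)
  idx <- unlist(marker_map)
  if (anyDuplicated(idx) || any(idx < 1) || any(idx > p))
    stop("marker_map sets must be disjoint gene indices in 1..p")
  structure(list(height = height, width = width, n1 = n1, p = p, q = q,
                 K = K, beta_true = beta_true, noise_e = noise_e,
                 marker_map = lapply(marker_map, as.integer),
                 effect_size = effect_size, resid_sd = resid_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Scenario presets for the scalability benchmark
#'
#' Four (n0, n1) sizes with p = 200: s1 (10000, 2500),
#' s2 (20000, 2500), s3 (10000, 5000), s4 (10000, 10000). The target
#' lattice is the near-square factorization of n0.
#'
#' @param name one of "s1", "s2", "s3", "s4".
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
scenario_config <- function(name = c("s1", "s2", "s3", "s4"), ...) {
  name <- match.arg(name)
  sizes <- list(s1 = c(10000, 2500), s2 = c(20000, 2500),
                s3 = c(10000, 5000), s4 = c(10000, 10000))
  n0 <- sizes[[name]][1]; n1 <- sizes[[name]][2]
  h <- 100; w <- n0 / h
  stopifnot(h * w == n0)
  args <- modifyList(list(height = h, width = w, n1 = n1, p = 200),
                     list(...))
  do.call(sim_config, args)
}

# deterministic, well-separated direction for cluster k in q dims:
# cycle the canonical axes with alternating sign
cluster_directions <- function(K, q) {
  D <- matrix(0, K, q)
  for (k in seq_len(K)) {
    ax <- (k - 1) %% q + 1
    sgn <- if (((k - 1) %/% q) %% 2 == 0) 1 else -1
    D[k, ax] <- sgn
  }
  D
}

# orthonormal loading whose first K columns are supported exactly on the
# marker genes of clusters 1..K (normalized indicators), with the
# remaining q-K columns a random orthonormal basis over the non-marker
# genes. Cluster k's mean mu_k = effect * e_k then elevates exactly its
# marker genes, so the marker genes uniquely determine the clusters
# while the expression stays an exact factors-times-loading product.
marker_loading <- function(p, q, marker_map) {
  K <- length(marker_map)
  stopifnot(q >= K)
  W <- matrix(0, p, q)
  for (k in seq_len(K)) {
    idx <- marker_map[[k]]
    W[idx, k] <- 1 / sqrt(length(idx))
  }
  rest <- setdiff(seq_len(p), unlist(marker_map))
  if (q > K) {
    B <- qr.Q(qr(matrix(rnorm(length(rest) * (q - K)), length(rest))))
    W[rest, (K + 1):q] <- B[, seq_len(q - K), drop = FALSE]
  }
  W
}

#' Generate a paired source/target benchmark dataset
#'
#' The generative chain: target labels come from the Potts model on
#' the lattice at `beta_true` (source labels are i.i.d. uniform —
#' the source carries no spatial structure); factors are
#' cluster-conditional Gaussians \eqn{u \mid z = k \sim
#' N(\mu_k, I_q)} with \eqn{\mu_k = \mathrm{effect\_size} \cdot e_k};
#' expression is the factors mapped through a shared orthonormal
#' loading matrix whose k-th column is supported exactly on cluster
#' k's marker genes (remaining columns: random orthonormal directions
#' over non-marker genes), so each cluster uniquely elevates its own
#' marker genes; the model's residual noise `resid_sd * N(0,1)` is
#' added to both source and target, and the target additionally
#' receives `noise_e * N(0,1)` noise. Coordinates are the lattice
#' positions.
#'
#' @param cfg a [sim_config()].
#' @return list with `source` ([labeled_source()]), `target`
#'   ([expression_matrix()]), `coords` (n0 x 2), `target_labels`
#'   (integer vector, row-major lattice order), `target_factors`,
#'   `source_factors`, `W` (the true loading), and `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n0 <- cfg$height * cfg$width
  z_tgt <- as.integer(t(sample_potts(cfg$height, cfg$width, cfg$K,
                                     cfg$beta_true, sweeps = 50,
                                     seed = cfg$seed)))
  # sample_potts consumed the stream; keep going from the post-Potts state
  z_src <- sample.int(cfg$K, cfg$n1, replace = TRUE)
  mu <- cfg$effect_size * cluster_directions(cfg$K, cfg$q)
  W <- marker_loading(cfg$p, cfg$q, cfg$marker_map)
  gene_ids <- paste0("gene_", seq_len(cfg$p))

  draw_block <- function(z, prefix) {
    n <- length(z)
    U <- mu[z, , drop = FALSE] + matrix(rnorm(n * cfg$q), n, cfg$q)
    X <- tcrossprod(U, W)
    if (cfg$resid_sd > 0)
      X <- X + cfg$resid_sd * matrix(rnorm(n * cfg$p), n, cfg$p)
    dimnames(X) <- list(paste0(prefix, seq_len(n)), gene_ids)
    list(X = X, U = U)
  }
  src <- draw_block(z_src, "src_")
  tgt <- draw_block(z_tgt, "tgt_")
  if (cfg$noise_e > 0)
    tgt$X <- tgt$X + cfg$noise_e * matrix(rnorm(n0 * cfg$p), n0, cfg$p)
  coords <- cbind(x = rep(seq_len(cfg$width), times = cfg$height),
                  y = rep(seq_len(cfg$height), each = cfg$width))
  rownames(coords) <- rownames(tgt$X)
  list(source = labeled_source(expression_matrix(src$X), z_src),
       target = expression_matrix(tgt$X),
       coords = coords,
       target_labels = z_tgt,
       target_factors = tgt$U,
       source_factors = src$U,
       W = W,
       cfg = cfg)
}
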