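#' Assemble a pipeline run configuration
#'
#' Inputs may be in-memory objects (matrices / label vectors) or file
#' paths understood by [read_expression()], [read_labels()] and
#' [read_coords()]. All hyperparameters are recorded in the run
#' report, including defaults.
#'
#' @param source_expr source expression (matrix, or path), or a list
#'   of several source matrices/paths to be combined.
#' @param source_labels labels per source (vector/path, or list
#'   matching `source_expr`).
#' @param target_expr target expression (matrix or path).
#' @param target_coords n0 x 2 coordinates (matrix or path).
#' @param q latent dimension (default 15).
#' @param n_hvg highly variable genes kept in preprocessing.
#' @param normalize logical; run the count-normalization steps
#'   (disable when inputs are already normalized).
#' @param k_neighbors spatial graph size (default 5).
#' @param lambda `"auto"` (two-fold selection) or a nonnegative value.
#' @param lambda_grid optional grid for `"auto"`.
#' @param beta_grid Potts smoothing line-search grid.
#' @param K `"auto"` (criterion search over `K_range`) or an integer.
#' @param K_range candidate cluster numbers for `K = "auto"`.
#' @param n_restarts clustering restarts, best kept by
#'   pseudo-likelihood (default 3).
#' @param seed master seed; per-stage seeds are derived as
#'   `seed + 1, ..., seed + 4` (source combine order: pldr, lambda,
#'   spgmm) so stages can be re-run in isolation.
#' @param expr_fmt on-disk format for expression paths.
#' @param out_dir optional output directory for `labels.tsv`,
#'   `factors.tsv` and `report.json`.
#' @return a `run_config` list.
#' @export
run_config <- function(source_expr, source_labels, target_expr,
                       target_coords, q = 15, n_hvg = 2000,
                       normalize = TRUE, k_neighbors = 5,
                       lambda = "auto", lambda_grid = NULL,
                       beta_grid = seq(0, 1, by = 0.1), K = "auto",
                       K_range = 2:8, n_restarts = 3L, seed = 1L,
                       expr_fmt = "csv", out_dir = NULL) {
  stopifnot(q >= 1, k_neighbors >= 1, length(seed) == 1)
  structure(list(source_expr = source_expr, source_labels = source_labels,
                 target_expr = target_expr, target_coords = target_coords,
                 q = q, n_hvg = n_hvg, normalize = normalize,
                 k_neighbors = k_neighbors, lambda = lambda,
                 lambda_grid = lambda_grid, beta_grid = beta_grid,
                 K = K, K_range = K_range, n_restarts = n_restarts,
                 seed = as.integer(seed),
                 expr_fmt = expr_fmt, out_dir = out_dir),
            class = "run_config")
}

load_expr <- function(x, fmt) {
  if (is.character(x) && length(x) == 1) read_expression(x, fmt = fmt)
  else expression_matrix(as.matrix(x))
}

load_lab <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) read_labels(x)
  else x
}

#' Run the full transfer-learning clustering pipeline
#'
#' Wiring: preprocess the target, align/combine the labeled sources
#' onto the target gene space, learn the loading matrix on the source
#' ([fit_pldr()]), transfer it to the target with a selected or given
#' penalty ([select_lambda()], [fit_transfer()]), build the spatial
#' graph and cluster the target factors ([fit_spgmm()] or
#' [select_K()]). Deterministic given the config.
#'
#' @param cfg a [run_config()].
#' @param true_labels optional ground-truth target labels; when given,
#'   the report includes the adjusted Rand index.
#' @return a `run_result` list: `labels` (integer vector named by spot
#'   id), `factors` (n0 x q), `pldr`, `transfer`, `spgmm`, and
#'   `report` (plain list, JSON-serializable).
#' @export
run_pipeline <- function(cfg, true_labels = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  seeds <- cfg$seed + 1:4

  target_raw <- load_expr(cfg$target_expr, cfg$expr_fmt)
  target <- preprocess(target_raw, n_hvg = cfg$n_hvg,
                       normalize = cfg$normalize)
  coords <- if (is.character(cfg$target_coords))
    read_coords(cfg$target_coords) else as.matrix(cfg$target_coords)
  stopifnot(nrow(coords) == nrow(target))

  srcs <- cfg$source_expr
  labs <- cfg$source_labels
  if (!is.list(srcs) || is.matrix(srcs)) { srcs <- list(srcs); labs <- list(labs) }
  sources <- mapply(function(x, l) labeled_source(load_expr(x, cfg$expr_fmt),
                                                  load_lab(l)),
                    srcs, labs, SIMPLIFY = FALSE)
  source <- align_and_combine_sources(sources, colnames(target), q = cfg$q,
                                      normalize = cfg$normalize)

  pldr <- fit_pldr(source, q = cfg$q, seed = seeds[2])

  if (identical(cfg$lambda, "auto")) {
    sel <- select_lambda(target, pldr$W0, grid = cfg$lambda_grid,
                         seed = seeds[3])
    lam <- sel$lam_star
    cv_table <- sel$cv_table
  } else {
    lam <- as.numeric(cfg$lambda)
    cv_table <- NULL
  }
  transfer <- fit_transfer(target, pldr$W0, lam)
  V <- canonicalize_factors(transfer$V)

  graph <- build_knn_graph(coords, k = cfg$k_neighbors)
  if (identical(cfg$K, "auto")) {
    ksel <- select_K(V, graph, K_range = cfg$K_range,
                     beta_grid = cfg$beta_grid, seed = seeds[4],
                     n_restarts = cfg$n_restarts)
    spgmm <- ksel$fit
    criterion_table <- ksel$criterion_table
  } else {
    spgmm <- fit_spgmm(V, graph, K = as.integer(cfg$K),
                       beta_grid = cfg$beta_grid, seed = seeds[4],
                       n_restarts = cfg$n_restarts)
    criterion_table <- NULL
  }

  labels <- stats::setNames(spgmm$labels, rownames(target))
  report <- list(
    n0 = nrow(target), n1 = nrow(source$expr), p = ncol(target),
    q = cfg$q, n_hvg = cfg$n_hvg, k_neighbors = cfg$k_neighbors,
    seed = cfg$seed, stage_seeds = seeds,
    lambda = lam, lambda_table = cv_table,
    beta = spgmm$beta, K = spgmm$K, criterion_table = criterion_table,
    pldr_iterations = pldr$n_iter, transfer_iterations = transfer$n_iter,
    spgmm_iterations = spgmm$n_iter,
    pseudo_loglik = spgmm$pseudo_loglik,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(true_labels))
    report$ari <- adjusted_rand_index(labels, true_labels)

  res <- structure(list(labels = labels, factors = V,
                        pldr = pldr, transfer = transfer, spgmm = spgmm,
                        report = report),
                   class = "run_result")
  if (!is.null(cfg$out_dir)) write_run_result(res, cfg$out_dir)
  res
}

#' Write pipeline outputs to a directory
#'
#' Writes `labels.tsv` (row_id, cluster), `factors.tsv` (row_id plus
#' one column per factor) and `report.json`.
#'
#' @param res a `run_result`.
#' @param dir output directory (created if missing).
#' @export
write_run_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(row_id = names(res$labels),
                         cluster = as.integer(res$labels)),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  fac <- data.frame(row_id = names(res$labels), res$factors)
  colnames(fac) <- c("row_id", paste0("factor_", seq_len(ncol(res$factors))))
  write.table(fac, file.path(dir, "factors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", null = "null")
  invisible(dir)
}

#' @export
print.run_result <- function(x, ...) {
  r <- x$report
  cat("run_result: n0 =", r$n0, ", K =", r$K, ", beta =", r$beta,
      ", lambda =", format(r$lambda, digits = 4))
  if (!is.null(r$ari)) cat(", ARI =", format(r$ari, digits = 3))
  cat("\n")
  invisible(x)
}
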