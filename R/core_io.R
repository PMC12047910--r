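#' Construct and validate an expression matrix
#'
#' The package-wide container for expression data is a plain numeric
#' matrix oriented spots-by-genes, with unique row names (spot/cell
#' ids) and unique column names (gene ids). This helper validates and
#' stamps the class attribute so downstream stages can assume the
#' invariants.
#'
#' @param values numeric matrix, rows = spots/cells, columns = genes.
#' @param row_ids character vector of unique spot ids; defaults to
#'   existing rownames or `spot_1..spot_n`.
#' @param gene_ids character vector of unique gene ids; defaults to
#'   existing colnames or `gene_1..gene_p`.
#' @return the matrix with dimnames set and class `expression_matrix`.
#' @export
expression_matrix <- function(values, row_ids = NULL, gene_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite entries")
  if (is.null(row_ids))
    row_ids <- rownames(values) %||%
      as.character(sprintf("spot_%d", seq_len(nrow(values))))
  if (is.null(gene_ids))
    gene_ids <- colnames(values) %||%
      as.character(sprintf("gene_%d", seq_len(ncol(values))))
  if (length(row_ids) != nrow(values) || anyDuplicated(row_ids))
    stop("row_ids must be unique and match the number of rows")
  if (length(gene_ids) != ncol(values) || anyDuplicated(gene_ids))
    stop("gene_ids must be unique and match the number of columns")
  dimnames(values) <- list(as.character(row_ids), as.character(gene_ids))
  class(values) <- c("expression_matrix", class(values))
  values
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundle an expression matrix with per-row cluster labels
#'
#' @param expr expression matrix (see [expression_matrix()]).
#' @param labels integer vector of cluster labels in `1..K`, one per row,
#'   or a factor/character vector which is re-coded to integers in sorted
#'   label order (the original codes are kept as `label_levels`).
#' @return a `labeled_source` list with elements `expr`, `labels`,
#'   `label_levels`.
#' @export
labeled_source <- function(expr, labels) {
  expr <- expression_matrix(unclass_expr(expr))
  if (length(labels) != nrow(expr))
    stop("labels length must equal the number of expression rows")
  if (is.numeric(labels) && all(labels == as.integer(labels))) {
    lv <- as.character(sort(unique(as.integer(labels))))
    z <- match(as.character(as.integer(labels)), lv)
  } else {
    lv <- sort(unique(as.character(labels)))
    z <- match(as.character(labels), lv)
  }
  structure(list(expr = expr, labels = as.integer(z), label_levels = lv),
            class = "labeled_source")
}

unclass_expr <- function(x) {
  class(x) <- "matrix"
  x
}

#' Read an expression matrix from disk
#'
#' Supports dense delimited files (CSV/TSV with a header row and row
#' ids in the first column) and MatrixMarket sparse files with
#' companion row/column name files (`<path>.rownames`,
#' `<path>.colnames`, one name per line). The on-disk orientation is
#' declared by `orientation`; the returned matrix is always
#' spots-by-genes. Duplicate gene names are disambiguated with
#' `make.unique` suffixes (`ACTB`, `ACTB.1`, ...).
#'
#' @param path file path.
#' @param fmt one of `"csv"`, `"tsv"`, `"mtx"`.
#' @param orientation `"spots_by_genes"` (default) or `"genes_by_spots"`.
#' @param rownames_path,colnames_path companion name files for `mtx`;
#'   defaults are `<path>.rownames` / `<path>.colnames`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, fmt = c("csv", "tsv", "mtx"),
                            orientation = c("spots_by_genes", "genes_by_spots"),
                            rownames_path = paste0(path, ".rownames"),
                            colnames_path = paste0(path, ".colnames")) {
  fmt <- match.arg(fmt)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed MatrixMarket file ",
                                           path, ": ", conditionMessage(e)))
    m <- as.matrix(m)
    if (!file.exists(rownames_path) || !file.exists(colnames_path))
      stop("companion name files missing for ", path,
           " (expected ", rownames_path, " and ", colnames_path, ")")
    rn <- readLines(rownames_path)
    cn <- readLines(colnames_path)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("dimension mismatch: matrix is ", nrow(m), "x", ncol(m),
           " but name files have ", length(rn), " / ", length(cn), " entries")
    dimnames(m) <- list(rn, cn)
  } else {
    sep <- if (fmt == "csv") "," else "\t"
    df <- tryCatch(
      read.table(path, sep = sep, header = TRUE, row.names = 1,
                 check.names = FALSE, comment.char = ""),
      error = function(e) stop("malformed ", fmt, " file ", path, ": ",
                               conditionMessage(e)))
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("non-numeric entries in ", path)
  }
  if (orientation == "genes_by_spots") m <- t(m)
  colnames(m) <- make.unique(colnames(m))
  rownames(m) <- make.unique(rownames(m))
  expression_matrix(m)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]: dense CSV/TSV round-trips values
#' exactly (full precision), `mtx` writes a MatrixMarket file plus
#' `.rownames` / `.colnames` companions.
#'
#' @inheritParams read_expression
#' @param expr an [expression_matrix()].
#' @export
write_expression <- function(expr, path, fmt = c("csv", "tsv", "mtx")) {
  fmt <- match.arg(fmt)
  expr <- expression_matrix(unclass_expr(expr))
  if (fmt == "mtx") {
    Matrix::writeMM(Matrix::Matrix(unclass_expr(expr), sparse = TRUE), path)
    writeLines(rownames(expr), paste0(path, ".rownames"))
    writeLines(colnames(expr), paste0(path, ".colnames"))
  } else {
    sep <- if (fmt == "csv") "," else "\t"
    df <- as.data.frame(unclass_expr(expr))
    write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                path, sep = sep, quote = FALSE, col.names = NA)
  }
  invisible(path)
}

#' Read per-spot labels from a two-column TSV (row_id, label)
#' @param path TSV path with a header line.
#' @return named character vector of labels (names = row ids).
#' @export
read_labels <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("labels file must have two columns (row_id, label)")
  stats::setNames(df[[2]], df[[1]])
}

#' Read spot coordinates from a three-column TSV (row_id, x, y)
#' @param path TSV path with a header line.
#' @return numeric n x 2 matrix with row ids as rownames.
#' @export
read_coords <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (ncol(df) < 3) stop("coordinates file must have columns row_id, x, y")
  m <- as.matrix(df[, 2:3])
  if (!all(is.finite(m))) stop("non-finite coordinates in ", path)
  rownames(m) <- as.character(df[[1]])
  colnames(m) <- c("x", "y")
  m
}

#' Preprocess an expression matrix
#'
#' Standard scRNA-seq recipe: library-size normalize each spot to the
#' median total count, `log1p`-transform, keep the `n_hvg` genes with
#' the largest log-scale variance (output columns in HVG ranking
#' order), then center and unit-scale each gene. Genes with zero
#' variance after subsetting are dropped with a warning. With
#' `normalize = FALSE` the library-size/log steps are skipped (input
#' already normalized); HVG selection and scaling still run.
#'
#' @param expr an [expression_matrix()]; raw nonnegative counts when
#'   `normalize = TRUE`.
#' @param n_hvg number of highly variable genes to keep (default 2000,
#'   capped at the gene count).
#' @param normalize logical; apply library-size + log1p normalization.
#' @param scale logical; center/unit-scale genes after HVG selection.
#' @return processed [expression_matrix()].
#' @export
preprocess <- function(expr, n_hvg = 2000, normalize = TRUE, scale = TRUE) {
  x <- unclass_expr(expression_matrix(unclass_expr(expr)))
  if (normalize) {
    tot <- rowSums(x)
    if (any(tot <= 0))
      stop("rows with zero total count: ",
           paste(rownames(x)[tot <= 0], collapse = ", "))
    x <- log1p(x / tot * stats::median(tot))
  }
  v <- apply(x, 2, stats::var)
  n_hvg <- min(n_hvg, ncol(x))
  # rank on 10 significant digits so float noise cannot reorder tied genes
  keep <- order(-signif(v, 10), seq_along(v))[seq_len(n_hvg)]
  keep <- keep[v[keep] > 0]
  if (length(keep) < n_hvg)
    warning("dropped ", n_hvg - length(keep), " zero-variance gene(s)")
  x <- x[, keep, drop = FALSE]
  if (scale) {
    x <- base::scale(x)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
  }
  expression_matrix(x)
}

#' Align source samples to the target gene space and combine them
#'
#' Each labeled source sample is subset to `target_genes` (genes the
#' source lacks become all-zero columns, recorded in the report),
#' normalized independently (library-size + log1p when `normalize`,
#' then per-gene center/scale; constant genes are left at zero), and
#' the rows are concatenated. Label codes from all sources are
#' re-indexed into a shared `1..K` space by label-string identity
#' (sorted order).
#'
#' @param sources list of [labeled_source()] objects.
#' @param target_genes character vector of target gene ids (defines the
#'   output gene space and order).
#' @param q latent dimension the downstream factor model will use; each
#'   source must share at least `q` genes with the target.
#' @param normalize logical, passed to the per-source normalization.
#' @return a [labeled_source()] whose `expr` has exactly the target
#'   genes, plus attribute `missing_genes` (per-source list of
#'   zero-filled gene names).
#' @export
align_and_combine_sources <- function(sources, target_genes, q = 15,
                                      normalize = TRUE) {
  if (inherits(sources, "labeled_source")) sources <- list(sources)
  stopifnot(length(sources) >= 1)
  missing_report <- vector("list", length(sources))
  blocks <- vector("list", length(sources))
  labels <- character(0)
  for (s in seq_along(sources)) {
    src <- sources[[s]]
    stopifnot(inherits(src, "labeled_source"))
    x <- unclass_expr(src$expr)
    shared <- intersect(target_genes, colnames(x))
    if (length(shared) < q)
      stop("source ", s, " shares only ", length(shared),
           " genes with the target (need at least q = ", q, ")")
    out <- matrix(0, nrow(x), length(target_genes),
                  dimnames = list(rownames(x), target_genes))
    out[, shared] <- x[, shared]
    missing_report[[s]] <- setdiff(target_genes, colnames(x))
    if (normalize) {
      tot <- rowSums(pmax(out, 0))
      if (all(tot > 0)) out <- log1p(out / tot * stats::median(tot))
    }
    mu <- colMeans(out)
    sdev <- apply(out, 2, stats::sd)
    out <- sweep(out, 2, mu, "-")
    nz <- sdev > 0
    out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sdev[nz], "/")
    out[, !nz] <- 0
    blocks[[s]] <- out
    labels <- c(labels, src$label_levels[src$labels])
  }
  combined <- do.call(rbind, blocks)
  rownames(combined) <- make.unique(rownames(combined))
  res <- labeled_source(expression_matrix(combined), labels)
  attr(res, "missing_genes") <- missing_report
  res
}

#' @export
print.labeled_source <- function(x, ...) {
  cat("labeled_source:", nrow(x$expr), "spots x", ncol(x$expr), "genes,",
      length(x$label_levels), "classes\n")
  invisible(x)
}
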