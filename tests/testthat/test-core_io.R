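test_that("dense and sparse readers round-trip values and orientation", {
  x <- matrix(c(1, 0, 3, 2.5, 0, 7), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("g1", "g2")))
  em <- expression_matrix(x)

  f <- tempfile(fileext = ".csv")
  write_expression(em, f, fmt = "csv")
  back <- read_expression(f, fmt = "csv")
  expect_identical(unclass(back)[, ], unclass(em)[, ])

  f2 <- tempfile(fileext = ".mtx")
  write_expression(em, f2, fmt = "mtx")
  back2 <- read_expression(f2, fmt = "mtx")
  expect_equal(unclass(back2)[, ], unclass(em)[, ])

  # genes-by-spots on disk comes back transposed to spots-by-genes
  tf <- tempfile(fileext = ".csv")
  write_expression(expression_matrix(t(x)), tf, fmt = "csv")
  back3 <- read_expression(tf, fmt = "csv", orientation = "genes_by_spots")
  expect_equal(dim(back3), dim(x))
  expect_equal(unclass(back3)[, ], unclass(em)[, ])
})

test_that("duplicate gene names are disambiguated and bad inputs error", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(",ACTB,ACTB", "s1,1,2", "s2,3,4"), f)
  em <- read_expression(f, fmt = "csv")
  expect_identical(colnames(em), c("ACTB", "ACTB.1"))

  expect_error(read_expression(tempfile(), fmt = "csv"), "not found")
  f3 <- tempfile(fileext = ".mtx")
  write_expression(expression_matrix(matrix(1:4, 2)), f3, fmt = "mtx")
  writeLines("only_one_name", paste0(f3, ".rownames"))
  expect_error(read_expression(f3, fmt = "mtx"), "dimension mismatch")
})

test_that("preprocess follows the documented recipe", {
  set.seed(42)
  counts <- matrix(rpois(50 * 20, 5), 50, 20)
  counts[, 7] <- rpois(50, 5) * sample(c(1, 40), 50, replace = TRUE)
  em <- expression_matrix(counts)

  out <- preprocess(em, n_hvg = 20)
  expect_equal(ncol(out), 20)
  # the overdispersed gene ranks first among HVGs (oracle: direct
  # log-scale variance computation)
  tot <- rowSums(counts)
  logn <- log1p(counts / tot * median(tot))
  expect_identical(colnames(out)[1], colnames(em)[which.max(apply(logn, 2, var))])
  expect_identical(colnames(out)[1], colnames(em)[7])
  # per-gene standardization
  expect_equal(unname(colMeans(out)), rep(0, 20), tolerance = 1e-12)
  expect_equal(unname(apply(out, 2, sd)), rep(1, 20), tolerance = 1e-12)

  # top-n_hvg subsetting
  out5 <- preprocess(em, n_hvg = 5)
  expect_equal(ncol(out5), 5)

  # degenerate all-equal counts: variance-0 genes dropped, never NaN
  flat <- expression_matrix(matrix(3, 10, 4))
  res <- suppressWarnings(preprocess(flat, n_hvg = 4))
  expect_equal(ncol(res), 0)
  expect_false(anyNA(res))

  # zero-count row is an error naming the row
  bad <- expression_matrix(rbind(counts, 0))
  expect_error(preprocess(bad), rownames(bad)[51])
})

test_that("preprocess is idempotent on its own output", {
  set.seed(7)
  em <- expression_matrix(matrix(rpois(200, 8), 20, 10))
  once <- preprocess(em, n_hvg = 10)
  twice <- preprocess(once, n_hvg = 10, normalize = FALSE)
  expect_equal(unclass(twice)[, ], unclass(once)[, ], tolerance = 1e-10)
})

test_that("source alignment subsets, zero-fills, re-indexes and stacks", {
  set.seed(1)
  tg <- paste0("g", 1:20)
  s1 <- labeled_source(
    expression_matrix(matrix(rpois(10 * 20, 6), 10, 20,
                             dimnames = list(NULL, tg))),
    rep(c("A", "B"), 5))
  s2 <- labeled_source(
    expression_matrix(matrix(rpois(8 * 15, 6), 8, 15,
                             dimnames = list(NULL, tg[1:15]))),
    rep("C", 8))

  comb <- align_and_combine_sources(list(s1, s2), tg, q = 5)
  expect_equal(nrow(comb$expr), 18)                 # row counts add
  expect_equal(colnames(comb$expr), tg)             # exactly target genes
  # disjoint vocabularies {A,B} and {C} -> shared codes {1,2,3}
  expect_identical(comb$label_levels, c("A", "B", "C"))
  expect_identical(sort(unique(comb$labels)), 1:3)
  # genes missing from source 2 are zero-filled and reported
  expect_identical(attr(comb, "missing_genes")[[2]], tg[16:20])
  expect_true(all(unclass(comb$expr)[11:18, 16:20] == 0))

  # single source already on the target genes: labels pass through
  solo <- align_and_combine_sources(list(s1), tg, q = 5)
  expect_equal(solo$labels, s1$labels)

  expect_error(align_and_combine_sources(list(s2), paste0("g", 14:20), q = 5),
               "shares only")
})

test_that("label and coordinate readers parse the documented TSV layouts", {
  f <- tempfile()
  writeLines(c("row_id\tlabel", "s1\tA", "s2\tB"), f)
  lab <- read_labels(f)
  expect_identical(lab, c(s1 = "A", s2 = "B"))

  f2 <- tempfile()
  writeLines(c("row_id\tx\ty", "s1\t1.5\t2", "s2\t3\t4"), f2)
  co <- read_coords(f2)
  expect_equal(co, matrix(c(1.5, 3, 2, 4), 2,
                          dimnames = list(c("s1", "s2"), c("x", "y"))))
})
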