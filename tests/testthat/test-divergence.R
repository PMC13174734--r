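make_sce <- function(counts, cell_type, condition) {
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(cell_type = cell_type, condition = condition,
                                   row.names = colnames(counts))
  )
}

test_that("normalisation is CP10K + log1p, depth-invariant, and drops empty cells", {
  counts <- matrix(0, 4, 3, dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  counts[2, 1] <- 7                  # a cell with all mass on one gene
  counts[, 2] <- c(1, 2, 3, 4)
  counts[, 3] <- c(2, 4, 6, 8)       # proportional to cell 2
  ds <- make_sce(counts, rep("ct1", 3), c("control", "treated", "treated"))
  ds <- normalize_cells(ds)
  ln <- as.matrix(SummarizedExperiment::assay(ds, "logcounts"))
  expect_equal(ln[2, 1], log(1 + 10000))
  expect_equal(ln[, 2], ln[, 3])

  # loop oracle on a seeded matrix
  set.seed(71)
  m <- matrix(rpois(100 * 50, 2), 100, dimnames = list(sprintf("g%03d", 1:100),
                                                       sprintf("c%02d", 1:50)))
  ds2 <- normalize_cells(make_sce(m, rep("a", 50), rep(c("control", "treated"), 25)))
  ln2 <- as.matrix(SummarizedExperiment::assay(ds2, "logcounts"))
  for (j in c(1, 17, 50)) {
    expect_equal(ln2[, j], log1p(m[, j] / sum(m[, j]) * 1e4), tolerance = 1e-12)
  }

  # zero-count cell dropped and tallied; all-zero refused
  m0 <- m; m0[, 5] <- 0
  expect_message(ds3 <- normalize_cells(make_sce(m0, rep("a", 50),
                                                 rep("control", 50))),
                 "dropping 1")
  expect_equal(ncol(ds3), 49L)
  expect_equal(S4Vectors::metadata(ds3)$n_dropped_zero_cells, 1L)
  expect_error(normalize_cells(make_sce(matrix(0, 3, 2,
                                               dimnames = list(letters[1:3], c("x", "y"))),
                                        c("a", "a"), c("control", "treated"))),
               "zero total counts")
})

test_that("group centroids are stratum means", {
  counts <- cbind(c1 = c(2, 0, 4), c2 = c(0, 6, 2), c3 = c(1, 1, 1))
  rownames(counts) <- paste0("g", 1:3)
  ds <- make_sce(counts, c("ct1", "ct1", "ct2"),
                 c("control", "control", "treated"))
  ds <- normalize_cells(ds)
  ln <- as.matrix(SummarizedExperiment::assay(ds, "logcounts"))
  expect_equal(group_centroid(ds, "ct1", "control"), rowMeans(ln[, 1:2]))
  expect_equal(group_centroid(ds, "ct2", "treated"), ln[, 3])
  expect_error(group_centroid(ds, "ct2", "control"), "empty stratum")
})

test_that("euclidean distance is the 3-4-5 metric", {
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_error(euclidean_distance(1:3, 1:4), "length mismatch")
  set.seed(81)
  a <- rnorm(2000); b <- rnorm(2000)
  s <- 0; for (i in 1:2000) s <- s + (a[i] - b[i])^2
  expect_equal(euclidean_distance(a, b), sqrt(s), tolerance = 1e-10)
})

test_that("permutation null agrees with a naive centroid-resampling loop", {
  ds <- normalize_cells(small_cells(seed = 91, lfc = 0.4, n_types = 1L,
                                    n_per_cond = 25L, n_genes = 60L))
  pn <- permutation_null(ds, "ct1", n_perm = 100, seed = 13)
  # observed statistic equals the explicit centroid distance
  d_direct <- euclidean_distance(group_centroid(ds, "ct1", "control"),
                                 group_centroid(ds, "ct1", "treated"))
  expect_equal(pn$observed_d, d_direct, tolerance = 1e-10)
  # null draws match a naive re-implementation consuming the same RNG stream
  X <- as.matrix(SummarizedExperiment::assay(ds, "logcounts"))
  n <- ncol(X); n_a <- pn$n_a
  set.seed(13)
  naive <- vapply(1:100, function(k) {
    idx <- sample.int(n, n_a)
    euclidean_distance(rowMeans(X[, idx, drop = FALSE]),
                       rowMeans(X[, -idx, drop = FALSE]))
  }, numeric(1))
  expect_equal(pn$null, naive, tolerance = 1e-10)
  expect_equal(pn$empirical_p, (1 + sum(naive >= pn$observed_d)) / 101,
               tolerance = 1e-12)
})

test_that("an overwhelming shift attains the pseudocount floor 1/(n_perm+1)", {
  ds <- normalize_cells(small_cells(seed = 92, lfc = 3, n_types = 1L,
                                    n_per_cond = 40L, n_genes = 80L))
  pn <- permutation_null(ds, "ct1", n_perm = 999, seed = 5)
  expect_equal(pn$empirical_p, 0.001)
  expect_error(permutation_null(ds, "ct1", n_perm = 50), ">= 100")
  expect_error(permutation_null(ds, "ct9", n_perm = 100), "unknown cell type")
  # a single condition level is refused
  ds2 <- ds[, ds$condition == "control"]
  expect_error(permutation_null(ds2, "ct1", n_perm = 100), "2 condition levels")
})

test_that("the scan filters small cell types, sorts, and Bonferroni-corrects", {
  sp <- cell_spec(cell_types = data.frame(name = c("big1", "big2", "tiny"),
                                          n_cells_per_condition = c(80L, 80L, 10L)),
                  n_genes = 100L,
                  planted_shift = list(cell_type = "big1",
                                       n_affected_genes = 30L,
                                       log_fold_change = 1),
                  seed = 93)
  ds <- normalize_cells(generate_cells(sp))
  expect_message(sc <- run_divergence_scan(ds, min_cells = 100L, n_perm = 199,
                                           seed = 3),
                 "excluding 1 cell type")
  expect_setequal(sc$cell_type, c("big1", "big2"))
  expect_identical(attr(sc, "excluded"), c(tiny = 20L))
  expect_true(all(sc$n_cells_total >= 100L))
  expect_equal(sc$adj_p, pmin(1, sc$empirical_p * 2))
  expect_identical(sc$cell_type[1], "big1") # the shifted type leads
  expect_true(all(diff(sc$observed_d) <= 0))
  # K = 1: Bonferroni is the identity
  sc1 <- run_divergence_scan(ds[, ds$cell_type == "big2"], min_cells = 100L,
                             n_perm = 199, seed = 3)
  expect_equal(sc1$adj_p, sc1$empirical_p)
  expect_error(suppressMessages(
    run_divergence_scan(ds, min_cells = 10000L, n_perm = 199)),
    "no cell type passes")
})

test_that("scan results are reproducible under a fixed seed", {
  ds <- normalize_cells(small_cells(seed = 94, lfc = 0.5))
  a <- run_divergence_scan(ds, min_cells = 100L, n_perm = 199, seed = 17)
  b <- run_divergence_scan(ds, min_cells = 100L, n_perm = 199, seed = 17)
  expect_identical(a, b)
})

test_that("detection rate is non-decreasing in the planted fold change", {
  deltas <- c(0.1, 0.25, 0.5)
  n_seeds <- 8L
  detect <- vapply(deltas, function(d) {
    hits <- 0L
    for (s in seq_len(n_seeds)) {
      ds <- normalize_cells(small_cells(seed = 300 + s, lfc = d,
                                        n_types = 2L, n_per_cond = 60L,
                                        n_genes = 150L))
      sc <- run_divergence_scan(ds, min_cells = 100L, n_perm = 199,
                                seed = s)
      hits <- hits + (sc$cell_type[1] == "ct1" && sc$adj_p[1] <= 0.05)
    }
    hits / n_seeds
  }, numeric(1))
  expect_true(all(diff(detect) >= 0))
})
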