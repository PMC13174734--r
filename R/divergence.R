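#' Library-size normalise single-cell counts
#'
#' Per cell: scale counts to `scale_factor` total (counts-per-10,000 by
#' default), then `log1p` — the Seurat-default-equivalent normalisation.
#' Cells with zero total counts cannot be normalised and are dropped with a
#' logged tally (recorded in `metadata(ds)$n_dropped_zero_cells`).
#'
#' @param ds A [SingleCellExperiment::SingleCellExperiment] with a
#'   `"counts"` assay (genes x cells, sparse or dense, non-negative).
#' @param scale_factor Target total per cell; default `1e4`.
#' @return The dataset with a `"logcounts"` assay added (zero-count cells
#'   removed).
#' @export
normalize_cells <- function(ds, scale_factor = 1e4) {
  counts <- SummarizedExperiment::assay(ds, "counts")
  neg <- if (methods::is(counts, "sparseMatrix")) any(counts@x < 0) else any(counts < 0)
  if (neg) stop("negative counts")
  totals <- Matrix::colSums(counts)
  if (all(totals == 0)) stop("all cells have zero total counts")
  n_zero <- sum(totals == 0)
  if (n_zero > 0) {
    message("normalize_cells: dropping ", n_zero, " zero-count cell(s)")
    ds <- ds[, totals > 0]
    counts <- SummarizedExperiment::assay(ds, "counts")
    totals <- totals[totals > 0]
  }
  norm <- counts
  if (methods::is(norm, "dgCMatrix")) {
    # scale the nonzero entries column-wise without densifying
    norm@x <- norm@x * rep.int(scale_factor / totals, diff(norm@p))
    norm@x <- log1p(norm@x)
  } else {
    norm <- log1p(sweep(as.matrix(norm), 2, totals / scale_factor, "/"))
  }
  SummarizedExperiment::assay(ds, "logcounts") <- norm
  S4Vectors::metadata(ds)$n_dropped_zero_cells <- n_zero
  ds
}

.cell_type_of <- function(ds) {
  ct <- SummarizedExperiment::colData(ds)$cell_type
  if (is.null(ct)) stop("colData lacks a 'cell_type' column")
  as.character(ct)
}

.condition_of <- function(ds) {
  cond <- SummarizedExperiment::colData(ds)$condition
  if (is.null(cond)) stop("colData lacks a 'condition' column")
  as.character(cond)
}

#' Per-gene mean expression of one cell-type/condition stratum
#'
#' The centroid (arithmetic mean per gene) of all cells of the given cell
#' type in the given condition — the pseudobulk profile the divergence
#' statistic compares between conditions.
#'
#' @param ds A `SingleCellExperiment` with `cell_type` and `condition`
#'   columns in its `colData`.
#' @param cell_type,condition Labels selecting the stratum.
#' @param assay Assay to average; default `"logcounts"`.
#' @return Named numeric vector over genes.
#' @export
group_centroid <- function(ds, cell_type, condition, assay = "logcounts") {
  sel <- .cell_type_of(ds) == cell_type & .condition_of(ds) == condition
  if (!any(sel)) {
    stop("empty stratum: cell_type '", cell_type, "', condition '", condition, "'")
  }
  m <- SummarizedExperiment::assay(ds, assay)[, sel, drop = FALSE]
  Matrix::rowMeans(m)
}

#' Euclidean distance between two expression vectors
#'
#' @param a,b Numeric vectors of equal length (e.g. two centroids over the
#'   same genes).
#' @return `sqrt(sum((a - b)^2))`.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("length mismatch: ", length(a), " vs ", length(b))
  }
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' Permutation null for one cell type's centroid divergence
#'
#' The observed statistic is the Euclidean distance between the two
#' condition centroids within one cell type. The null is built by randomly
#' re-partitioning that cell type's cells into two pseudo-groups of the
#' same sizes as the observed condition groups (a size-preserving label
#' permutation) and recomputing the centroid distance, `n_perm` times.
#' The empirical p-value is `(1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' Internally all permutations are evaluated with one matrix product
#' (genes x cells times a cells x n_perm group-indicator matrix), so the
#' default 1000 permutations are cheap even for large cell types.
#'
#' @param ds A `SingleCellExperiment` with exactly two condition levels.
#' @param cell_type Cell type to test.
#' @param n_perm Number of permutations, `>= 100`; default `1000`.
#' @param seed Integer seed for reproducible null draws.
#' @param assay Assay used for the centroids; default `"logcounts"`.
#' @return A list: `observed_d`, `null` (numeric vector, length `n_perm`),
#'   `empirical_p`, `n_a`, `n_b`.
#' @export
permutation_null <- function(ds, cell_type, n_perm = 1000L, seed = NULL,
                             assay = "logcounts") {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  ct <- .cell_type_of(ds); cond <- .condition_of(ds)
  levels_ <- sort(unique(cond))
  if (length(levels_) != 2L) stop("need exactly 2 condition levels, found ", length(levels_))
  sel <- ct == cell_type
  if (!any(sel)) stop("unknown cell type: ", cell_type)
  grp <- cond[sel]
  n_a <- sum(grp == levels_[1]); n_b <- sum(grp == levels_[2])
  if (n_a == 0L || n_b == 0L) {
    stop("cell type '", cell_type, "' has an empty condition stratum")
  }
  X <- as.matrix(SummarizedExperiment::assay(ds, assay)[, sel, drop = FALSE])
  n <- n_a + n_b
  tot <- rowSums(X)
  # d = || s_A * (1/n_a + 1/n_b) - tot / n_b ||, with s_A the group-A row sums
  dist_from_sa <- function(SA) {
    sqrt(colSums((SA * (1 / n_a + 1 / n_b) - tot / n_b)^2))
  }
  observed_d <- dist_from_sa(cbind(rowSums(X[, grp == levels_[1], drop = FALSE])))
  if (!is.null(seed)) set.seed(seed)
  P <- matrix(0, nrow = n, ncol = n_perm)
  for (k in seq_len(n_perm)) P[sample.int(n, n_a), k] <- 1
  null <- dist_from_sa(X %*% P)
  list(observed_d = as.numeric(observed_d), null = null,
       empirical_p = (1 + sum(null >= observed_d)) / (1 + n_perm),
       n_a = n_a, n_b = n_b)
}

#' Per-cell-type transcriptional divergence scan
#'
#' Quantifies, for every sufficiently large cell type, how far the whole
#' transcriptome shifted between the two conditions: the observed centroid
#' Euclidean distance is compared against a size-preserving permutation
#' null ([permutation_null()]), and empirical p-values are
#' Bonferroni-corrected across the retained cell types. Cell types with
#' fewer than `min_cells` total cells across conditions are excluded (and
#' logged) before testing, so the correction family is the retained set.
#'
#' @param ds A `SingleCellExperiment` with `cell_type` and `condition`
#'   columns and (unless `assay` says otherwise) a `"logcounts"` assay —
#'   see [normalize_cells()].
#' @param min_cells Minimum total cells per cell type; default `1000`.
#' @param n_perm Permutations per cell type; default `1000`.
#' @param seed Integer seed; the scan iterates cell types in sorted order,
#'   so a fixed seed reproduces every null draw.
#' @param assay Assay for the centroids; default `"logcounts"`.
#' @return A `data.frame` with one row per retained cell type — columns
#'   `cell_type`, `n_cells_total`, `n_cells_a`, `n_cells_b`, `observed_d`,
#'   `null_mean`, `null_sd`, `empirical_p`, `adj_p` — sorted by
#'   `observed_d` descending. Attribute `"excluded"`: named integer vector
#'   of cell counts for the cell types below `min_cells`.
#' @export
run_divergence_scan <- function(ds, min_cells = 1000L, n_perm = 1000L,
                                seed = NULL, assay = "logcounts") {
  ct <- .cell_type_of(ds)
  cond <- .condition_of(ds)
  if (length(unique(cond)) != 2L) {
    stop("need exactly 2 condition levels, found ", length(unique(cond)))
  }
  counts_by_type <- table(ct)
  retained <- sort(names(counts_by_type)[counts_by_type >= min_cells])
  excluded <- counts_by_type[setdiff(names(counts_by_type), retained)]
  if (length(excluded) > 0) {
    message("run_divergence_scan: excluding ", length(excluded),
            " cell type(s) below ", min_cells, " cells: ",
            paste0(names(excluded), " (", as.integer(excluded), ")", collapse = ", "))
  }
  if (length(retained) == 0L) stop("no cell type passes the min_cells filter")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(retained, function(tct) {
    pn <- permutation_null(ds, tct, n_perm = n_perm, seed = NULL, assay = assay)
    data.frame(cell_type = tct,
               n_cells_total = pn$n_a + pn$n_b,
               n_cells_a = pn$n_a, n_cells_b = pn$n_b,
               observed_d = pn$observed_d,
               null_mean = mean(pn$null), null_sd = stats::sd(pn$null),
               empirical_p = pn$empirical_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- pmin(1, out$empirical_p * length(retained))
  out <- out[order(-out$observed_d, out$cell_type), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- stats::setNames(as.integer(excluded), names(excluded))
  out
}
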