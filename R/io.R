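#' Read a genes x samples expression matrix from TSV
#'
#' Expected layout: header row of sample IDs, first column gene IDs,
#' tab-separated, UTF-8. Empty cells become missing values; any other
#' non-numeric cell is an error naming the offending gene row. Duplicate
#' gene or sample IDs are refused by name.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE,
                          na.strings = c("", "NA"))
  if (ncol(dt) < 2L) stop("malformed header: need gene column plus >= 1 sample")
  gene_ids <- dt[[1]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop("duplicate gene IDs: ", paste(dup, collapse = ", "))
  }
  sample_ids <- colnames(dt)[-1]
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  vals <- dt[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    # fread left a column character: find the first non-numeric cell
    for (j in which(bad)) {
      col <- vals[[j]]
      nn <- suppressWarnings(as.numeric(col))
      row <- which(is.na(nn) & !is.na(col))[1]
      stop("non-numeric value '", col[row], "' for gene ", gene_ids[row],
           " (line ", row + 1L, ", sample ", sample_ids[j], ")")
    }
  }
  m <- as.matrix(vals)
  dimnames(m) <- list(gene_ids, sample_ids)
  m
}

#' Write a genes x samples expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]; round-trips exactly (values are
#' written with full precision; missing values as empty cells).
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  dt <- data.table::data.table(gene = rownames(m))
  for (j in colnames(m)) {
    # %.17g round-trips doubles exactly; empty cell encodes missing
    col <- sprintf("%.17g", m[, j])
    col[is.na(m[, j])] <- ""
    dt[[j]] <- col
  }
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a secreted-gene list
#'
#' One gene symbol per line; `#` starts a comment (whole-line or trailing);
#' blank lines ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of unique symbols, in file order.
#' @export
read_secretome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}

#' Write a secreted-gene list
#' @param symbols Character vector of gene symbols.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_secretome <- function(symbols, path) {
  writeLines(as.character(symbols), path)
  invisible(path)
}

#' Assemble a single-cell dataset from MatrixMarket + sidecar files
#'
#' Reads a coordinate-format `.mtx` counts matrix with its features
#' (genes) and barcodes files plus a cell-metadata TSV carrying `barcode`,
#' `cell_type` and `condition` columns. The orientation flag says which
#' axis of the matrix is genes; the returned object is always genes x
#' cells.
#'
#' @param mtx,features,barcodes Paths to the MatrixMarket file and the
#'   one-ID-per-line feature and barcode files.
#' @param meta Path to the metadata TSV.
#' @param orientation `"genes_by_cells"` (default) or `"cells_by_genes"`.
#' @return A [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `"counts"` assay and `colData` columns `cell_type`, `condition`.
#' @export
read_mtx_dataset <- function(mtx, features, barcodes, meta,
                             orientation = c("genes_by_cells", "cells_by_genes")) {
  orientation <- match.arg(orientation)
  for (f in c(mtx, features, barcodes, meta)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  if (orientation == "cells_by_genes") m <- Matrix::t(m)
  gene_ids <- readLines(features)
  cell_ids <- readLines(barcodes)
  if (nrow(m) != length(gene_ids)) {
    stop("dimension mismatch: matrix has ", nrow(m), " gene rows but ",
         length(gene_ids), " features listed")
  }
  if (ncol(m) != length(cell_ids)) {
    stop("dimension mismatch: matrix has ", ncol(m), " cell columns but ",
         length(cell_ids), " barcodes listed")
  }
  if (any(m@x < 0)) stop("negative counts in ", mtx)
  md <- data.table::fread(meta, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("barcode", "cell_type", "condition")
  if (!all(need %in% colnames(md))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  missing_bc <- setdiff(cell_ids, md$barcode)
  if (length(missing_bc)) {
    stop("barcode(s) missing from metadata: ",
         paste(utils::head(missing_bc, 5), collapse = ", "))
  }
  md <- md[match(cell_ids, md$barcode), , drop = FALSE]
  dimnames(m) <- list(gene_ids, cell_ids)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(cell_type = as.character(md$cell_type),
                                   condition = as.character(md$condition),
                                   row.names = cell_ids)
  )
}

#' Write a single-cell dataset as MatrixMarket + sidecar files
#'
#' Inverse of [read_mtx_dataset()] (genes x cells orientation): writes
#' `matrix.mtx`, `features.tsv`, `barcodes.tsv` and `metadata.tsv` into
#' `dir`.
#'
#' @param ds A `SingleCellExperiment` with a `"counts"` assay and
#'   `cell_type`/`condition` in `colData`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_mtx_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- SummarizedExperiment::assay(ds, "counts")
  paths <- c(mtx = file.path(dir, "matrix.mtx"),
             features = file.path(dir, "features.tsv"),
             barcodes = file.path(dir, "barcodes.tsv"),
             meta = file.path(dir, "metadata.tsv"))
  Matrix::writeMM(methods::as(counts, "generalMatrix"), paths["mtx"])
  writeLines(rownames(counts), paths["features"])
  writeLines(colnames(counts), paths["barcodes"])
  md <- data.frame(barcode = colnames(counts),
                   cell_type = .cell_type_of(ds),
                   condition = .condition_of(ds),
                   stringsAsFactors = FALSE)
  data.table::fwrite(md, paths["meta"], sep = "\t", quote = FALSE)
  invisible(paths)
}

#' Write a run manifest
#'
#' Every pipeline run records the configuration, seed, package version and
#' any skipped-item tallies as JSON, sufficient to reproduce the run.
#'
#' @param path Output path for the JSON file.
#' @param config Named list of configuration values (paths, thresholds,
#'   seed, ...).
#' @param tallies Named list/vector of skipped-gene or skipped-cell
#'   counts; optional.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, tallies = list()) {
  manifest <- list(
    package = "crossmed",
    version = as.character(utils::packageVersion("crossmed")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config,
    tallies = as.list(tallies)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
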