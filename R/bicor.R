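#' Median absolute deviation (unscaled)
#'
#' Median of absolute deviations from the median, without the 1.4826
#' normal-consistency factor. This is the raw MAD used inside the biweight
#' midcorrelation weights, where only the relative scale matters.
#'
#' @param x Numeric vector with at least one finite value.
#' @return A single non-negative number.
#' @examples
#' mad_raw(c(1, 2, 3, 4, 5)) # 1
#' @export
mad_raw <- function(x) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("empty input")
  stats::median(abs(x - stats::median(x)))
}

#' Biweight transform of a numeric vector
#'
#' Centres `x` at its median and downweights points by Tukey's biweight:
#' with `m = median(x)`, `u_i = (x_i - m) / (9 * mad_raw(x))` and
#' `w_i = (1 - u_i^2)^2 * I(|u_i| < 1)`, returns `(x_i - m) * w_i`.
#' Points further than 9 raw MADs from the median get weight zero, which is
#' what makes the midcorrelation resistant to single-sample outliers.
#'
#' @param x Numeric vector; must have strictly positive `mad_raw(x)`.
#' @return Numeric vector of the same length as `x`.
#' @seealso [bicor()]
#' @export
biweight_transform <- function(x) {
  x <- as.numeric(x)
  m <- mad_raw(x)
  if (m == 0) {
    stop("zero MAD: bicor undefined for (near-)constant vector")
  }
  med <- stats::median(x, na.rm = TRUE)
  u <- (x - med) / (9 * m)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - med) * w
}

.check_n <- function(n) {
  if (n < 5L) stop("need at least 5 paired observations, got ", n)
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation in which the usual mean/SD centring of Pearson's r is
#' replaced by median/MAD-based biweight downweighting (see
#' [biweight_transform()]). Missing values are removed pairwise-complete;
#' at least 5 complete pairs are required. Vectors whose raw MAD is zero
#' (constant or majority-constant) are refused rather than silently falling
#' back to Pearson, so degenerate genes surface as errors, not as numbers.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The correlation, a number in `[-1, 1]`, with attribute `"n"`
#'   giving the number of complete pairs used.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- x + rnorm(50)
#' bicor(x, y)
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y))
  }
  ok <- is.finite(x) & is.finite(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  .check_n(n)
  xt <- biweight_transform(x)
  yt <- biweight_transform(y)
  r <- sum(xt * yt) / (sqrt(sum(xt^2)) * sqrt(sum(yt^2)))
  r <- max(-1, min(1, r))
  attr(r, "n") <- n
  r
}

#' Two-sided p-value for a correlation coefficient
#'
#' Student-t approximation with `n - 2` degrees of freedom:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`. This is the convention of the
#' WGCNA ecosystem for biweight midcorrelation p-values. `r = +/-1`
#' returns `p = 0`.
#'
#' @param r Correlation value(s) in `[-1, 1]` (vectorised).
#' @param n Number of paired observations, `>= 5`.
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @export
corr_pvalue <- function(r, n) {
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12)) {
    stop("correlation out of [-1, 1]")
  }
  r <- pmax(-1, pmin(1, r))
  .check_n(n)
  p <- rep(0, length(r))
  inner <- abs(r) < 1
  tstat <- r[inner] * sqrt(n - 2) / sqrt(1 - r[inner]^2)
  p[inner] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p
}

# Row-wise biweight transform for a complete (no-NA) matrix.
# Returns list(xt = transformed matrix over admissible rows, admissible =
# logical per input row). Rows with zero raw MAD are inadmissible.
.biweight_transform_rows <- function(M) {
  med <- apply(M, 1L, stats::median)
  madv <- apply(abs(M - med), 1L, stats::median)
  admissible <- madv > 0
  Ma <- M[admissible, , drop = FALSE]
  u <- (Ma - med[admissible]) / (9 * madv[admissible])
  w <- (1 - u^2)^2 * (abs(u) < 1)
  list(xt = (Ma - med[admissible]) * w, admissible = admissible)
}

#' Biweight midcorrelation of one vector against every row of a matrix
#'
#' Correlates `x` (e.g. one origin-tissue gene) with every gene (row) of a
#' panel matrix over the shared samples, returning r and the Student-t
#' p-value per gene. Target genes that fail the admissibility checks
#' (zero MAD, fewer than 5 complete pairs) are skipped and tallied, never
#' silently dropped.
#'
#' @param x Named numeric vector (names are sample IDs) or unnamed vector
#'   already aligned to `M`'s columns.
#' @param M Numeric matrix, genes x samples, with rownames (gene IDs) and
#'   colnames (sample IDs).
#' @return A `data.frame` with columns `gene`, `r`, `p`, `n`, one row per
#'   retained target gene (in `M`'s row order), with attribute `"skipped"`:
#'   a named integer tally of skip reasons.
#' @export
bicor_vs_matrix <- function(x, M) {
  stopifnot(is.matrix(M), !is.null(rownames(M)))
  if (!is.null(names(x)) && !is.null(colnames(M))) {
    shared <- intersect(names(x), colnames(M))
    if (length(shared) == 0L) stop("no sample overlap")
    x <- x[shared]
    M <- M[, shared, drop = FALSE]
  } else if (length(x) != ncol(M)) {
    stop("length mismatch: x has ", length(x), " samples, M has ", ncol(M))
  }
  skipped <- c(zero_mad = 0L, too_few_pairs = 0L)

  if (all(is.finite(x)) && !anyNA(M)) { # fast vectorised path
    n <- length(x)
    .check_n(n)
    xt <- biweight_transform(as.numeric(x))
    tr <- .biweight_transform_rows(M)
    skipped["zero_mad"] <- sum(!tr$admissible)
    r <- as.numeric(tr$xt %*% xt) /
      (sqrt(rowSums(tr$xt^2)) * sqrt(sum(xt^2)))
    r <- pmax(-1, pmin(1, r))
    out <- data.frame(
      gene = rownames(M)[tr$admissible],
      r = r,
      p = corr_pvalue(r, n),
      n = n,
      stringsAsFactors = FALSE
    )
  } else {
    # pairwise-complete path, gene by gene
    keep <- logical(nrow(M)); rs <- ps <- numeric(nrow(M)); ns <- integer(nrow(M))
    for (i in seq_len(nrow(M))) {
      yi <- M[i, ]
      ok <- is.finite(x) & is.finite(yi)
      if (sum(ok) < 5L) { skipped["too_few_pairs"] <- skipped["too_few_pairs"] + 1L; next }
      if (mad_raw(x[ok]) == 0 || mad_raw(yi[ok]) == 0) {
        skipped["zero_mad"] <- skipped["zero_mad"] + 1L; next
      }
      ri <- bicor(x, yi)
      keep[i] <- TRUE
      rs[i] <- ri; ns[i] <- attr(ri, "n"); ps[i] <- corr_pvalue(as.numeric(ri), ns[i])
    }
    out <- data.frame(
      gene = rownames(M)[keep], r = rs[keep], p = ps[keep], n = ns[keep],
      stringsAsFactors = FALSE
    )
  }
  attr(out, "skipped") <- skipped
  out
}
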