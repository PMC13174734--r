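#' Restrict two panel matrices to their shared samples
#'
#' Cross-tissue correlation requires both tissues measured on the same
#' panel samples (strains). Columns are restricted to the intersection of
#' sample IDs, in the origin matrix's order, and both outputs share that
#' order exactly.
#'
#' @param origin,target Numeric matrices, genes x samples, with sample IDs
#'   as colnames.
#' @return A list with elements `origin`, `target` (aligned matrices) and
#'   `n_shared` (number of shared samples).
#' @export
align_samples <- function(origin, target) {
  stopifnot(is.matrix(origin), is.matrix(target),
            !is.null(colnames(origin)), !is.null(colnames(target)))
  shared <- intersect(colnames(origin), colnames(target))
  if (length(shared) < 5L) {
    stop("need at least 5 shared samples, found ", length(shared))
  }
  message("align_samples: ", length(shared), " shared samples")
  list(origin = origin[, shared, drop = FALSE],
       target = target[, shared, drop = FALSE],
       n_shared = length(shared))
}

# -log10 p aggregation with the p-floor cap; p = 0 would give Inf.
.p_floor_default <- 1e-300

.aggregate_scores <- function(r, p, aggregate, p_floor = .p_floor_default) {
  switch(aggregate,
    mean_log10p = mean(-log10(pmax(p, p_floor))),
    mean_abs_r  = mean(abs(r)),
    stop("unknown aggregation: ", aggregate)
  )
}

#' Crosstalk score of one origin gene against a target transcriptome
#'
#' The S_sec statistic: the aggregate biweight-midcorrelation coupling of a
#' single (typically secreted) origin-tissue gene with the entire
#' target-tissue transcriptome across a genetic panel. The default
#' aggregation is the mean of `-log10(p)` over all admissible target genes;
#' `aggregate = "mean_abs_r"` gives the mean absolute correlation instead.
#' p-values are floored at `p_floor` before taking logs, so a target matrix
#' perfectly coupled to the origin gene yields the cap `-log10(p_floor)`.
#'
#' @param origin_gene Gene ID present in `origin`'s rownames.
#' @param origin,target Aligned genes x samples matrices (see
#'   [align_samples()]).
#' @param aggregate `"mean_log10p"` (default) or `"mean_abs_r"`.
#' @param p_floor Lower p-value bound before `-log10`; default `1e-300`.
#' @return A one-row `data.frame` with columns `origin_gene`, `s_sec`,
#'   `n_target_genes`; attributes `"skipped"` (target-gene skip tally) and
#'   `"cap"` (the score cap implied by `p_floor`).
#' @export
ssec_score <- function(origin_gene, origin, target,
                       aggregate = c("mean_log10p", "mean_abs_r"),
                       p_floor = .p_floor_default) {
  aggregate <- match.arg(aggregate)
  if (!origin_gene %in% rownames(origin)) {
    stop("origin gene absent: ", origin_gene)
  }
  x <- origin[origin_gene, ]
  res <- bicor_vs_matrix(x, target)
  if (nrow(res) == 0L) stop("no admissible target genes")
  out <- data.frame(
    origin_gene = origin_gene,
    s_sec = .aggregate_scores(res$r, res$p, aggregate, p_floor),
    n_target_genes = nrow(res),
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- attr(res, "skipped")
  attr(out, "cap") <- -log10(p_floor)
  out
}

#' Rank secreted origin-tissue genes by crosstalk score
#'
#' The mediator screen: computes [ssec_score()] for every secreted gene
#' present in the origin matrix and returns them ranked by score,
#' descending, with deterministic tie-breaking by gene symbol. Secreted
#' genes that are absent from the origin matrix or inadmissible (zero MAD)
#' are tallied in the `"skipped_origin"` attribute. Optionally attaches a
#' permutation p-value per gene (see [ssec_permutation_null()]).
#'
#' @param origin,target Genes x samples matrices; aligned internally.
#' @param secretome Character vector of secreted gene IDs (the candidate
#'   mediator space).
#' @param aggregate,p_floor Passed to [ssec_score()].
#' @param n_perm If `NULL` (default) no permutation p is computed;
#'   otherwise the number of permutations (`>= 100`) per gene.
#' @param seed Integer seed for the permutations.
#' @return A `data.frame` with columns `origin_gene`, `s_sec`,
#'   `n_target_genes`, `perm_p` (NA when `n_perm` is NULL) and `rank`,
#'   sorted by rank. Attributes: `"skipped_origin"`, `"skipped_target"`,
#'   `"cap"`.
#' @export
rank_mediators <- function(origin, target, secretome,
                           aggregate = c("mean_log10p", "mean_abs_r"),
                           p_floor = .p_floor_default,
                           n_perm = NULL, seed = NULL) {
  aggregate <- match.arg(aggregate)
  al <- align_samples(origin, target)
  origin <- al$origin; target <- al$target
  candidates <- intersect(unique(secretome), rownames(origin))
  if (length(candidates) == 0L) {
    stop("no secreted genes found in the origin matrix")
  }
  n <- ncol(origin)
  .check_n(n)
  if (anyNA(target) || anyNA(origin[candidates, , drop = FALSE])) {
    return(.rank_mediators_slow(origin, target, candidates, aggregate,
                                p_floor, n_perm, seed))
  }
  # shared precomputation: transform target rows once for all candidates
  tr <- .biweight_transform_rows(target)
  tnorm <- sqrt(rowSums(tr$xt^2))
  n_target <- sum(tr$admissible)
  if (n_target == 0L) stop("no admissible target genes")
  skipped_origin <- c(zero_mad = 0L)

  score_one <- function(x) {
    xt <- biweight_transform(x)
    r <- pmax(-1, pmin(1, as.numeric(tr$xt %*% xt) / (tnorm * sqrt(sum(xt^2)))))
    .aggregate_scores(r, corr_pvalue(r, n), aggregate, p_floor)
  }

  scores <- rep(NA_real_, length(candidates))
  admissible <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    x <- origin[candidates[i], ]
    if (mad_raw(x) == 0) { skipped_origin["zero_mad"] <- skipped_origin["zero_mad"] + 1L; next }
    admissible[i] <- TRUE
    scores[i] <- score_one(as.numeric(x))
  }
  out <- data.frame(
    origin_gene = candidates[admissible],
    s_sec = scores[admissible],
    n_target_genes = n_target,
    perm_p = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(n_perm)) {
    if (n_perm < 100L) stop("n_perm must be >= 100")
    if (!is.null(seed)) set.seed(seed)
    for (i in seq_len(nrow(out))) {
      x <- as.numeric(origin[out$origin_gene[i], ])
      perm_scores <- vapply(seq_len(n_perm),
                            function(k) score_one(sample(x)), numeric(1))
      out$perm_p[i] <- (1 + sum(perm_scores >= out$s_sec[i])) / (1 + n_perm)
    }
  }
  ord <- order(-out$s_sec, out$origin_gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (skipped_origin["zero_mad"] > 0) {
    message("rank_mediators: skipped ", skipped_origin["zero_mad"],
            " zero-MAD secreted gene(s)")
  }
  attr(out, "skipped_origin") <- skipped_origin
  attr(out, "skipped_target") <- c(zero_mad = sum(!tr$admissible))
  attr(out, "cap") <- -log10(p_floor)
  out
}

# pairwise-complete fallback when matrices carry missing values
.rank_mediators_slow <- function(origin, target, candidates, aggregate,
                                 p_floor, n_perm, seed) {
  skipped_origin <- c(zero_mad = 0L)
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    g <- candidates[i]
    x <- origin[g, ]
    xf <- x[is.finite(x)]
    if (length(xf) < 5L || mad_raw(xf) == 0) {
      skipped_origin["zero_mad"] <- skipped_origin["zero_mad"] + 1L
      next
    }
    rows[[i]] <- ssec_score(g, origin, target, aggregate, p_floor)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) stop("no admissible secreted genes")
  out$perm_p <- NA_real_
  if (!is.null(n_perm)) {
    if (n_perm < 100L) stop("n_perm must be >= 100")
    for (i in seq_len(nrow(out))) {
      pn <- ssec_permutation_null(out$origin_gene[i], origin, target,
                                  n_perm = n_perm,
                                  seed = if (is.null(seed)) NULL else seed + i,
                                  aggregate = aggregate, p_floor = p_floor)
      out$perm_p[i] <- pn$perm_p
    }
  }
  ord <- order(-out$s_sec, out$origin_gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "skipped_origin") <- skipped_origin
  out
}

#' Permutation null for one gene's crosstalk score
#'
#' Assesses the significance of an observed S_sec by shuffling the origin
#' gene's sample labels, which preserves both tissues' marginal expression
#' structure while breaking only the cross-tissue link, and recomputing the
#' score per permutation. The empirical p-value uses the pseudocount
#' convention `(1 + exceedances) / (1 + n_perm)`, so it is never zero.
#'
#' @inheritParams ssec_score
#' @param n_perm Number of permutations, `>= 100`.
#' @param seed Integer seed; identical seeds give identical null draws.
#' @return A list: `observed` (the unpermuted score), `null` (numeric
#'   vector of permuted scores), `perm_p`.
#' @export
ssec_permutation_null <- function(origin_gene, origin, target,
                                  n_perm = 1000L, seed = NULL,
                                  aggregate = c("mean_log10p", "mean_abs_r"),
                                  p_floor = .p_floor_default) {
  aggregate <- match.arg(aggregate)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (!origin_gene %in% rownames(origin)) stop("origin gene absent: ", origin_gene)
  observed <- ssec_score(origin_gene, origin, target, aggregate, p_floor)$s_sec
  x <- as.numeric(origin[origin_gene, ])
  if (!is.null(seed)) set.seed(seed)
  if (!anyNA(target) && all(is.finite(x))) {
    n <- length(x)
    tr <- .biweight_transform_rows(target)
    tnorm <- sqrt(rowSums(tr$xt^2))
    null <- vapply(seq_len(n_perm), function(k) {
      xt <- biweight_transform(sample(x))
      r <- pmax(-1, pmin(1, as.numeric(tr$xt %*% xt) / (tnorm * sqrt(sum(xt^2)))))
      .aggregate_scores(r, corr_pvalue(r, n), aggregate, p_floor)
    }, numeric(1))
  } else {
    null <- vapply(seq_len(n_perm), function(k) {
      op <- origin
      op[origin_gene, ] <- sample(x)
      ssec_score(origin_gene, op, target, aggregate, p_floor)$s_sec
    }, numeric(1))
  }
  list(observed = observed, null = null,
       perm_p = (1 + sum(null >= observed)) / (1 + n_perm))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: with `m` p-values sorted
#' ascending, `q_(i) = min over j >= i of m * p_(j) / j`, capped at 1 and
#' returned in the input order. Implemented literally as that formula (a
#' reverse cumulative minimum over `m * p_(j) / j`); agrees with
#' `stats::p.adjust(method = "BH")` up to floating-point association.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (no NAs).
#' @return q-values, same length and order as `pvals`.
#' @export
bh_adjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals)
  adj <- m * pvals[o] / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(adj))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Gene-centric cross-tissue correlation profile
#'
#' For one origin gene, scans every gene of every supplied target tissue,
#' computing the biweight midcorrelation and p-value, then applies a single
#' Benjamini-Hochberg adjustment jointly across all tissue-gene pairs of
#' the scan (one scan = one FDR family). Tissues are summarised and ranked
#' by their count of genes with `q < q_threshold`.
#'
#' @param origin_gene Gene ID present in `origin`.
#' @param origin Genes x samples matrix for the origin tissue.
#' @param tissues Named list of genes x samples matrices (the target
#'   tissues); each must share at least 5 samples with `origin`.
#' @param q_threshold FDR cutoff for the per-tissue counts; default `0.1`.
#' @return A list: `profile` — `data.frame(tissue, target_gene, r, p, q)`;
#'   `summary` — per-tissue `data.frame(tissue, n_genes, n_significant)`
#'   sorted by `n_significant` descending (ties by tissue name);
#'   `q_threshold`.
#' @export
gene_centric_profile <- function(origin_gene, origin, tissues,
                                 q_threshold = 0.1) {
  stopifnot(is.list(tissues), length(tissues) > 0)
  if (is.null(names(tissues)) || any(names(tissues) == "")) {
    stop("tissues must be a named list")
  }
  if (!origin_gene %in% rownames(origin)) stop("origin gene absent: ", origin_gene)
  pieces <- list()
  for (tis in names(tissues)) {
    shared <- intersect(colnames(origin), colnames(tissues[[tis]]))
    if (length(shared) < 5L) {
      message("gene_centric_profile: skipping tissue '", tis,
              "' (", length(shared), " shared samples)")
      next
    }
    x <- origin[origin_gene, shared]
    res <- bicor_vs_matrix(x, tissues[[tis]][, shared, drop = FALSE])
    if (nrow(res) == 0L) next
    pieces[[tis]] <- data.frame(tissue = tis, target_gene = res$gene,
                                r = res$r, p = res$p,
                                stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0L) stop("no tissue with sufficient sample overlap")
  profile <- do.call(rbind, pieces)
  rownames(profile) <- NULL
  profile$q <- bh_adjust(profile$p) # joint family across the whole scan
  counts <- vapply(split(profile$q, profile$tissue),
                   function(q) sum(q < q_threshold), integer(1))
  summary <- data.frame(tissue = names(counts),
                        n_genes = as.integer(table(profile$tissue)[names(counts)]),
                        n_significant = as.integer(counts),
                        stringsAsFactors = FALSE)
  summary <- summary[order(-summary$n_significant, summary$tissue), , drop = FALSE]
  rownames(summary) <- NULL
  list(profile = profile, summary = summary, q_threshold = q_threshold)
}
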