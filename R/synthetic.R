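#' Specification for a synthetic two-tissue panel
#'
#' Describes a strain-panel expression dataset in the style of the Hybrid
#' Mouse Diversity Panel: two tissues measured on the same ~100 samples
#' (continuous, array-era-like log-intensities), a secreted-gene candidate
#' set, and one or more planted mediators — secreted origin-tissue genes
#' whose expression drives a correlated block of target-tissue genes
#' through a shared latent level.
#'
#' @param n_samples Number of panel samples (strains); default 100.
#' @param n_origin_genes,n_target_genes Genes per tissue; defaults 1000
#'   and 2000.
#' @param n_secreted Size of the secreted candidate set (planted mediators
#'   plus random decoys); default 200.
#' @param planted_mediators List of `list(gene, n_coupled_targets,
#'   coupling_rho)` entries; `gene` must be an origin gene ID
#'   (`"OG0001"`-style). Default: one mediator, 100 coupled targets,
#'   rho 0.5. Use `list()` for a fully uncoupled (null) panel.
#' @param noise_sd Standard deviation of the expression noise; default 1
#'   (correlation structure is scale-free, this only sets units).
#' @param mediator_purity Correlation between a planted mediator's
#'   expression and its latent driver; default 0.95. Coupling of targets
#'   is adjusted so the population correlation between target and mediator
#'   expression equals `coupling_rho` exactly.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A classed list (`"panel_spec"`).
#' @export
panel_spec <- function(n_samples = 100L,
                       n_origin_genes = 1000L,
                       n_target_genes = 2000L,
                       n_secreted = 200L,
                       planted_mediators = list(
                         list(gene = "OG0001", n_coupled_targets = 100L,
                              coupling_rho = 0.5)
                       ),
                       noise_sd = 1,
                       mediator_purity = 0.95,
                       seed = 1L) {
  stopifnot(n_samples >= 5, n_origin_genes >= 1, n_target_genes >= 1,
            n_secreted >= length(planted_mediators),
            n_secreted <= n_origin_genes,
            noise_sd > 0, mediator_purity > 0, mediator_purity <= 1)
  for (pm in planted_mediators) {
    stopifnot(is.character(pm$gene), pm$n_coupled_targets >= 1)
    if (!is.numeric(pm$coupling_rho) || pm$coupling_rho <= 0 ||
        pm$coupling_rho >= 1) {
      stop("coupling_rho must lie strictly in (0, 1)")
    }
    if (pm$coupling_rho / mediator_purity >= 1) {
      stop("coupling_rho must be below mediator_purity")
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_origin_genes = as.integer(n_origin_genes),
                 n_target_genes = as.integer(n_target_genes),
                 n_secreted = as.integer(n_secreted),
                 planted_mediators = planted_mediators,
                 noise_sd = noise_sd,
                 mediator_purity = mediator_purity,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' Generate a synthetic two-tissue panel with planted mediators
#'
#' Per sample, each planted mediator has a standard-normal latent level
#' `z`; the mediator's measured expression is
#' `x = purity * z + sqrt(1 - purity^2) * e` (so `cor(x, z) = purity`), and
#' each of its coupled target genes is
#' `y = rho' * z + sqrt(1 - rho'^2) * eps` with `rho' =
#' coupling_rho / purity`, giving population `cor(y, x) = coupling_rho`.
#' All remaining genes in both tissues are independent noise. Gene-level
#' baseline means (log-intensity-like) are added; they do not affect
#' correlations. The secretome is the planted mediators plus uniformly
#' sampled decoy origin genes.
#'
#' @param spec A [panel_spec()].
#' @return A list: `origin`, `target` (genes x samples matrices with gene
#'   and sample IDs), `secretome` (character vector), `truth`
#'   (`data.frame(mediator, target_gene, coupling_rho)` of planted edges),
#'   `spec`.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  og <- sprintf("OG%04d", seq_len(spec$n_origin_genes))
  tg <- sprintf("TG%04d", seq_len(spec$n_target_genes))

  origin <- matrix(stats::rnorm(spec$n_origin_genes * n, sd = spec$noise_sd),
                   nrow = spec$n_origin_genes, dimnames = list(og, samples))
  target <- matrix(stats::rnorm(spec$n_target_genes * n, sd = spec$noise_sd),
                   nrow = spec$n_target_genes, dimnames = list(tg, samples))

  truth <- list()
  free_targets <- tg
  purity <- spec$mediator_purity
  for (pm in spec$planted_mediators) {
    if (!pm$gene %in% og) stop("planted mediator not an origin gene: ", pm$gene)
    if (pm$n_coupled_targets > length(free_targets)) {
      stop("not enough free target genes to couple")
    }
    z <- stats::rnorm(n)
    x <- purity * z + sqrt(1 - purity^2) * stats::rnorm(n)
    origin[pm$gene, ] <- spec$noise_sd * x
    rho_z <- pm$coupling_rho / purity
    coupled <- sample(free_targets, pm$n_coupled_targets)
    free_targets <- setdiff(free_targets, coupled)
    eps <- matrix(stats::rnorm(length(coupled) * n), nrow = length(coupled))
    target[coupled, ] <- spec$noise_sd *
      (rho_z * matrix(z, nrow = length(coupled), ncol = n, byrow = TRUE) +
         sqrt(1 - rho_z^2) * eps)
    truth[[pm$gene]] <- data.frame(mediator = pm$gene, target_gene = coupled,
                                   coupling_rho = pm$coupling_rho,
                                   stringsAsFactors = FALSE)
  }

  mediators <- vapply(spec$planted_mediators, `[[`, character(1), "gene")
  decoys <- sample(setdiff(og, mediators), spec$n_secreted - length(mediators))
  secretome <- sort(c(mediators, decoys))

  # gene-level baselines (location shifts leave correlations untouched)
  origin <- origin + stats::rnorm(nrow(origin), mean = 7, sd = 1)
  target <- target + stats::rnorm(nrow(target), mean = 7, sd = 1)

  truth <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
           else data.frame(mediator = character(), target_gene = character(),
                           coupling_rho = numeric())
  list(origin = origin, target = target, secretome = secretome,
       truth = truth, spec = spec)
}

#' Specification for a synthetic multi-cell-type count dataset
#'
#' Describes a two-condition single-nucleus-like dataset: several cell
#' types, negative-binomial counts with a shared dispersion, per-gene,
#' per-cell-type baseline means drawn log-uniformly, and optionally one
#' planted shift — a set of genes whose means are multiplied by
#' `exp(log_fold_change)` in the treated condition of one cell type.
#'
#' @param cell_types `data.frame(name, n_cells_per_condition)`; default 5
#'   cell types with 600 cells per condition (1200 total each, clearing
#'   the scan's default 1000-cell filter).
#' @param n_genes Genes; default 2000.
#' @param baseline_logmean_range Range (natural log of counts/cell) for
#'   the per-gene, per-cell-type baseline means; default `log(c(0.01, 2))`
#'   — mostly-low means giving the sparse, overdispersed counts typical of
#'   single-nucleus data.
#' @param dispersion Negative-binomial dispersion (1/size), shared across
#'   the dataset; default 0.5.
#' @param planted_shift `list(cell_type, n_affected_genes,
#'   log_fold_change)` or `NULL` for a null (exchangeable-conditions)
#'   dataset. Default: 200 genes shifted by 0.5 (natural log) in cell type
#'   `"ct1"`.
#' @param seed Integer seed.
#' @return A classed list (`"cell_spec"`).
#' @export
cell_spec <- function(cell_types = data.frame(
                        name = paste0("ct", 1:5),
                        n_cells_per_condition = 600L),
                      n_genes = 2000L,
                      baseline_logmean_range = log(c(0.01, 2)),
                      dispersion = 0.5,
                      planted_shift = list(cell_type = "ct1",
                                           n_affected_genes = 200L,
                                           log_fold_change = 0.5),
                      seed = 1L) {
  stopifnot(is.data.frame(cell_types),
            all(c("name", "n_cells_per_condition") %in% names(cell_types)),
            all(cell_types$n_cells_per_condition >= 1),
            !anyDuplicated(cell_types$name),
            n_genes >= 1, dispersion >= 0,
            length(baseline_logmean_range) == 2,
            baseline_logmean_range[1] < baseline_logmean_range[2])
  if (!is.null(planted_shift)) {
    stopifnot(planted_shift$cell_type %in% cell_types$name,
              planted_shift$n_affected_genes >= 1,
              planted_shift$n_affected_genes <= n_genes,
              is.numeric(planted_shift$log_fold_change))
  }
  structure(list(cell_types = cell_types, n_genes = as.integer(n_genes),
                 baseline_logmean_range = baseline_logmean_range,
                 dispersion = dispersion, planted_shift = planted_shift,
                 seed = as.integer(seed)),
            class = "cell_spec")
}

# negative-binomial draws for one stratum, assembled sparse without ever
# materialising index vectors of full gene-x-cell length twice
.rnbinom_block <- function(mu_gene, n_cells, dispersion) {
  n_genes <- length(mu_gene)
  if (dispersion > 0) {
    x <- stats::rnbinom(n_genes * n_cells, size = 1 / dispersion, mu = mu_gene)
  } else {
    x <- stats::rpois(n_genes * n_cells, lambda = mu_gene)
  }
  nz <- which(x > 0L)
  Matrix::sparseMatrix(i = ((nz - 1L) %% n_genes) + 1L,
                       j = ((nz - 1L) %/% n_genes) + 1L,
                       x = x[nz], dims = c(n_genes, n_cells))
}

#' Generate a synthetic two-condition single-cell count dataset
#'
#' For each gene and cell type a baseline mean is drawn log-uniformly in
#' `baseline_logmean_range`; counts are negative-binomial with that mean
#' and the shared dispersion. In the planted cell type, the affected
#' genes' means are multiplied by `exp(log_fold_change)` in the treated
#' condition. Conditions are labelled `"control"` and `"treated"`.
#'
#' @param spec A [cell_spec()].
#' @return A [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `"counts"` assay (genes x cells), `colData` columns `cell_type` and
#'   `condition`, barcode column names, and `metadata(ds)$truth` — a
#'   `data.frame(gene, cell_type, log_fold_change)` of planted effects
#'   (zero rows for a null dataset).
#' @export
generate_cells <- function(spec) {
  stopifnot(inherits(spec, "cell_spec"))
  set.seed(spec$seed)
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  lo <- spec$baseline_logmean_range[1]; hi <- spec$baseline_logmean_range[2]

  shift_genes <- character(0)
  if (!is.null(spec$planted_shift) && spec$planted_shift$log_fold_change != 0) {
    shift_genes <- sample(genes, spec$planted_shift$n_affected_genes)
  }

  blocks <- list(); ct_lab <- list(); cond_lab <- list()
  for (i in seq_len(nrow(spec$cell_types))) {
    ct <- spec$cell_types$name[i]
    ncond <- spec$cell_types$n_cells_per_condition[i]
    mu <- exp(stats::runif(spec$n_genes, lo, hi))
    names(mu) <- genes
    mu_treated <- mu
    if (length(shift_genes) && !is.null(spec$planted_shift) &&
        spec$planted_shift$cell_type == ct) {
      mu_treated[shift_genes] <- mu[shift_genes] *
        exp(spec$planted_shift$log_fold_change)
    }
    blocks[[length(blocks) + 1L]] <- .rnbinom_block(mu, ncond, spec$dispersion)
    blocks[[length(blocks) + 1L]] <- .rnbinom_block(mu_treated, ncond, spec$dispersion)
    ct_lab[[length(ct_lab) + 1L]] <- rep(ct, 2L * ncond)
    cond_lab[[length(cond_lab) + 1L]] <- rep(c("control", "treated"), each = ncond)
  }
  counts <- do.call(cbind, blocks)
  rownames(counts) <- genes
  barcodes <- sprintf("CELL%06d", seq_len(ncol(counts)))
  colnames(counts) <- barcodes

  truth <- if (length(shift_genes)) {
    data.frame(gene = sort(shift_genes),
               cell_type = spec$planted_shift$cell_type,
               log_fold_change = spec$planted_shift$log_fold_change,
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(), cell_type = character(),
               log_fold_change = numeric())
  }

  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cell_type = unlist(ct_lab),
                                   condition = unlist(cond_lab),
                                   row.names = barcodes),
    metadata = list(truth = truth, spec = spec)
  )
}
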