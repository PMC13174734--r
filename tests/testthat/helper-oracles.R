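# Independent oracles, deliberately coded from first principles with
# loops/sorting rather than the package's vectorised formulas.

# sort-based median (no stats::median)
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_mad <- function(x) {
  m <- oracle_median(x)
  dev <- numeric(length(x))
  for (i in seq_along(x)) dev[i] <- abs(x[i] - m)
  oracle_median(dev)
}

# direct-formula biweight midcorrelation, element by element
oracle_bicor <- function(x, y) {
  tf <- function(v) {
    m <- oracle_median(v)
    s <- oracle_mad(v)
    out <- numeric(length(v))
    for (i in seq_along(v)) {
      u <- (v[i] - m) / (9 * s)
      if (abs(u) < 1) out[i] <- (v[i] - m) * (1 - u^2)^2
    }
    out
  }
  a <- tf(x); b <- tf(y)
  num <- 0; da <- 0; db <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    da <- da + a[i]^2
    db <- db + b[i]^2
  }
  num / (sqrt(da) * sqrt(db))
}

# naive Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m * p_(j) / j,
# capped at 1, returned in input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) {
      cand <- m * p[o[j]] / j
      if (cand < best) best <- cand
    }
    q[o[i]] <- min(1, best)
  }
  q
}

# small aligned two-tissue panel for quick crosstalk tests
small_panel <- function(seed = 1, coupled = TRUE) {
  generate_panel(panel_spec(
    n_samples = 60L, n_origin_genes = 60L, n_target_genes = 150L,
    n_secreted = 20L,
    planted_mediators = if (coupled) {
      list(list(gene = "OG0001", n_coupled_targets = 30L, coupling_rho = 0.5))
    } else list(),
    seed = seed
  ))
}

# small two-condition cell dataset
small_cells <- function(seed = 1, lfc = 0, n_types = 2L, n_per_cond = 80L,
                        n_genes = 120L) {
  shift <- if (lfc != 0) {
    list(cell_type = "ct1", n_affected_genes = 30L, log_fold_change = lfc)
  } else NULL
  generate_cells(cell_spec(
    cell_types = data.frame(name = paste0("ct", seq_len(n_types)),
                            n_cells_per_condition = n_per_cond),
    n_genes = n_genes, planted_shift = shift, seed = seed
  ))
}
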