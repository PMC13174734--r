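---
title: "Cross-tissue mediator screening and single-cell divergence: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue mediator screening and single-cell divergence: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmed)
```

# The scientific setting

A genetic reference panel — here emulating a ~100-strain inbred mouse panel
with expression measured in two tissues per strain — turns natural genetic
variation into a perturbation screen: if a secreted liver protein
signals to the heart, strains that express its gene highly should show a
coherent shift across much of the cardiac transcriptome. `crossmed`
implements the three statistics of that reasoning chain: a robust
aggregate-correlation screen over secreted candidates, a gene-centric
cross-tissue FDR profile, and, for the follow-up perturbation experiment, a
per-cell-type transcriptome-shift test on single-nucleus data.

# Biweight midcorrelation

All panel correlations use the biweight midcorrelation. Each vector is
centred at its median; deviations are scaled by 9 times the raw
(unscaled) median absolute deviation; points with `|u| >= 1` on that scale
receive zero weight and the rest the Tukey biweight `(1 - u^2)^2`. The
correlation is then the usual normalised cross-product of the weighted,
centred vectors. The constant 9 is the standard tuning of the biweight
midcovariance: roughly, only points further than 4.5 sigma-equivalents from
the centre are discarded in clean data, so efficiency under normality stays
high while a single gross outlier (a bad array, a mislabelled strain)
cannot manufacture or destroy a correlation. A property test in the suite
verifies directly that, with one coordinate corrupted by a 50x outlier,
bicor stays closer to the true correlation than Pearson in at least 95% of
trials.

Two deliberate refusals:

* **Zero-MAD vectors are errors, not fallbacks.** A gene whose expression
  is constant (or majority-constant) in the panel has no defined biweight
  transform. Some implementations silently substitute Pearson for such
  genes; that changes the statistic per gene without telling the user. We
  refuse and count these genes in a skip tally that every stage reports.
* **Fewer than 5 complete pairs is an error.** Below that, any correlation
  and especially its p-value is noise.

P-values use the Student-t approximation `t = r sqrt(n-2) / sqrt(1-r^2)`
with `n - 2` degrees of freedom — the convention of the weighted
co-expression-network ecosystem this statistic comes from. It is an
approximation (the exact null of bicor is not the t distribution), adequate
at panel sizes of 50–150; where exactness matters the package offers the
permutation route instead (`ssec_permutation_null()`).

# The S_sec crosstalk score

For a secreted origin gene the score aggregates evidence over the *whole*
target transcriptome: `S_sec = mean_g(-log10 p_g)`. The aggregation is an
open design point — "aggregate correlation" admits sums or means, of
`-log10 p` or of `|r|`. We fix the mean of `-log10 p` as the default
because it has a parameter-free null reference (`E[-log10 U] = 1/ln 10 ≈
0.434`), is invariant to the number of target genes, and weights strong
couplings on the scale on which they are actually surprising. `aggregate =
"mean_abs_r"` provides the absolute-correlation variant; rankings under the
two rarely differ materially in the planted-structure simulations.

Numerical choices: p-values are floored at `1e-300` before the log, so a
pathological perfectly-coupled target matrix yields the documented cap of
300 rather than infinity; ranking ties break by ascending gene symbol so
ranked tables are byte-reproducible; the permutation null shuffles the
origin gene's sample labels, which preserves both tissues' internal
correlation structure and both marginals, severing only the cross-tissue
link — exactly the null hypothesis the screen tests. Empirical p-values use
the `(1 + exceedances) / (1 + n_perm)` pseudocount, so no permutation p is
ever exactly zero.

# The gene-centric profile

`gene_centric_profile()` scans one origin gene against every gene of every
supplied target tissue and adjusts all resulting p-values with a single
Benjamini–Hochberg step-up, then counts q < 0.1 per tissue. Whether the FDR
family should be per-tissue or global is genuinely underdetermined; we
adjust globally per scan because one cutoff is applied across tissues and a
per-tissue family would make counts incomparable between tissues scanned
together. The BH step-up is implemented literally as
`q_(i) = min_{j>=i} m p_(j) / j` (capped at 1) and is tested for exact
equality against an independently coded naive oracle, plus agreement with
`stats::p.adjust`.

# Per-cell-type divergence

The single-nucleus test asks, per cell type, whether the treatment moved
the whole transcriptome, not any single gene: the statistic is the
Euclidean distance between the two condition centroids over all genes.
Choices that the source procedure leaves open, fixed here:

* **Normalisation**: counts-per-10,000 + `log1p` per cell before
  averaging (the common single-cell default), so centroid distances are not
  dominated by sequencing-depth differences; `assay = "counts"` switches to
  raw means.
* **Null scheme**: "randomly sampled cells" is fixed as a size-preserving
  permutation of condition labels within the cell type — the permutation
  that matches the observed statistic's sampling frame exactly, making the
  test exact under exchangeability. The suite verifies this empirically:
  the type-I error at alpha = 0.05 over 200 null datasets lands inside
  [0.03, 0.08].
* **Gene set**: all genes in the dataset; no highly-variable-gene
  pre-selection, since the statistic is meant to capture global shift.
* **Multiplicity**: Bonferroni across the *retained* cell types (those
  with at least `min_cells = 1000` total cells), matching the stated
  correction; sub-threshold cell types are excluded before testing and
  reported in a tally, so they neither dilute power nor inflate the family.

One scope caveat the documentation states explicitly: in the motivating
design the two condition groups are single pooled libraries (one pool of
three hearts per group), so there is no biological replication; the
permutation test quantifies within-dataset transcriptional divergence, not
population-level treatment effects.

Implementation note: all `n_perm` permutations are evaluated as one
matrix product between the genes x cells block and a cells x n_perm
group-indicator matrix (`d = || s_A (1/n_a + 1/n_b) - tot/n_b ||`), which
makes the default 1000 permutations effectively free; a test pins this
vectorised path to a naive loop that recomputes centroids per permutation
from the same RNG stream.

# What the generators emulate — and what they do not

`generate_panel()` states the panel world: 100 samples; continuous
Gaussian expression on a log-intensity-like scale (the emulated panel data
are array-era intensities, hence no count model); one planted mediator
whose measured expression correlates 0.95 with a latent per-strain driver;
100 of 2000 target genes coupled to that driver so the *population*
mediator–target correlation is exactly `coupling_rho = 0.5`; 199 decoy
secreted genes of pure noise. The defaults are the recovery world the
acceptance suite tests: the planted gene must rank 1 in at least 95% of
seeds.

`generate_cells()` states the single-nucleus world: 5 cell types x 1200
cells (600 per condition, comfortably above the 1000-cell filter), 2000
genes, negative-binomial counts with shared dispersion 0.5 and per-gene,
per-cell-type means log-uniform between 0.01 and 2 counts/cell — sparse,
overdispersed data of realistic depth (~750 counts/cell). The planted
alternative multiplies 200 genes' means by `exp(0.5)` in the treated
condition of one cell type.

Deliberately absent, hence outside what a green test establishes:
gene–gene co-expression network topology beyond the planted block, batch
and library-composition effects, doublets and ambient RNA, per-cell-type
dispersion differences, and any curated secretome biology (the shipped
secretome is generator-made). Truth tables accompany every dataset, and
recovery tests consume only those tables.

# Known limitations

* The t-approximation p-values feeding `S_sec` are approximate for bicor;
  the score is therefore best read as a ranking statistic, with the
  permutation p as its calibrated significance.
* `S_sec` aggregates over correlated target genes, so its variance exceeds
  the independence value; the analytic null mean is exact but the
  3-standard-error calibration band in the tests assumes weak dependence,
  which holds in the generator's world and approximately in real panels.
* The divergence statistic weights all genes equally on the log scale;
  highly expressed genes still dominate Euclidean distance. Comparisons
  should be made within a dataset, not across datasets with different gene
  sets or depths.
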