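#!/usr/bin/env Rscript
# Stage 1: simulate the study's two input datasets with planted structure.
#
# (a) A two-tissue strain panel (100 samples, continuous expression) with one
#     planted secreted mediator driving a 100-gene block of the target tissue
#     at rho = 0.5, plus 199 decoy secreted genes.
# (b) A two-condition single-nucleus-like count dataset (5 cell types x 1200
#     cells, 2000 genes) with a 200-gene, log-FC 0.5 shift planted in ct1.
#
# Outputs under results/sim/ in the exact formats the later stages read.

suppressMessages({
  library(optparse)
  library(crossmed)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/sim")
)))

dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)

message("Simulating the two-tissue panel (seed ", opts$seed, ") ...")
panel <- generate_panel(panel_spec(seed = opts$seed))
write_expression_tsv(panel$origin, file.path(opts$out, "liver.tsv"))
write_expression_tsv(panel$target, file.path(opts$out, "heart.tsv"))
write_secretome(panel$secretome, file.path(opts$out, "secretome.txt"))
data.table::fwrite(panel$truth, file.path(opts$out, "panel_truth.tsv"), sep = "\t")
message("  planted mediator: ", unique(panel$truth$mediator),
        " -> ", nrow(panel$truth), " coupled target genes")

message("Simulating the single-nucleus dataset ...")
cells <- generate_cells(cell_spec(seed = opts$seed + 1L))
write_mtx_dataset(cells, file.path(opts$out, "cells"))
truth <- S4Vectors::metadata(cells)$truth
data.table::fwrite(truth, file.path(opts$out, "cells_truth.tsv"), sep = "\t")
message("  ", ncol(cells), " cells, ", nrow(cells), " genes; planted shift: ",
        nrow(truth), " genes in ", unique(truth$cell_type))

write_run_manifest(file.path(opts$out, "manifest.json"),
                   config = list(stage = "simulate", seed = opts$seed,
                                 out = opts$out))
message("Done: inputs written under ", opts$out)
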