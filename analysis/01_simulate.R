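#!/usr/bin/env Rscript
# Step 1: simulate the study inputs.
#
# Generates a desk-scale stand-in for a fungal genome-annotation project:
# an 11-scaffold ~5.8-Mb genome at 49% GC, four predictor gene-model sets
# (two homology-based, one transcript-assembly, one ab initio) derived
# from 2,000 placed true genes with known consolidation ground truth, and
# a four-condition count matrix with planted never-expressed and
# condition-specific genes. All outputs land under results/sim/.

suppressMessages(library(genetier))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

cfg <- simulation_config(seed = seed)
out <- write_simulation(cfg, "results/sim")

models <- out$models$collection$models
cat(sprintf("Simulated %d scaffolds (%.2f Mb) at seed %d\n",
            cfg$n_scaffolds,
            cfg$n_scaffolds * cfg$scaffold_length / 1e6, seed))
cat(sprintf("Placed %d true genes; emitted %d models:\n",
            cfg$n_true_genes, nrow(models)))
print(table(models$source))
cat(sprintf("Planted expression classes: %s\n",
            paste(names(table(out$expression$truth$class)),
                  table(out$expression$truth$class), collapse = ", ",
                  sep = "=")))
cat("Wrote genome.fa, per-source GFF3s, count TSVs and truth tables to results/sim/\n")
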