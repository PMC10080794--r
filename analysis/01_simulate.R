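#!/usr/bin/env Rscript
# Step 1: generate the synthetic multi-omics study with known ground truth.
#
# The configuration encodes the study conditions: three developmental stages
# (MII oocyte, late 1-cell, late 2-cell) x three replicates of paired IP/input
# SLIM-seq-style libraries plus matched RNA-seq, 5000 genes at a million reads
# per library, dynamics categories at realistic transcriptome proportions, a
# control-vs-knockdown RNA-seq experiment, ribosome-profiling and proteomic
# detection matrices linked to m6A inheritance, and a qPCR Ct table including
# GFP/mCherry MeRIP spike-ins.

suppressMessages(library(mztm6a))

out_dir <- "results/sim"
cfg <- sim_config(seed = 1)
bundle <- simulate_dataset(cfg, out_dir)

truth <- bundle$truth
message(sprintf("simulated %d genes x %d libraries -> %s",
                nrow(truth), ncol(bundle$dataset$counts), out_dir))
message("true category counts:")
print(table(truth$category))
message(sprintf("m6A-tagged genes (any stage): %d",
                sum(truth$category != "untagged")))
message(sprintf("knockdown-affected genes: %d (log2FC %.1f)",
                sum(truth$kd_effect != 0), cfg$kd_lfc))
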