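#!/usr/bin/env Rscript
# Step 3: classify cross-stage m6A dynamics and call ZGA genes.
#
# Stage-call triples map to maternal loss (1,0,0), inherited (1,1,1), de novo
# gain (0,0,1 / 0,1,1), transient, or untagged; Sankey transition counts
# summarise each stage boundary. Minor/major ZGA genes are those whose
# stage-mean TPM fold-change (L1C/MII, respectively L2C/L1C) strictly exceeds
# 5; the major wave is then intersected with the L2C m6A set.

suppressMessages(library(mztm6a))

ds <- load_dataset("results/sim/counts.tsv", "results/sim/samples.tsv",
                   "results/sim/lengths.tsv")
calls <- readr::read_tsv("results/m6a/calls.tsv", show_col_types = FALSE)
l2c_set <- read_gene_set("results/m6a/set_L2C.txt")

dyn <- classify_dynamics(calls)
dir.create("results/dynamics", showWarnings = FALSE, recursive = TRUE)
readr::write_tsv(dyn$records, "results/dynamics/dynamics.tsv")
readr::write_tsv(dyn$sankey, "results/dynamics/sankey.tsv")
message("m6A dynamics categories:")
print(table(dyn$records$category))

input_cols <- ds$samples$assay == "input"
tpm <- counts_to_tpm(ds$counts[, input_cols], ds$gene_lengths)
st_tpm <- stage_mean_tpm(tpm, ds$samples$stage[input_cols])
zga <- detect_zga(st_tpm)
readr::write_tsv(zga, "results/dynamics/zga.tsv")
message(sprintf("minor ZGA: %d genes; major ZGA: %d genes",
                sum(zga$minor_zga), sum(zga$major_zga)))

ov <- zga_m6a_overlap(zga, l2c_set, wave = "major")
message(sprintf("major-ZGA genes with L2C m6A: %d of %d (%.1f%%); %d without",
                ov$n_overlap, ov$n_zga, 100 * ov$fraction_m6a,
                ov$n_without_m6a))

loss <- couple_mrna_change(dyn$records, st_tpm, "MII", "L1C")
gain <- couple_mrna_change(dyn$records, st_tpm, "L1C", "L2C")
message(sprintf("maternal-loss genes with decreasing mRNA: %d",
                length(loss$sets$loss_down$members)))
message(sprintf("de-novo-gain genes with increasing mRNA: %d",
                length(gain$sets$gain_up$members)))
write_gene_set(loss$sets$loss_down, "results/dynamics/set_loss_down.txt")
write_gene_set(gain$sets$gain_up, "results/dynamics/set_gain_up.txt")
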