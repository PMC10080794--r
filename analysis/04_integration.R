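#!/usr/bin/env Rscript
# Step 4: integrate m6A dynamics with translation, proteome and knockdown data.
#
# Detection rule: value above threshold in >= 2 replicates of >= 1 stage.
# The inherited genes' translation-active ratio is compared against a null of
# equally sized random gene sets (resampling without replacement); knockdown
# DEGs (p < 0.05, |log2FC| > 1) are overlapped with the m6A-tagged set.

suppressMessages(library(mztm6a))

read_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$gene_id
  m
}

dyn <- readr::read_tsv("results/dynamics/dynamics.tsv", show_col_types = FALSE)
m6a_any <- read_gene_set("results/m6a/set_m6A_any.txt")
ribo <- read_matrix("results/sim/ribo_tpm.tsv")
protein <- read_matrix("results/sim/protein.tsv")
stages <- sub("_.*$", "", colnames(ribo))

ribo_det <- detected_gene_set(ribo, stages, name = "ribo_detected")
prot_norm <- upper_quartile_normalize(protein)
prot_det <- detected_gene_set(prot_norm, stages, name = "protein_detected")
message(sprintf("translation-detected genes: %d; protein-detected: %d",
                length(ribo_det$members), length(prot_det$members)))

universe <- gene_set("universe", dyn$gene_id)
groups <- list(
  inherited = gene_set("inherited", dyn$gene_id[dyn$category == "inherited"]),
  m6a_pos = m6a_any,
  m6a_neg = gene_set("m6a_neg", setdiff(dyn$gene_id, m6a_any$members)),
  total = universe)
for (nm in names(groups)) {
  r <- translation_active_ratio(groups[[nm]], ribo_det)
  message(sprintf("%-10s translation-active: %d/%d (%.1f%%)",
                  nm, r$n_active, r$n_total, 100 * r$ratio))
}

inh <- groups$inherited
obs <- translation_active_ratio(inh, ribo_det)
rn <- resample_ratio_null(obs$n_total, universe, ribo_det, n_iter = 999,
                          seed = 4, observed = obs$ratio)
message(sprintf(
  "random sets of %d genes: mean ratio %.1f%%; observed %.1f%% (empirical p = %.3g)",
  obs$n_total, 100 * rn$null_mean, 100 * obs$ratio, rn$p_value))

# three-way overlap: m6A-inherited x translation x proteome
venn3 <- overlap_venn(list(groups$inherited, ribo_det, prot_det))
readr::write_tsv(venn3, "results/dynamics/venn_inherited_ribo_protein.tsv")

# knockdown DEGs and their m6A overlap
kd <- load_dataset("results/sim/kd_counts.tsv", "results/sim/kd_samples.tsv",
                   "results/sim/lengths.tsv")
degs <- de_test(kd)
dir.create("results/integration", showWarnings = FALSE, recursive = TRUE)
readr::write_tsv(degs, "results/integration/degs.tsv")
down <- gene_set("down_degs", degs$gene_id[degs$status == "down"])
message(sprintf("DEGs: %d down, %d up", length(down$members),
                sum(degs$status == "up")))
v <- overlap_venn(list(down, m6a_any))
n_both <- v$count[v$down_degs & v$m6A_any]
message(sprintf("down-regulated DEGs carrying m6A: %d/%d (%.1f%%)",
                n_both, length(down$members),
                100 * n_both / length(down$members)))
tab <- matrix(c(n_both, length(down$members) - n_both,
                length(m6a_any$members) - n_both,
                length(universe$members) - length(down$members) -
                  length(m6a_any$members) + n_both), 2, 2)
et <- enrichment_test(tab)
message(sprintf("m6A enrichment among down DEGs: OR = %.2f, exact p = %.3g",
                et$odds_ratio, et$p_value))
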