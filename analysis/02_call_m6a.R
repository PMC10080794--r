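#!/usr/bin/env Rscript
# Step 2: call m6A-tagged genes per stage from the IP/input libraries.
#
# Per stage: median-of-ratios size factors, an NB Wald test of IP vs input
# (stage-level p), per-replicate log2 fold-changes, then the decision rule
# (input count > 1, log2FC > 0 with p < 0.05, or log2FC > 2 when p is NA) with
# a >= 2-of-3 replicate consensus. A gene is m6A-tagged overall when called in
# at least one stage.

suppressMessages(library(mztm6a))

ds <- load_dataset("results/sim/counts.tsv", "results/sim/samples.tsv",
                   "results/sim/lengths.tsv")
truth <- readr::read_tsv("results/sim/truth.tsv", show_col_types = FALSE)

calls <- call_m6a(ds)
sets <- m6a_gene_sets(calls)

dir.create("results/m6a", showWarnings = FALSE, recursive = TRUE)
readr::write_tsv(calls, "results/m6a/calls.tsv")
for (s in sets) write_gene_set(s, sprintf("results/m6a/set_%s.txt", s$name))

for (st in c("MII", "L1C", "L2C")) {
  message(sprintf("%s: %d m6A-tagged genes", st, length(sets[[st]]$members)))
}
message(sprintf("m6A_any (>=1 stage): %d genes", length(sets$m6A_any$members)))

tagged <- truth$gene_id[truth$category != "untagged"]
sens <- mean(tagged %in% sets$m6A_any$members)
fp <- length(setdiff(sets$m6A_any$members, tagged))
message(sprintf("recovery vs truth: sensitivity %.1f%%, %d false positives",
                100 * sens, fp))

# per-sample QC: correlation of relative m6A levels between replicates
tpm <- counts_to_tpm(ds$counts, ds$gene_lengths)
cc <- sample_correlation(tpm[, ds$samples$assay == "IP"])
message(sprintf("median between-IP-replicate correlation: %.3f",
                median(cc[upper.tri(cc)])))
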