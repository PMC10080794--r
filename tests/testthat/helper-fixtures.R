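# Fixture builders shared across the suite. Everything is generated in code;
# no data files are read.

# A tiny paired IP/input dataset: `n_genes` genes, `n_rep` replicate pairs per
# stage, counts drawn NB around `mu` with dispersion `alpha`; optional per-gene
# IP enrichment (log2) applied at all stages.
toy_ipinput_dataset <- function(n_genes = 50, n_rep = 3, mu = 100,
                                alpha = 0.05, enrich_log2 = NULL,
                                stages = c("MII", "L1C", "L2C"),
                                seed = 1) {
  set.seed(seed)
  if (is.null(enrich_log2)) enrich_log2 <- rep(0, n_genes)
  ids <- sprintf("g%03d", seq_len(n_genes))
  cols <- list()
  meta <- list()
  for (st in stages) {
    for (r in seq_len(n_rep)) {
      id_in <- sprintf("%s_input_%d", st, r)
      id_ip <- sprintf("%s_IP_%d", st, r)
      cols[[id_in]] <- rnbinom(n_genes, mu = mu, size = 1 / alpha)
      cols[[id_ip]] <- rnbinom(n_genes, mu = mu * 2^enrich_log2,
                               size = 1 / alpha)
      meta[[id_in]] <- c(st, "input", r)
      meta[[id_ip]] <- c(st, "IP", r)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- ids
  samples <- tibble::tibble(
    sample_id = names(meta),
    stage = vapply(meta, `[`, character(1), 1),
    assay = vapply(meta, `[`, character(1), 2),
    replicate = as.integer(vapply(meta, `[`, character(1), 3)))
  lengths <- stats::setNames(rep(1000, n_genes), ids)
  omics_dataset(counts, samples, lengths)
}

# A deterministic Ct table for qPCR tests: one target plus the Actb reference
# in Ctrl/KD, and a GFP/mCherry spike-in pair measured as IP and 10% input.
toy_ct_table <- function(target_shift_kd = 1, gfp_pct = 10, mch_pct = 0.5,
                         ct_ref = 20, ct_target = 24, input_fraction = 0.1) {
  adj <- log2(1 / input_fraction)
  ct_in <- 25
  tibble::tibble(
    target = c("Myt1", "Myt1", "Actb", "Actb",
               "GFP", "GFP", "mCherry", "mCherry"),
    condition = c("Ctrl", "KD", "Ctrl", "KD", "MII", "MII", "MII", "MII"),
    fraction_kind = c(rep("total", 4), "input", "IP", "input", "IP"),
    ct = c(ct_target, ct_target + target_shift_kd, ct_ref, ct_ref,
           ct_in, ct_in - adj - log2(gfp_pct / 100),
           ct_in, ct_in - adj - log2(mch_pct / 100)),
    replicate = 1L)
}

# Category-level F1 from a truth/predicted cross-table.
category_f1 <- function(truth_cat, pred_cat) {
  cats <- sort(unique(truth_cat))
  vapply(cats, function(cc) {
    tp <- sum(truth_cat == cc & pred_cat == cc)
    2 * tp / (sum(pred_cat == cc) + sum(truth_cat == cc))
  }, numeric(1))
}
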