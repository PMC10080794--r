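# The m6A-tagged-gene decision rules: per-replicate IP/input log2 fold-changes,
# the per-replicate calling rule, the >= 2-of-3 replicate consensus within a
# stage, and the >= 1-stage union across stages.

#' Per-replicate IP/input log2 fold-changes within a stage
#'
#' Pairs the stage's IP and input libraries by replicate number and computes
#' `log2((ip / sf_ip + c) / (input / sf_input + c))` per gene and replicate,
#' where `c` is a pseudocount guarding against zero counts.
#'
#' @param dataset An [omics_dataset()].
#' @param stage Stage label.
#' @param pseudocount Pseudocount `c` on normalised counts (default 0.5).
#' @param size_factors Optional named/per-sample factors for the stage's
#'   IP+input columns (in dataset column order); computed on that subset when
#'   `NULL`.
#' @return A list with `lfc` (genes x replicates matrix of log2FCs),
#'   `input_counts` (genes x replicates raw input counts) and `replicates`.
#' @export
per_replicate_lfc <- function(dataset, stage, pseudocount = 0.5,
                              size_factors = NULL) {
  stopifnot(inherits(dataset, "omics_dataset"))
  keep <- dataset$samples$stage == stage &
    dataset$samples$assay %in% c("IP", "input")
  if (!any(keep)) abort_value(sprintf("stage '%s' absent from dataset", stage))
  sub <- dataset$samples[keep, , drop = FALSE]
  counts <- dataset$counts[, keep, drop = FALSE]

  ip_reps <- sort(sub$replicate[sub$assay == "IP"])
  in_reps <- sort(sub$replicate[sub$assay == "input"])
  orphan <- c(setdiff(ip_reps, in_reps), setdiff(in_reps, ip_reps))
  if (length(orphan) > 0) {
    abort_value(sprintf("unpaired replicate(s) in stage %s: %s", stage,
                        paste(unique(orphan), collapse = ", ")))
  }
  reps <- ip_reps
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)

  lfc <- matrix(NA_real_, nrow(counts), length(reps),
                dimnames = list(rownames(counts), paste0("rep", reps)))
  input_raw <- lfc
  for (i in seq_along(reps)) {
    r <- reps[i]
    ip_col <- which(sub$assay == "IP" & sub$replicate == r)
    in_col <- which(sub$assay == "input" & sub$replicate == r)
    ip_norm <- counts[, ip_col] / size_factors[ip_col]
    in_norm <- counts[, in_col] / size_factors[in_col]
    lfc[, i] <- log2((ip_norm + pseudocount) / (in_norm + pseudocount))
    input_raw[, i] <- counts[, in_col]
  }
  list(lfc = lfc, input_counts = input_raw, replicates = reps)
}

#' Apply the per-replicate m6A calling rule for one stage
#'
#' A gene is called in replicate `r` iff its raw input count exceeds
#' `min_input_count` in that replicate AND either (a) the stage-level Wald
#' p-value is below `p_threshold` and the replicate log2FC is positive, or
#' (b) the stage p-value is undefined (`NA`) and the replicate log2FC exceeds
#' `lfc_na_threshold`. The stage-level consensus call requires the rule to hold
#' in at least `consensus` replicates.
#'
#' @param rep_lfc Genes x replicates matrix of per-replicate log2FCs.
#' @param input_counts Genes x replicates matrix of raw input counts.
#' @param stage_result Stage-level [nb_wald_test()] tibble.
#' @param stage Stage label recorded in the output.
#' @param p_threshold Stage p-value threshold (default 0.05).
#' @param lfc_na_threshold Log2FC threshold for undefined-p genes (default 2).
#' @param min_input_count Input raw count must strictly exceed this (default 1).
#' @param consensus Minimum replicate calls for a stage call (default 2).
#' @param prior_sd Prior SD for the shrunken relative m6A level (default 1).
#' @return A tibble with one row per gene: per-replicate log2FCs
#'   (`rep_lfc_*`), per-replicate flags (`rep_called_*`), `stage_p`,
#'   `rel_m6a`, `n_rep_called`, `stage_called`.
#' @export
call_m6a_stage <- function(rep_lfc, input_counts, stage_result, stage,
                           p_threshold = 0.05, lfc_na_threshold = 2,
                           min_input_count = 1, consensus = 2,
                           prior_sd = 1) {
  if (!identical(rownames(rep_lfc), stage_result$gene_id)) {
    abort_value("rep_lfc rows and stage_result genes must align")
  }
  if (!identical(dim(rep_lfc), dim(input_counts))) {
    abort_value("rep_lfc and input_counts must have identical shape")
  }
  n_rep <- ncol(rep_lfc)
  if (n_rep < 2) {
    warning(sprintf(
      "stage %s has %d replicate pair(s); consensus of %d is unreachable",
      stage, n_rep, consensus))
  }

  p <- stage_result$wald_p
  p_def <- !is.na(p)
  called <- matrix(FALSE, nrow(rep_lfc), n_rep, dimnames = dimnames(rep_lfc))
  for (r in seq_len(n_rep)) {
    sig <- p_def & p < p_threshold & rep_lfc[, r] > 0
    na_fallback <- !p_def & rep_lfc[, r] > lfc_na_threshold
    called[, r] <- input_counts[, r] > min_input_count & (sig | na_fallback)
  }
  n_called <- rowSums(called)

  rel_m6a <- shrink_lfc(stage_result, prior_sd = prior_sd,
                        fallback_lfc = rowMeans(rep_lfc))

  out <- tibble::tibble(gene_id = stage_result$gene_id, stage = stage)
  for (r in seq_len(n_rep)) out[[paste0("rep_lfc_", r)]] <- unname(rep_lfc[, r])
  for (r in seq_len(n_rep)) out[[paste0("rep_called_", r)]] <- unname(called[, r])
  out$stage_p <- p
  out$rel_m6a <- unname(rel_m6a)
  out$n_rep_called <- unname(as.integer(n_called))
  out$stage_called <- unname(n_called >= consensus)
  out
}

#' Call m6A-tagged genes across all stages
#'
#' Runs, for every stage of the dataset's stage vocabulary: size-factor
#' normalisation of that stage's IP+input libraries, the stage-level NB Wald
#' test, the per-replicate log2 fold-changes, and the replicate-consensus
#' calling rule; results are stacked into one stage-call table.
#'
#' @param dataset An [omics_dataset()] with IP and input samples per stage.
#' @inheritParams call_m6a_stage
#' @param pseudocount Pseudocount for per-replicate log2FCs (default 0.5).
#' @return A tibble with one row per gene x stage (see [call_m6a_stage()]).
#' @export
call_m6a <- function(dataset, p_threshold = 0.05, lfc_na_threshold = 2,
                     min_input_count = 1, consensus = 2, pseudocount = 0.5,
                     prior_sd = 1) {
  stopifnot(inherits(dataset, "omics_dataset"))
  stages <- intersect(dataset$stage_levels, unique(dataset$samples$stage))
  rows <- lapply(stages, function(st) {
    res <- nb_wald_stage_test(dataset, st)
    pr <- per_replicate_lfc(dataset, st, pseudocount = pseudocount)
    call_m6a_stage(pr$lfc, pr$input_counts, res, st,
                   p_threshold = p_threshold,
                   lfc_na_threshold = lfc_na_threshold,
                   min_input_count = min_input_count,
                   consensus = consensus, prior_sd = prior_sd)
  })
  dplyr::bind_rows(rows)
}

#' Per-stage and union m6A gene sets
#'
#' A gene is m6A-tagged overall if it has a consensus call in at least one
#' stage (`m6A_any`); the complement within the expressed universe is
#' `m6A_neg`.
#'
#' @param calls Stage-call table from [call_m6a()].
#' @param universe Optional character vector of expressed gene ids defining
#'   the complement; defaults to every gene in the table.
#' @return Named list of [gene_set()]s: one per stage, plus `m6A_any` and
#'   `m6A_neg`.
#' @export
m6a_gene_sets <- function(calls, universe = NULL) {
  stages <- unique(calls$stage)
  sets <- lapply(stages, function(st) {
    g <- calls$gene_id[calls$stage == st & calls$stage_called]
    gene_set(st, g)
  })
  names(sets) <- stages
  any_genes <- unique(calls$gene_id[calls$stage_called])
  if (is.null(universe)) universe <- unique(calls$gene_id)
  sets$m6A_any <- gene_set("m6A_any", any_genes)
  sets$m6A_neg <- gene_set("m6A_neg", setdiff(universe, any_genes))
  sets
}
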