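# Cross-stage m6A dynamics: per-gene stage-call patterns, the named dynamics
# categories, Sankey-style stage-to-stage transition counts, ZGA calls from
# TPM fold-changes, and m6A--mRNA coupling.

.category_of_pattern <- function(mii, l1c, l2c) {
  dplyr::case_when(
    mii & !l1c & !l2c ~ "maternal_loss",
    mii & l1c & l2c ~ "inherited",
    !mii & l2c ~ "de_novo_gain",     # (0,0,1) and (0,1,1)
    !mii & !l1c & !l2c ~ "untagged",
    TRUE ~ "transient")              # (0,1,0), (1,0,1), (1,1,0)
}

#' Classify per-gene m6A dynamics across MII -> L1C -> L2C
#'
#' Maps each gene's ordered triple of stage calls to a named category:
#' `(1,0,0)` maternal loss, `(1,1,1)` inherited, `(0,0,1)` / `(0,1,1)`
#' de novo gain, `(0,1,0)` / `(1,0,1)` / `(1,1,0)` transient, `(0,0,0)`
#' untagged. The raw 8-pattern string is kept so users can regroup, and
#' Sankey-style transition counts (kept / lost / gained / absent) are reported
#' for both stage boundaries.
#'
#' @param calls Stage-call table from [call_m6a()] covering all three stages.
#' @param stages Ordered stage triple (default `c("MII","L1C","L2C")`).
#' @return A list with `records` (tibble: `gene_id`, per-stage logical calls,
#'   `pattern` such as `"101"`, `category`) and `sankey` (tibble of per-boundary
#'   transition counts).
#' @export
classify_dynamics <- function(calls, stages = c("MII", "L1C", "L2C")) {
  wide <- tidyr::pivot_wider(calls[, c("gene_id", "stage", "stage_called")],
                             names_from = "stage",
                             values_from = "stage_called")
  missing_stage <- setdiff(stages, names(wide))
  if (length(missing_stage) > 0) {
    abort_value(sprintf("stage-call table lacks stage(s): %s",
                        paste(missing_stage, collapse = ", ")))
  }
  if (anyNA(wide[stages])) {
    abort_value("some genes lack a call in at least one stage")
  }
  s1 <- wide[[stages[1]]]
  s2 <- wide[[stages[2]]]
  s3 <- wide[[stages[3]]]
  records <- tibble::tibble(
    gene_id = wide$gene_id,
    !!stages[1] := s1, !!stages[2] := s2, !!stages[3] := s3,
    pattern = paste0(as.integer(s1), as.integer(s2), as.integer(s3)),
    category = .category_of_pattern(s1, s2, s3))

  boundary <- function(from, to, a, b) {
    tibble::tibble(
      from = from, to = to,
      kept = sum(a & b), lost = sum(a & !b),
      gained = sum(!a & b), absent = sum(!a & !b))
  }
  sankey <- dplyr::bind_rows(
    boundary(stages[1], stages[2], s1, s2),
    boundary(stages[2], stages[3], s2, s3))

  list(records = records, sankey = sankey)
}

#' Stage-mean TPM matrix
#'
#' Averages TPM columns per stage, in stage order.
#'
#' @param tpm Genes-by-samples TPM matrix.
#' @param stages Stage label per column of `tpm`.
#' @param stage_levels Ordered stage vocabulary.
#' @return Genes-by-stages matrix of mean TPM.
#' @export
stage_mean_tpm <- function(tpm, stages, stage_levels = c("MII", "L1C", "L2C")) {
  stages <- as.character(stages)
  present <- intersect(stage_levels, unique(stages))
  out <- vapply(present, function(st) {
    rowMeans(tpm[, stages == st, drop = FALSE])
  }, numeric(nrow(tpm)))
  if (nrow(tpm) == 1) out <- matrix(out, nrow = 1, dimnames = list(rownames(tpm), present))
  out
}

#' Call minor and major ZGA genes
#'
#' Minor ZGA: TPM fold-change L1C over MII strictly greater than `fc_threshold`
#' (default 5); major ZGA: L2C over L1C strictly greater than the threshold.
#' Fold-changes are computed on stage-mean TPM with a pseudocount so silent-MII
#' genes (the dominant ZGA case) stay finite.
#'
#' @param stage_tpm Genes-by-stages matrix of mean TPM (see
#'   [stage_mean_tpm()]) with columns MII, L1C, L2C.
#' @param fc_threshold Strict fold-change threshold (default 5).
#' @param pseudocount TPM pseudocount (default 0.1).
#' @return A tibble (`gene_id`, `fc_l1c_mii`, `fc_l2c_l1c`, `minor_zga`,
#'   `major_zga`).
#' @export
detect_zga <- function(stage_tpm, fc_threshold = 5, pseudocount = 0.1) {
  need <- c("MII", "L1C", "L2C")
  if (!all(need %in% colnames(stage_tpm))) {
    abort_value("stage_tpm must have columns MII, L1C, L2C")
  }
  fc1 <- (stage_tpm[, "L1C"] + pseudocount) / (stage_tpm[, "MII"] + pseudocount)
  fc2 <- (stage_tpm[, "L2C"] + pseudocount) / (stage_tpm[, "L1C"] + pseudocount)
  tibble::tibble(
    gene_id = rownames(stage_tpm),
    fc_l1c_mii = unname(fc1),
    fc_l2c_l1c = unname(fc2),
    minor_zga = unname(fc1 > fc_threshold),
    major_zga = unname(fc2 > fc_threshold))
}

#' Couple m6A dynamics categories to mRNA expression direction
#'
#' Annotates every gene with its mRNA direction over a stage transition
#' (`up` when the pseudocounted TPM ratio exceeds `fc_threshold`, `down` when
#' it is below `1 / fc_threshold`, else `flat`; the default threshold of 1
#' reduces to the sign of change) and emits the two coupled sets: maternal-loss
#' genes whose mRNA also decreases, and de-novo-gain genes whose mRNA also
#' increases.
#'
#' @param records Dynamics records from [classify_dynamics()].
#' @param stage_tpm Genes-by-stages mean TPM matrix.
#' @param from_stage,to_stage Transition over which direction is assessed.
#' @param fc_threshold Fold-change threshold `>= 1` (default 1 = sign rule).
#' @param pseudocount TPM pseudocount (default 0.1).
#' @return A list with `records` (input records plus `mrna_direction`) and
#'   `sets` (gene sets `loss_down` and `gain_up`).
#' @export
couple_mrna_change <- function(records, stage_tpm, from_stage, to_stage,
                               fc_threshold = 1, pseudocount = 0.1) {
  if (fc_threshold < 1) abort_value("fc_threshold must be >= 1")
  for (st in c(from_stage, to_stage)) {
    if (!st %in% colnames(stage_tpm)) {
      abort_value(sprintf("unknown stage '%s' in stage_tpm", st))
    }
  }
  tpm <- stage_tpm[match(records$gene_id, rownames(stage_tpm)), , drop = FALSE]
  ratio <- (tpm[, to_stage] + pseudocount) / (tpm[, from_stage] + pseudocount)
  dir <- ifelse(ratio > fc_threshold, "up",
                ifelse(ratio < 1 / fc_threshold, "down", "flat"))
  out <- records
  out$mrna_direction <- unname(dir)
  sets <- list(
    loss_down = gene_set("loss_down",
                         out$gene_id[out$category == "maternal_loss" &
                                       out$mrna_direction == "down"]),
    gain_up = gene_set("gain_up",
                       out$gene_id[out$category == "de_novo_gain" &
                                     out$mrna_direction == "up"]))
  list(records = out, sets = sets)
}

#' Overlap between ZGA genes and stage m6A calls
#'
#' Intersects a ZGA wave's gene set with a stage's m6A set, reporting the
#' overlap set, the count of ZGA genes without the mark, and the overlap
#' fraction.
#'
#' @param zga ZGA call tibble from [detect_zga()].
#' @param stage_set A [gene_set()] of m6A-tagged genes (typically L2C for the
#'   major wave).
#' @param wave `"major"` (default) or `"minor"`.
#' @return A list: `overlap` (gene_set), `n_zga`, `n_overlap`,
#'   `n_without_m6a`, `fraction_m6a`.
#' @export
zga_m6a_overlap <- function(zga, stage_set, wave = c("major", "minor")) {
  wave <- match.arg(wave)
  zga_genes <- zga$gene_id[if (wave == "major") zga$major_zga else zga$minor_zga]
  ov <- intersect(zga_genes, stage_set$members)
  list(
    overlap = gene_set(sprintf("%s_zga_m6a", wave), ov),
    n_zga = length(zga_genes),
    n_overlap = length(ov),
    n_without_m6a = length(zga_genes) - length(ov),
    fraction_m6a = if (length(zga_genes) > 0) length(ov) / length(zga_genes)
    else NA_real_)
}
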