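#' Construct a validated multi-omics count dataset
#'
#' The common container consumed by every count-based step: a genes-by-samples
#' count matrix, a sample sheet describing stage / assay / replicate for each
#' column, and (optionally) gene lengths for TPM computation.
#'
#' @param counts Integer-valued matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids).
#' @param samples Data frame with columns `sample_id`, `stage`, `assay`,
#'   `replicate` and optionally `group` (e.g. `Ctrl` / `KD`).
#' @param gene_lengths Optional named numeric vector of positive lengths in
#'   nucleotides, one per gene; required later for TPM.
#' @param stage_levels Ordered stage vocabulary. The developmental ordering is
#'   fixed at MII -> L1C -> L2C by default; a sheet mentioning other stages is
#'   rejected unless this argument lists them.
#'
#' @return An object of class `omics_dataset`: a list with elements `counts`,
#'   `samples` (tibble), `gene_lengths` and `stage_levels`.
#'
#' @details Validation enforces: every count column has exactly one sample-sheet
#'   row; counts for sequencing assays (`IP`, `input`, `rna`) are non-negative
#'   integers; `(stage, assay, replicate)` triples are unique; gene lengths,
#'   when given, are positive and cover all genes.
#'
#' @export
omics_dataset <- function(counts, samples, gene_lengths = NULL,
                          stage_levels = c("MII", "L1C", "L2C")) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_schema("counts must have gene ids as rownames and sample ids as colnames")
  }
  samples <- tibble::as_tibble(samples)
  required <- c("sample_id", "stage", "assay", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf("sample sheet lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$stage <- as.character(samples$stage)
  samples$assay <- as.character(samples$assay)
  samples$replicate <- as.integer(samples$replicate)

  if (anyDuplicated(samples$sample_id)) {
    abort_schema("duplicate sample_id in sample sheet")
  }
  orphans <- setdiff(colnames(counts), samples$sample_id)
  if (length(orphans) > 0) {
    abort_schema(sprintf("sample(s) in counts absent from sheet: %s",
                         paste(orphans, collapse = ", ")))
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]

  bad_stage <- setdiff(unique(samples$stage), stage_levels)
  if (length(bad_stage) > 0) {
    abort_schema(sprintf(
      "stage(s) %s not in the stage vocabulary (%s); pass stage_levels to override",
      paste(bad_stage, collapse = ", "), paste(stage_levels, collapse = ", ")))
  }
  bad_assay <- setdiff(unique(samples$assay), .known_assays)
  if (length(bad_assay) > 0) {
    abort_schema(sprintf("unknown assay value(s): %s",
                         paste(bad_assay, collapse = ", ")))
  }
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1)) {
    abort_schema("replicate must be a positive integer")
  }
  key <- paste(samples$stage, samples$assay, samples$replicate,
               if ("group" %in% names(samples)) samples$group else "")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort_schema(sprintf("duplicate (stage, assay, replicate) triple: %s", dup))
  }

  count_like <- samples$assay %in% c("IP", "input", "rna")
  cm <- counts[, count_like, drop = FALSE]
  if (length(cm) > 0) {
    if (anyNA(cm) || !is.numeric(cm)) {
      bad <- which(is.na(cm) | !is.finite(cm), arr.ind = TRUE)[1, , drop = TRUE]
      abort_value(sprintf("non-numeric count for gene %s, sample %s",
                          rownames(cm)[bad[1]], colnames(cm)[bad[2]]))
    }
    if (any(cm < 0) || any(cm != round(cm))) {
      bad <- which(cm < 0 | cm != round(cm), arr.ind = TRUE)[1, , drop = TRUE]
      abort_value(sprintf("negative or non-integral count for gene %s, sample %s",
                          rownames(cm)[bad[1]], colnames(cm)[bad[2]]))
    }
  }

  if (!is.null(gene_lengths)) {
    gene_lengths <- unlist(gene_lengths)
    missing_len <- setdiff(rownames(counts), names(gene_lengths))
    if (length(missing_len) > 0) {
      abort_schema(sprintf("gene length missing for %d gene(s), e.g. %s",
                           length(missing_len), missing_len[1]))
    }
    if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0)) {
      abort_value("gene lengths must be positive and finite")
    }
    gene_lengths <- gene_lengths[rownames(counts)]
  }

  structure(
    list(counts = counts, samples = samples, gene_lengths = gene_lengths,
         stage_levels = stage_levels),
    class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("<omics_dataset> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(stage = x$samples$stage, assay = x$samples$assay)
  print(tab)
  invisible(x)
}

#' Load a dataset from TSV files
#'
#' Reads a genes-by-samples counts TSV (first column `gene_id`, remaining
#' columns one per sample), a sample sheet TSV and, optionally, a gene length
#' TSV (`gene_id`, `length`), and returns a validated [omics_dataset()].
#'
#' @param counts_path,samples_path,lengths_path Paths to the TSV files;
#'   `lengths_path` may be `NULL`.
#' @inheritParams omics_dataset
#' @return An `omics_dataset`.
#' @export
load_dataset <- function(counts_path, samples_path, lengths_path = NULL,
                         stage_levels = c("MII", "L1C", "L2C")) {
  for (p in c(counts_path, samples_path, lengths_path)) {
    if (!file.exists(p)) abort_io(sprintf("file not found: %s", p))
  }
  counts_df <- readr::read_tsv(counts_path, show_col_types = FALSE,
                               progress = FALSE)
  if (names(counts_df)[1] != "gene_id") {
    abort_schema("counts TSV must have 'gene_id' as its first column")
  }
  gene_ids <- as.character(counts_df$gene_id)
  if (anyDuplicated(gene_ids)) abort_schema("duplicate gene_id in counts TSV")
  mat_cols <- counts_df[, -1, drop = FALSE]
  non_num <- names(mat_cols)[!vapply(mat_cols, is.numeric, logical(1))]
  if (length(non_num) > 0) {
    abort_value(sprintf("non-numeric count column(s): %s",
                        paste(non_num, collapse = ", ")))
  }
  counts <- as.matrix(mat_cols)
  rownames(counts) <- gene_ids

  samples <- readr::read_tsv(samples_path, show_col_types = FALSE,
                             progress = FALSE)

  gene_lengths <- NULL
  if (!is.null(lengths_path)) {
    len_df <- readr::read_tsv(lengths_path, show_col_types = FALSE,
                              progress = FALSE)
    if (!all(c("gene_id", "length") %in% names(len_df))) {
      abort_schema("lengths TSV must have columns gene_id and length")
    }
    gene_lengths <- stats::setNames(as.numeric(len_df$length),
                                    as.character(len_df$gene_id))
  }
  omics_dataset(counts, samples, gene_lengths, stage_levels = stage_levels)
}

#' Write a dataset to a directory of TSV files
#'
#' Inverse of [load_dataset()]: writes `counts.tsv`, `samples.tsv` and (when
#' lengths are present) `lengths.tsv` so that loading them back reproduces the
#' dataset exactly.
#'
#' @param dataset An `omics_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "omics_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts_path <- file.path(dir, "counts.tsv")
  samples_path <- file.path(dir, "samples.tsv")
  counts_df <- tibble::tibble(gene_id = rownames(dataset$counts))
  counts_df <- cbind(counts_df, tibble::as_tibble(dataset$counts))
  readr::write_tsv(counts_df, counts_path, progress = FALSE)
  readr::write_tsv(dataset$samples, samples_path, progress = FALSE)
  paths <- c(counts_path, samples_path)
  if (!is.null(dataset$gene_lengths)) {
    lengths_path <- file.path(dir, "lengths.tsv")
    readr::write_tsv(
      tibble::tibble(gene_id = names(dataset$gene_lengths),
                     length = unname(dataset$gene_lengths)),
      lengths_path, progress = FALSE)
    paths <- c(paths, lengths_path)
  }
  invisible(paths)
}

# Subset the samples of a dataset by a logical/index vector over columns.
#' @keywords internal
#' @noRd
subset_samples <- function(dataset, keep) {
  omics_dataset(dataset$counts[, keep, drop = FALSE],
                dataset$samples[keep, , drop = FALSE],
                dataset$gene_lengths,
                stage_levels = dataset$stage_levels)
}
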