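#' Median-of-ratios size factors
#'
#' Per-sample scaling constants equalising sequencing depth: each sample's
#' factor is the median, over reference genes, of that sample's count divided
#' by the gene's geometric mean across samples. Reference genes are those with
#' nonzero counts in every sample. When no such gene exists the function falls
#' back to total-count ratios (each library size divided by the geometric mean
#' of library sizes) with a warning.
#'
#' @param counts Genes-by-samples count matrix.
#' @return A positive numeric vector, one factor per sample.
#' @export
compute_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0)) {
    abort_value("every sample must have at least one nonzero count")
  }
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    warning("no gene has nonzero counts in all samples; ",
            "falling back to total-count ratio normalization")
    totals <- colSums(counts)
    return(totals / geomean(totals))
  }
  log_gm <- rowMeans(log(counts[ref, , drop = FALSE]))
  sf <- apply(log(counts[ref, , drop = FALSE]), 2,
              function(lc) exp(stats::median(lc - log_gm)))
  unname(sf)
}

#' Counts to transcripts per million (TPM)
#'
#' Normalises each gene's count by its length, then scales each sample so the
#' length-normalised rates sum to one million. An all-zero sample yields an
#' all-zero TPM column (not NaN).
#'
#' @param counts Genes-by-samples count matrix.
#' @param gene_lengths Named positive lengths (nucleotides) covering all genes.
#' @return Matrix of TPM values with the same dimnames as `counts`.
#' @export
counts_to_tpm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  gene_lengths <- unlist(gene_lengths)
  missing_len <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing_len) > 0) {
    abort_value(sprintf("no length for gene(s): %s",
                        paste(utils::head(missing_len, 3), collapse = ", ")))
  }
  len <- gene_lengths[rownames(counts)]
  if (any(!is.finite(len)) || any(len <= 0)) {
    abort_value("gene lengths must be positive and finite")
  }
  rate <- counts / len
  denom <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(denom > 0, denom, 1), "/") * 1e6
  tpm[, denom == 0] <- 0
  dimnames(tpm) <- dimnames(counts)
  tpm
}

#' Upper-quartile normalisation of an intensity matrix
#'
#' Scales every sample so its 75th percentile of positive (non-missing) values
#' equals the geometric mean of the raw per-sample 75th percentiles. Zeros and
#' `NA` entries are preserved. The standard normalisation for label-free
#' proteomic intensities before detection-rule harmonisation.
#'
#' @param values Genes-by-samples numeric matrix; `NA` marks a missing
#'   measurement.
#' @return The normalised matrix.
#' @export
upper_quartile_normalize <- function(values) {
  values <- as.matrix(values)
  q75 <- apply(values, 2, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (length(v) == 0) return(NA_real_)
    stats::quantile(v, 0.75, names = FALSE)
  })
  if (anyNA(q75)) {
    bad <- colnames(values)[is.na(q75)]
    abort_value(sprintf("sample(s) with no positive value: %s",
                        paste(bad, collapse = ", ")))
  }
  target <- geomean(q75)
  sweep(values, 2, target / q75, "*")
}

#' Pairwise sample correlation
#'
#' Pearson correlation between all pairs of samples, by default on
#' `log2(x + 1)`-transformed values (the convention for TPM or m6A-level
#' matrices). Samples with zero variance produce flagged `NA` entries and a
#' warning rather than silently propagating NaN.
#'
#' @param values Genes-by-samples numeric matrix.
#' @param log_transform Apply `log2(x + 1)` first (default `TRUE`).
#' @return Symmetric correlation matrix with unit diagonal; degenerate samples
#'   (zero variance) are listed in the `degenerate_samples` attribute.
#' @export
sample_correlation <- function(values, log_transform = TRUE) {
  values <- as.matrix(values)
  if (ncol(values) < 2) abort_value("need at least two samples")
  m <- if (log_transform) log2(values + 1) else values
  sds <- apply(m, 2, stats::sd)
  degenerate <- colnames(m)[sds == 0]
  if (length(degenerate) > 0) {
    warning(sprintf("zero-variance sample(s): %s; correlations set to NA",
                    paste(degenerate, collapse = ", ")))
  }
  cc <- suppressWarnings(stats::cor(m, method = "pearson"))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc) <- 1
  attr(cc, "degenerate_samples") <- degenerate
  cc
}
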