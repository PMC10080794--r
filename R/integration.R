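# Multi-omics integration: detection-rule harmonisation for ribosome-profiling
# and proteomic matrices, translation-active ratios with a resampling null,
# exact 2x2 enrichment tests, and BH multiple-testing correction.

#' Detected genes from a detection matrix
#'
#' A gene is "detected" iff, in at least one stage, at least `min_reps`
#' replicates have a (non-missing) value strictly greater than `min_value`.
#' This is the shared rule for ribosome profiling (TPM) and proteomics
#' (normalised intensity, where `NA` marks a missing measurement).
#'
#' @param values Genes-by-samples matrix.
#' @param stages Stage label per column.
#' @param min_value Detection threshold on values (default 0, i.e. any
#'   positive signal).
#' @param min_reps Minimum replicates within a stage (default 2).
#' @param name Name of the returned set (default `"detected"`).
#' @return A [gene_set()] of detected genes.
#' @export
detected_gene_set <- function(values, stages, min_value = 0, min_reps = 2,
                              name = "detected") {
  if (min_value < 0) abort_value("min_value must be >= 0")
  values <- as.matrix(values)
  stages <- as.character(stages)
  hit <- !is.na(values) & values > min_value
  detected <- rep(FALSE, nrow(values))
  for (st in unique(stages)) {
    n_hit <- rowSums(hit[, stages == st, drop = FALSE])
    detected <- detected | n_hit >= min_reps
  }
  gene_set(name, rownames(values)[detected])
}

#' Translation-active ratio of a gene set
#'
#' Fraction of a gene set that is also in the detected set (e.g. detected by
#' ribosome profiling), with both counts reported.
#'
#' @param gs Query [gene_set()] (non-empty).
#' @param detected Detected-gene [gene_set()].
#' @return A list: `ratio` in \[0, 1\], `n_active`, `n_total`.
#' @export
translation_active_ratio <- function(gs, detected) {
  stopifnot(inherits(gs, "gene_set"), inherits(detected, "gene_set"))
  if (length(gs$members) == 0) abort_value("gene set is empty")
  n_active <- length(intersect(gs$members, detected$members))
  list(ratio = n_active / length(gs$members),
       n_active = n_active,
       n_total = length(gs$members))
}

#' Resampling null for a detection ratio
#'
#' Draws `n_iter` random gene sets of size `n` uniformly without replacement
#' from the universe, computes each draw's detected fraction, and (when an
#' observed ratio is supplied) the empirical upper-tail p-value
#' `(1 + #{null >= observed}) / (1 + n_iter)`. Reproducible given `seed`; the
#' caller's RNG state is untouched.
#'
#' @param n Size of the resampled sets.
#' @param universe Universe [gene_set()] to draw from.
#' @param detected Detected-gene [gene_set()].
#' @param n_iter Number of draws (default 1000).
#' @param seed Integer seed.
#' @param observed Optional observed ratio for which to report the p-value.
#' @return A list: `null` (vector of length `n_iter`), `null_mean`, and,
#'   when `observed` is given, `observed` and `p_value`.
#' @export
resample_ratio_null <- function(n, universe, detected, n_iter = 1000, seed,
                                observed = NULL) {
  stopifnot(inherits(universe, "gene_set"), inherits(detected, "gene_set"))
  if (n_iter < 1) abort_value("n_iter must be >= 1")
  n_univ <- length(universe$members)
  if (n > n_univ) {
    abort_value(sprintf("cannot draw %d genes from a universe of %d", n, n_univ))
  }
  is_detected <- universe$members %in% detected$members
  null <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      mean(is_detected[sample.int(n_univ, n)])
    }, numeric(1))
  })
  out <- list(null = null, null_mean = mean(null))
  if (!is.null(observed)) {
    out$observed <- observed
    out$p_value <- (1 + sum(null >= observed)) / (1 + n_iter)
  }
  out
}

#' Exact 2x2 enrichment test
#'
#' Two-sided Fisher exact p-value (sum of hypergeometric tables with
#' probability no larger than the observed table's) and the sample odds ratio,
#' Haldane-corrected (0.5 added to every cell) when any cell is zero.
#'
#' @param table2x2 A 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return A list: `odds_ratio`, `p_value`.
#' @export
enrichment_test <- function(table2x2) {
  m <- as.matrix(table2x2)
  if (!all(dim(m) == c(2, 2))) abort_value("expected a 2x2 table")
  if (any(m < 0) || any(m != round(m))) {
    abort_value("cells must be non-negative integers")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort_value("margins must be positive")
  }
  p <- stats::fisher.test(m)$p.value
  if (any(m == 0)) m <- m + 0.5
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction. Undefined (`NA`) entries are
#' passed through unchanged and do not count toward the number of tests.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort_value("p-values must lie in [0, 1]")
  }
  out <- pvalues
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}
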