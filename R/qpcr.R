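# qPCR quantification: delta-delta-Ct relative expression, RIP percent-input,
# and spike-in MeRIP signal-to-noise. Amplification efficiency is fixed at 2
# (perfect doubling per cycle); replicate Cts are averaged arithmetically
# before exponentiation, the conventional ddCt procedure.

#' Validate and normalise a Ct record table
#' @keywords internal
#' @noRd
validate_ct_records <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("target", "condition", "fraction_kind", "ct", "replicate")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf("Ct table lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(records$ct))) abort_value("all Ct values must be finite")
  bad_kind <- setdiff(unique(records$fraction_kind), c("total", "IP", "input"))
  if (length(bad_kind) > 0) {
    abort_schema(sprintf("unknown fraction_kind: %s",
                         paste(bad_kind, collapse = ", ")))
  }
  key <- paste(records$target, records$condition, records$fraction_kind,
               records$replicate)
  if (anyDuplicated(key)) {
    abort_schema("duplicate (target, condition, fraction_kind, replicate) row")
  }
  records
}

.mean_ct <- function(records, target, condition, kind) {
  ct <- records$ct[records$target == target &
                     records$condition == condition &
                     records$fraction_kind == kind]
  if (length(ct) == 0) return(NA_real_)
  mean(ct)
}

#' Delta-delta-Ct relative expression
#'
#' `RQ = 2^-[(Ct_target - Ct_ref)_condition - (Ct_target - Ct_ref)_baseline]`,
#' with replicate Cts averaged first; the baseline condition has RQ 1 by
#' construction. The reference gene (loading control, e.g. Actb) must be
#' measured in every condition.
#'
#' @param records Ct table (`target`, `condition`, `fraction_kind`, `ct`,
#'   `replicate`); only `fraction_kind == "total"` rows are used.
#' @param target Target amplicon id.
#' @param reference_gene Loading-control amplicon id (default `"Actb"`).
#' @param baseline_condition Condition with RQ fixed at 1 (default `"Ctrl"`).
#' @return A tibble (`condition`, `delta_ct`, `ddct`, `rq`).
#' @export
ddct_relative_expression <- function(records, target, reference_gene = "Actb",
                                     baseline_condition = "Ctrl") {
  records <- validate_ct_records(records)
  records <- records[records$fraction_kind == "total", , drop = FALSE]
  conditions <- unique(records$condition[records$target == target])
  if (!baseline_condition %in% conditions) {
    abort_value(sprintf("baseline condition '%s' has no Ct for target '%s'",
                        baseline_condition, target))
  }
  dct <- vapply(conditions, function(cond) {
    ct_t <- .mean_ct(records, target, cond, "total")
    ct_r <- .mean_ct(records, reference_gene, cond, "total")
    if (is.na(ct_r)) {
      abort_value(sprintf("reference gene '%s' missing in condition '%s'",
                          reference_gene, cond))
    }
    ct_t - ct_r
  }, numeric(1))
  ddct <- dct - dct[[baseline_condition]]
  tibble::tibble(condition = conditions,
                 delta_ct = unname(dct),
                 ddct = unname(ddct),
                 rq = 2^(-unname(ddct)))
}

#' RIP percent-input
#'
#' Recovery of a transcript by immunoprecipitation relative to the
#' dilution-adjusted input aliquot:
#' `%input = 100 * 2^[(Ct_input - log2(1/f)) - Ct_IP]` where `f` is the
#' fraction of lysate set aside as input (e.g. 0.1 for a 10% input).
#'
#' @param records Ct table with `IP` and `input` fraction rows.
#' @param target Target amplicon id.
#' @param input_fraction Input aliquot fraction in (0, 1\] (default 0.1).
#' @param condition Condition to quantify (default the single condition
#'   present).
#' @return Percent of input recovered (numeric scalar).
#' @export
percent_input <- function(records, target, input_fraction = 0.1,
                          condition = NULL) {
  records <- validate_ct_records(records)
  if (input_fraction <= 0 || input_fraction > 1) {
    abort_value("input_fraction must lie in (0, 1]")
  }
  if (is.null(condition)) {
    conds <- unique(records$condition[records$target == target])
    if (length(conds) != 1) {
      abort_value("multiple conditions present; specify `condition`")
    }
    condition <- conds
  }
  ct_ip <- .mean_ct(records, target, condition, "IP")
  ct_in <- .mean_ct(records, target, condition, "input")
  if (is.na(ct_ip) || is.na(ct_in)) {
    abort_value(sprintf("target '%s' needs both IP and input Cts in '%s'",
                        target, condition))
  }
  adjusted_input <- ct_in - log2(1 / input_fraction)
  100 * 2^(adjusted_input - ct_ip)
}

#' Spike-in MeRIP signal-to-noise ratio
#'
#' Percent-input recovery of the m6A-modified spike-in divided by that of the
#' unmodified spike-in; a selectivity of 1 means no enrichment.
#'
#' @param records Ct table containing both spike-ins in IP and input fractions.
#' @param positive,negative Spike-in amplicon ids (defaults `"GFP"` m6A+ and
#'   `"mCherry"` m6A-).
#' @param input_fraction Input aliquot fraction (default 0.1).
#' @param condition Optional condition (defaults as in [percent_input()]).
#' @return The SN ratio; `Inf` with a warning when the negative spike-in's
#'   recovery is exactly zero.
#' @export
spikein_sn_ratio <- function(records, positive = "GFP", negative = "mCherry",
                             input_fraction = 0.1, condition = NULL) {
  pos <- percent_input(records, positive, input_fraction, condition)
  neg <- percent_input(records, negative, input_fraction, condition)
  if (neg == 0) {
    warning("negative spike-in recovery is zero; SN ratio reported as Inf")
    return(Inf)
  }
  pos / neg
}
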