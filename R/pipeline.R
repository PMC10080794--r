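#' Pipeline configuration
#'
#' Bundles every threshold the workflow uses, with the field's published
#' defaults: stage p-value 0.05, NA-fallback log2FC 2, minimum input count 1
#' (strictly exceeded), replicate consensus 2, ZGA fold-change 5, knockdown
#' DEG p-value 0.05 and |log2FC| 1, detection in at least 2 replicates of one
#' stage.
#'
#' @param p_call Stage-level Wald p threshold for m6A calls.
#' @param lfc_na NA-fallback log2FC threshold.
#' @param min_input_count Input raw count must strictly exceed this.
#' @param consensus Replicate consensus for a stage call.
#' @param pseudocount Pseudocount for per-replicate log2FCs.
#' @param prior_sd Prior SD of the shrunken relative m6A level.
#' @param zga_fc Strict ZGA TPM fold-change threshold.
#' @param deg_p,deg_lfc Knockdown DEG thresholds.
#' @param detection_reps Replicates required for detection.
#' @param n_iter Resampling-null iterations.
#' @param seed Seed for the resampling null.
#' @param n_replicates Replicate count the consensus must not exceed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(p_call = 0.05, lfc_na = 2, min_input_count = 1,
                            consensus = 2, pseudocount = 0.5, prior_sd = 1,
                            zga_fc = 5, deg_p = 0.05, deg_lfc = 1,
                            detection_reps = 2, n_iter = 1000, seed = 1,
                            n_replicates = 3) {
  thr <- c(p_call = p_call, lfc_na = lfc_na, consensus = consensus,
           pseudocount = pseudocount, prior_sd = prior_sd, zga_fc = zga_fc,
           deg_p = deg_p, deg_lfc = deg_lfc, detection_reps = detection_reps,
           n_iter = n_iter)
  if (any(thr <= 0)) abort_value("all thresholds must be positive")
  if (min_input_count < 0) abort_value("min_input_count must be >= 0")
  if (consensus > n_replicates) {
    abort_value(sprintf("consensus (%d) cannot exceed replicate count (%d)",
                        consensus, n_replicates))
  }
  structure(list(p_call = p_call, lfc_na = lfc_na,
                 min_input_count = min_input_count, consensus = consensus,
                 pseudocount = pseudocount, prior_sd = prior_sd,
                 zga_fc = zga_fc, deg_p = deg_p, deg_lfc = deg_lfc,
                 detection_reps = detection_reps, n_iter = n_iter,
                 seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "pipeline_config")
}

#' Run the end-to-end m6A/MZT workflow
#'
#' Executes, in order: m6A calling with replicate consensus, cross-stage
#' dynamics classification and Sankey counts, ZGA calling and m6A overlap,
#' mRNA coupling, detection-set integration with the resampling null, and
#' (when knockdown data is supplied) the DEG test and its m6A overlap. All
#' randomness flows from `config$seed`; reruns with the same inputs and seeds
#' are identical.
#'
#' @param dataset An [omics_dataset()] with IP/input (and optionally rna)
#'   samples across the three stages.
#' @param config A [pipeline_config()].
#' @param ribo,ribo_stages Optional ribosome-profiling detection matrix and
#'   its per-column stage labels.
#' @param kd_dataset Optional control-vs-knockdown [omics_dataset()].
#' @param out_dir Optional directory: stage tables are written as TSVs and the
#'   report as JSON.
#' @return A list: `calls`, `sets`, `dynamics`, `zga`, `coupling`,
#'   `integration`, `degs`, and `report` (plain named list of sizes, ratios
#'   and thresholds).
#' @export
run_pipeline <- function(dataset, config = pipeline_config(), ribo = NULL,
                         ribo_stages = NULL, kd_dataset = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(dataset, "omics_dataset"),
            inherits(config, "pipeline_config"))

  calls <- call_m6a(dataset,
                    p_threshold = config$p_call,
                    lfc_na_threshold = config$lfc_na,
                    min_input_count = config$min_input_count,
                    consensus = config$consensus,
                    pseudocount = config$pseudocount,
                    prior_sd = config$prior_sd)
  sets <- m6a_gene_sets(calls)

  dyn <- classify_dynamics(calls)

  input_cols <- dataset$samples$assay == "input"
  tpm <- counts_to_tpm(dataset$counts[, input_cols, drop = FALSE],
                       dataset$gene_lengths)
  st_tpm <- stage_mean_tpm(tpm, dataset$samples$stage[input_cols],
                           dataset$stage_levels)
  zga <- detect_zga(st_tpm, fc_threshold = config$zga_fc)
  zga_ov <- zga_m6a_overlap(zga, sets[["L2C"]], wave = "major")

  coup_loss <- couple_mrna_change(dyn$records, st_tpm, "MII", "L1C")
  coup_gain <- couple_mrna_change(dyn$records, st_tpm, "L1C", "L2C")

  integration <- NULL
  if (!is.null(ribo)) {
    detected <- detected_gene_set(ribo, ribo_stages,
                                  min_reps = config$detection_reps,
                                  name = "ribo_detected")
    universe <- gene_set("universe", rownames(dataset$counts))
    inherited <- gene_set("inherited",
                          dyn$records$gene_id[dyn$records$category ==
                                                "inherited"])
    integration <- list(detected = detected)
    if (length(inherited$members) > 0) {
      tar <- translation_active_ratio(inherited, detected)
      null <- resample_ratio_null(tar$n_total, universe, detected,
                                  n_iter = config$n_iter, seed = config$seed,
                                  observed = tar$ratio)
      integration$inherited_ratio <- tar
      integration$null_mean <- null$null_mean
      integration$empirical_p <- null$p_value
    }
  }

  degs <- NULL
  deg_m6a_overlap <- NULL
  if (!is.null(kd_dataset)) {
    degs <- de_test(kd_dataset, p_threshold = config$deg_p,
                    lfc_threshold = config$deg_lfc)
    down <- gene_set("down_degs", degs$gene_id[degs$status == "down"])
    deg_m6a_overlap <- overlap_venn(list(down, sets$m6A_any))
  }

  report <- list(
    thresholds = unclass(config),
    n_genes = nrow(dataset$counts),
    set_sizes = lapply(sets, function(s) length(s$members)),
    category_counts = as.list(table(dyn$records$category)),
    sankey = dyn$sankey,
    n_minor_zga = sum(zga$minor_zga),
    n_major_zga = sum(zga$major_zga),
    major_zga_m6a = zga_ov[c("n_zga", "n_overlap", "n_without_m6a",
                             "fraction_m6a")],
    n_loss_down = length(coup_loss$sets$loss_down$members),
    n_gain_up = length(coup_gain$sets$gain_up$members))
  if (!is.null(integration) && !is.null(integration$inherited_ratio)) {
    report$inherited_translation_ratio <- integration$inherited_ratio$ratio
    report$inherited_translation_p <- integration$empirical_p
    report$null_mean_ratio <- integration$null_mean
  }
  if (!is.null(degs)) {
    report$n_degs <- sum(degs$status != "ns")
    report$n_down <- sum(degs$status == "down")
    report$n_up <- sum(degs$status == "up")
    report$down_m6a_overlap <-
      deg_m6a_overlap$count[deg_m6a_overlap$down_degs &
                              deg_m6a_overlap$m6A_any]
  }

  result <- list(calls = calls, sets = sets, dynamics = dyn, zga = zga,
                 coupling = list(loss = coup_loss, gain = coup_gain),
                 integration = integration, degs = degs, report = report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(calls, file.path(out_dir, "calls.tsv"), progress = FALSE)
    readr::write_tsv(dyn$records, file.path(out_dir, "dynamics.tsv"),
                     progress = FALSE)
    readr::write_tsv(zga, file.path(out_dir, "zga.tsv"), progress = FALSE)
    if (!is.null(degs)) {
      readr::write_tsv(degs, file.path(out_dir, "degs.tsv"), progress = FALSE)
    }
    for (s in sets) {
      write_gene_set(s, file.path(out_dir, paste0("set_", s$name, ".txt")))
    }
    json_report <- report
    json_report$sankey <- NULL
    jsonlite::write_json(json_report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
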