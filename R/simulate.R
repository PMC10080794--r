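# Synthetic multi-omics generator with known ground truth: stage-structured
# expression trajectories, per-gene m6A status and enrichment, NB-distributed
# IP/input/rna counts, detection matrices for ribosome profiling and
# proteomics linked to m6A inheritance, knockdown counts, and qPCR Ct tables.
# One global seed expands into per-component substreams so changing one
# stage's draws does not reshuffle the others.

#' Simulation configuration
#'
#' Defaults define the study conditions the generator emulates: three stages
#' (MII, L1C, L2C) times three replicates of paired IP/input libraries at one
#' million reads each, NB dispersion 0.10, category proportions mirroring the
#' field's observed partition of the transcriptome (about 5.6% maternal loss,
#' 3.5% inherited, 7.2% de novo gain, 3.2% transient, the rest untagged),
#' m6A enrichment of mean 3 log2 units (sd 0.5), a 5-fold maternal mRNA decay,
#' a 10-fold zygotic burst, a 0.5 probability that an m6A change is coupled to
#' the mRNA change ("about half"), and translation-detection propensities of
#' 0.92 / 0.70 / 0.46 for inherited / other m6A-tagged / untagged genes at
#' full link strength.
#'
#' @param n_genes Number of genes (default 5000).
#' @param n_replicates Replicates per stage and assay (default 3).
#' @param library_size Expected reads per library (default 1e6).
#' @param dispersion NB dispersion alpha (default 0.10).
#' @param proportions Named category proportions summing to 1.
#' @param enrichment_mean,enrichment_sd Log2 IP/input enrichment of m6A-tagged
#'   genes (defaults 3, 0.5).
#' @param maternal_decay_fold Expression decay fold for coupled maternal-loss
#'   genes (default 5).
#' @param zga_burst_fold Expression burst fold for coupled de novo / ZGA genes
#'   (default 10).
#' @param mrna_coupling Probability an m6A gain/loss is coupled to an mRNA
#'   change (default 0.5).
#' @param zga_extra_frac Fraction of untagged genes given a pure-ZGA burst
#'   (default 0.06).
#' @param link_strength Inheritance-translation link in \[0, 1\]; 0 makes
#'   detection independent of category (default 1).
#' @param detection_base Baseline detection propensity (default 0.46).
#' @param kd_n_genes,kd_lfc Number of knockdown-affected genes and their log2
#'   effect (defaults 200, -2).
#' @param ct_sd Ct measurement noise, cycles (default 0.2).
#' @param ct_intercept Ct of one abundance unit (default 32).
#' @param expr_meanlog,expr_sdlog Log-normal baseline expression parameters
#'   (defaults log(10), 1).
#' @param seed Global seed (default 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000,
                       n_replicates = 3,
                       library_size = 1e6,
                       dispersion = 0.10,
                       proportions = c(maternal_loss = 0.056,
                                       inherited = 0.035,
                                       de_novo_gain = 0.072,
                                       transient = 0.032,
                                       untagged = 0.805),
                       enrichment_mean = 3,
                       enrichment_sd = 0.5,
                       maternal_decay_fold = 5,
                       zga_burst_fold = 10,
                       mrna_coupling = 0.5,
                       zga_extra_frac = 0.06,
                       link_strength = 1,
                       detection_base = 0.46,
                       kd_n_genes = 200,
                       kd_lfc = -2,
                       ct_sd = 0.2,
                       ct_intercept = 32,
                       expr_meanlog = log(10),
                       expr_sdlog = 1,
                       seed = 1) {
  cats <- c("maternal_loss", "inherited", "de_novo_gain", "transient",
            "untagged")
  if (!setequal(names(proportions), cats)) {
    abort_value(sprintf("proportions must be named: %s",
                        paste(cats, collapse = ", ")))
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort_value("category proportions must sum to 1")
  }
  scales <- c(n_genes = n_genes, n_replicates = n_replicates,
              library_size = library_size, dispersion = dispersion,
              enrichment_mean = enrichment_mean,
              maternal_decay_fold = maternal_decay_fold,
              zga_burst_fold = zga_burst_fold)
  if (any(scales <= 0)) abort_value("all scale parameters must be positive")
  if (link_strength < 0 || link_strength > 1) {
    abort_value("link_strength must lie in [0, 1]")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    library_size = library_size, dispersion = dispersion,
    proportions = proportions[cats],
    enrichment_mean = enrichment_mean, enrichment_sd = enrichment_sd,
    maternal_decay_fold = maternal_decay_fold,
    zga_burst_fold = zga_burst_fold,
    mrna_coupling = mrna_coupling, zga_extra_frac = zga_extra_frac,
    link_strength = link_strength, detection_base = detection_base,
    kd_n_genes = as.integer(kd_n_genes), kd_lfc = kd_lfc,
    ct_sd = ct_sd, ct_intercept = ct_intercept,
    expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
    seed = as.integer(seed)), class = "sim_config")
}

.stage_pattern <- list(
  maternal_loss = c(TRUE, FALSE, FALSE),
  inherited = c(TRUE, TRUE, TRUE),
  de_novo_gain = c(FALSE, FALSE, TRUE),
  transient = c(FALSE, TRUE, FALSE),
  untagged = c(FALSE, FALSE, FALSE))

#' Simulate per-gene ground truth
#'
#' Draws each gene's dynamics category at the configured proportions, assigns
#' the matching per-stage m6A status pattern and a log2 enrichment effect,
#' builds stage-coupled expression trajectories (maternal decay after m6A
#' loss, zygotic bursts under de novo gain, plus a fraction of pure-ZGA genes
#' without the mark), sets the inheritance-linked translation propensity, and
#' marks knockdown-affected genes. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A tibble (`gene_id`, `category`, `m6a_MII`, `m6a_L1C`, `m6a_L2C`,
#'   `enrichment`, `expr_MII`, `expr_L1C`, `expr_L2C`,
#'   `translation_propensity`, `kd_effect`, `length`), class `sim_truth`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "truth"), {
    n <- config$n_genes
    cats <- names(config$proportions)
    category <- sample(cats, n, replace = TRUE, prob = config$proportions)
    pat <- t(vapply(category, function(cc) .stage_pattern[[cc]], logical(3)))
    colnames(pat) <- c("m6a_MII", "m6a_L1C", "m6a_L2C")

    tagged <- category != "untagged"
    enrichment <- ifelse(
      tagged,
      pmax(stats::rnorm(n, config$enrichment_mean, config$enrichment_sd), 0.5),
      0)

    base <- stats::rlnorm(n, config$expr_meanlog, config$expr_sdlog)
    expr <- matrix(base, n, 3,
                   dimnames = list(NULL, c("expr_MII", "expr_L1C", "expr_L2C")))
    coupled <- stats::runif(n) < config$mrna_coupling
    # Maternal-loss genes coupled to decay lose expression after MII.
    dec <- category == "maternal_loss" & coupled
    expr[dec, "expr_L1C"] <- expr[dec, "expr_L1C"] / config$maternal_decay_fold
    expr[dec, "expr_L2C"] <- expr[dec, "expr_L2C"] / config$maternal_decay_fold
    # De novo gain coupled to transcription bursts at the major wave.
    burst <- category == "de_novo_gain" & coupled
    expr[burst, "expr_MII"] <- expr[burst, "expr_MII"] / config$zga_burst_fold
    expr[burst, "expr_L1C"] <- expr[burst, "expr_L1C"] / config$zga_burst_fold
    # Pure-ZGA genes: an untagged slice silent before the major wave.
    pure_zga <- category == "untagged" &
      stats::runif(n) < config$zga_extra_frac
    expr[pure_zga, "expr_MII"] <- expr[pure_zga, "expr_MII"] / config$zga_burst_fold
    expr[pure_zga, "expr_L1C"] <- expr[pure_zga, "expr_L1C"] / config$zga_burst_fold

    s <- config$link_strength
    target_prop <- ifelse(category == "inherited", 0.92,
                          ifelse(tagged, 0.70, config$detection_base))
    propensity <- 0.5 + s * (target_prop - 0.5)

    kd_effect <- rep(0, n)
    kd_pool <- which(tagged)
    n_kd <- min(config$kd_n_genes, length(kd_pool))
    if (n_kd > 0) {
      kd_effect[kd_pool[sample.int(length(kd_pool), n_kd)]] <- config$kd_lfc
    }

    len <- round(stats::rlnorm(n, log(2000), 0.5))
    truth <- tibble::tibble(
      gene_id = sprintf("g%05d", seq_len(n)),
      category = category,
      m6a_MII = pat[, 1], m6a_L1C = pat[, 2], m6a_L2C = pat[, 3],
      enrichment = enrichment,
      expr_MII = expr[, 1], expr_L1C = expr[, 2], expr_L2C = expr[, 3],
      translation_propensity = propensity,
      kd_effect = kd_effect,
      length = pmax(len, 200))
    class(truth) <- c("sim_truth", class(truth))
    truth
  })
}

# NB sampler for one library given per-gene expected shares.
#' @noRd
.sample_library <- function(weights, library_size, dispersion, depth_factor) {
  mu <- weights / sum(weights) * library_size * depth_factor
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate IP, input and RNA count libraries
#'
#' Input and rna libraries draw NB counts around each gene's expression share
#' of the library; IP libraries multiply the share by `2^enrichment` for
#' m6A-tagged genes at that stage before renormalising to the library size.
#' Per-library depth varies log-normally (sd 0.1) so size-factor estimation is
#' exercised. Deterministic given the config seed.
#'
#' @param truth A [simulate_truth()] table.
#' @param config The matching [sim_config()].
#' @return An [omics_dataset()] with IP, input and rna samples for the three
#'   stages, plus gene lengths.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "counts"), {
    stages <- c("MII", "L1C", "L2C")
    n <- nrow(truth)
    cols <- list()
    meta <- list()
    for (st in stages) {
      expr <- truth[[paste0("expr_", st)]]
      m6a <- truth[[paste0("m6a_", st)]]
      ip_w <- expr * 2^(truth$enrichment * m6a)
      for (r in seq_len(config$n_replicates)) {
        depth_in <- stats::rlnorm(1, 0, 0.1)
        depth_ip <- stats::rlnorm(1, 0, 0.1)
        depth_rna <- stats::rlnorm(1, 0, 0.1)
        id_in <- sprintf("%s_input_%d", st, r)
        id_ip <- sprintf("%s_IP_%d", st, r)
        id_rna <- sprintf("%s_rna_%d", st, r)
        cols[[id_in]] <- .sample_library(expr, config$library_size,
                                         config$dispersion, depth_in)
        cols[[id_ip]] <- .sample_library(ip_w, config$library_size,
                                         config$dispersion, depth_ip)
        cols[[id_rna]] <- .sample_library(expr, config$library_size,
                                          config$dispersion, depth_rna)
        meta[[id_in]] <- list(st, "input", r)
        meta[[id_ip]] <- list(st, "IP", r)
        meta[[id_rna]] <- list(st, "rna", r)
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- truth$gene_id
    samples <- tibble::tibble(
      sample_id = names(meta),
      stage = vapply(meta, `[[`, character(1), 1),
      assay = vapply(meta, `[[`, character(1), 2),
      replicate = vapply(meta, function(x) as.integer(x[[3]]), integer(1)))
    lengths <- stats::setNames(truth$length, truth$gene_id)
    omics_dataset(counts, samples, lengths)
  })
}

#' Simulate a control-vs-knockdown RNA-seq dataset
#'
#' Control libraries draw from the L2C expression profile; knockdown libraries
#' multiply affected genes' expression by `2^kd_effect`. Deterministic given
#' the config seed.
#'
#' @inheritParams simulate_counts
#' @return An [omics_dataset()] of `rna` samples at L2C with a `group` column
#'   (`Ctrl` / `KD`).
#' @export
simulate_kd_counts <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "kd"), {
    expr <- truth$expr_L2C
    kd_expr <- expr * 2^truth$kd_effect
    cols <- list()
    for (r in seq_len(config$n_replicates)) {
      cols[[sprintf("Ctrl_rna_%d", r)]] <-
        .sample_library(expr, config$library_size, config$dispersion,
                        stats::rlnorm(1, 0, 0.1))
      cols[[sprintf("KD_rna_%d", r)]] <-
        .sample_library(kd_expr, config$library_size, config$dispersion,
                        stats::rlnorm(1, 0, 0.1))
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- truth$gene_id
    samples <- tibble::tibble(
      sample_id = names(cols),
      stage = "L2C",
      assay = "rna",
      replicate = as.integer(sub(".*_(\\d+)$", "\\1", names(cols))),
      group = sub("_rna_\\d+$", "", names(cols)))
    omics_dataset(counts, samples,
                  stats::setNames(truth$length, truth$gene_id))
  })
}

#' Simulate detection matrices and a qPCR Ct table
#'
#' Ribosome-profiling TPM and proteomic intensity matrices: per stage and
#' replicate, each gene is detected with its translation propensity; detected
#' entries carry log-normal signal around the gene's expression (intensities
#' use `NA` dropout, ribo uses 0). The Ct table covers knockdown validation
#' (`total` fraction, Ctrl vs KD, target plus Actb reference) and a spike-in
#' MeRIP experiment (GFP m6A+ with 20-fold recovery over mCherry m6A-) with
#' `Ct = intercept - log2(abundance) + N(0, ct_sd)`. Deterministic given the
#' config seed.
#'
#' @inheritParams simulate_counts
#' @param kd_targets Gene ids quantified in the knockdown Ct table (default:
#'   three affected genes from the truth, when present).
#' @return A list: `ribo` (matrix), `ribo_stages`, `protein` (matrix),
#'   `protein_stages`, `ct` (tibble of Ct records).
#' @export
simulate_detection_and_ct <- function(truth, config, kd_targets = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  n <- nrow(truth)
  stages <- c("MII", "L1C", "L2C")
  det <- with_seed(substream_seed(config$seed, "detection"), {
    nrep <- config$n_replicates
    ribo <- matrix(0, n, 3 * nrep)
    prot <- matrix(NA_real_, n, 3 * nrep)
    labels <- character(3 * nrep)
    # Translation activity is a gene-level state (drawn once, with the
    # propensity set by m6A inheritance); individual libraries then miss an
    # active gene with a small dropout probability. This keeps detection
    # correlated across replicates and stages, as in real profiling data.
    active <- stats::runif(n) < truth$translation_propensity
    k <- 0
    for (st in stages) {
      expr <- truth[[paste0("expr_", st)]]
      for (r in seq_len(nrep)) {
        k <- k + 1
        labels[k] <- st
        hit <- active & stats::runif(n) < 0.9
        signal <- expr * stats::rlnorm(n, 0, 0.3)
        ribo[hit, k] <- signal[hit]
        prot[hit, k] <- signal[hit] * 1e4
      }
    }
    colnames(ribo) <- sprintf("%s_ribo_%d", rep(stages, each = nrep),
                              rep(seq_len(nrep), 3))
    colnames(prot) <- sprintf("%s_protein_%d", rep(stages, each = nrep),
                              rep(seq_len(nrep), 3))
    rownames(ribo) <- rownames(prot) <- truth$gene_id
    list(ribo = ribo, prot = prot, labels = labels)
  })

  ct <- with_seed(substream_seed(config$seed, "ct"), {
    nrep <- config$n_replicates
    if (is.null(kd_targets)) {
      kd_targets <- utils::head(truth$gene_id[truth$kd_effect != 0], 3)
    }
    noise <- function(k) stats::rnorm(k, 0, config$ct_sd)
    ct_of <- function(abundance, k) {
      config$ct_intercept - log2(abundance) + noise(k)
    }
    rows <- list()
    add <- function(target, condition, kind, abundance) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        target = target, condition = condition, fraction_kind = kind,
        ct = ct_of(abundance, nrep), replicate = seq_len(nrep))
    }
    # Knockdown validation: target mRNAs shift by kd_effect, Actb is stable.
    for (g in kd_targets) {
      expr <- truth$expr_L2C[truth$gene_id == g]
      eff <- truth$kd_effect[truth$gene_id == g]
      add(g, "Ctrl", "total", expr)
      add(g, "KD", "total", expr * 2^eff)
    }
    add("Actb", "Ctrl", "total", 100)
    add("Actb", "KD", "total", 100)
    # Spike-in MeRIP: both spike-ins at equal input abundance; IP recovers
    # 10% of the modified spike-in and 1/20 of that for the unmodified one,
    # measured against a 10% input aliquot.
    spike_in <- 1
    input_aliquot <- 0.1
    for (sp in c(GFP = 20, mCherry = 1)) {
      name <- if (sp == 20) "GFP" else "mCherry"
      add(name, "MII", "input", spike_in * input_aliquot)
      add(name, "MII", "IP", spike_in * 0.10 * sp / 20)
    }
    dplyr::bind_rows(rows)
  })

  list(ribo = det$ribo, ribo_stages = det$labels,
       protein = det$prot, protein_stages = det$labels,
       ct = ct)
}

#' Write a complete synthetic dataset to TSV files
#'
#' Generates truth, counts, knockdown counts, detection matrices and Ct table
#' for one config and writes them as plain TSVs (`counts.tsv`, `samples.tsv`,
#' `lengths.tsv`, `kd_counts.tsv`, `kd_samples.tsv`, `ribo_tpm.tsv`,
#' `protein.tsv`, `ct.tsv`, `truth.tsv`).
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return Invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(config, dir) {
  truth <- simulate_truth(config)
  ds <- simulate_counts(truth, config)
  kd <- simulate_kd_counts(truth, config)
  det <- simulate_detection_and_ct(truth, config)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(ds, dir)
  kd_counts <- tibble::tibble(gene_id = rownames(kd$counts))
  kd_counts <- cbind(kd_counts, tibble::as_tibble(kd$counts))
  readr::write_tsv(kd_counts, file.path(dir, "kd_counts.tsv"), progress = FALSE)
  readr::write_tsv(kd$samples, file.path(dir, "kd_samples.tsv"),
                   progress = FALSE)
  write_matrix <- function(m, path) {
    df <- tibble::tibble(gene_id = rownames(m))
    df <- cbind(df, tibble::as_tibble(m))
    readr::write_tsv(df, path, progress = FALSE)
  }
  write_matrix(det$ribo, file.path(dir, "ribo_tpm.tsv"))
  write_matrix(det$protein, file.path(dir, "protein.tsv"))
  readr::write_tsv(det$ct, file.path(dir, "ct.tsv"), progress = FALSE)
  readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(list(truth = truth, dataset = ds, kd = kd, detection = det))
}
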