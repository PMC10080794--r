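test_that("truth categories land within binomial bounds and obey the config", {
  cfg <- sim_config(seed = 2)
  truth <- simulate_truth(cfg)
  counts <- table(factor(truth$category, levels = names(cfg$proportions)))
  for (cc in names(cfg$proportions)) {
    p <- cfg$proportions[[cc]]
    bound <- 2.58 * sqrt(cfg$n_genes * p * (1 - p))  # 99% binomial interval
    expect_lt(abs(counts[[cc]] - cfg$n_genes * p), bound + 1)
  }
  # enrichment positive exactly where tagged; category matches the pattern
  tagged <- truth$category != "untagged"
  expect_true(all(truth$enrichment[tagged] > 0))
  expect_true(all(truth$enrichment[!tagged] == 0))
  expect_true(all(truth$m6a_MII[truth$category == "maternal_loss"]))
  expect_false(any(truth$m6a_L2C[truth$category == "maternal_loss"]))
  expect_true(all(truth$m6a_MII[truth$category == "inherited"] &
                    truth$m6a_L1C[truth$category == "inherited"] &
                    truth$m6a_L2C[truth$category == "inherited"]))
  # zero inherited proportion means no (1,1,1) pattern
  cfg0 <- sim_config(seed = 2, proportions = c(
    maternal_loss = 0.1, inherited = 0, de_novo_gain = 0.15,
    transient = 0.02, untagged = 0.73))
  t0 <- simulate_truth(cfg0)
  expect_false(any(t0$m6a_MII & t0$m6a_L1C & t0$m6a_L2C))
  # invalid proportions rejected
  expect_error(sim_config(proportions = c(
    maternal_loss = 0.5, inherited = 0.1, de_novo_gain = 0.1,
    transient = 0.1, untagged = 0.1)), class = "mztm6a_value_error")
})

test_that("generators are bit-reproducible and substreams are independent", {
  cfg <- sim_config(seed = 42, n_genes = 300)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1, t2)
  d1 <- simulate_counts(t1, cfg)
  d2 <- simulate_counts(t1, cfg)
  expect_identical(d1$counts, d2$counts)
  det1 <- simulate_detection_and_ct(t1, cfg)
  det2 <- simulate_detection_and_ct(t1, cfg)
  expect_identical(det1$ct$ct, det2$ct$ct)
  # different seeds change the draw
  t3 <- simulate_truth(sim_config(seed = 43, n_genes = 300))
  expect_false(identical(t1$category, t3$category))
})

test_that("IP counts carry the configured enrichment, input stays neutral", {
  cfg <- sim_config(seed = 6, n_genes = 2000, dispersion = 0.02,
                    enrichment_mean = 3, enrichment_sd = 1e-6)
  truth <- simulate_truth(cfg)
  ds <- simulate_counts(truth, cfg)
  pick <- function(assay, stage) {
    ds$counts[, ds$samples$assay == assay & ds$samples$stage == stage]
  }
  sf_in <- colSums(pick("input", "MII"))
  sf_ip <- colSums(pick("IP", "MII"))
  in_norm <- rowMeans(sweep(pick("input", "MII"), 2, sf_in / mean(sf_in), "/"))
  ip_norm <- rowMeans(sweep(pick("IP", "MII"), 2, sf_ip / mean(sf_ip), "/"))
  tagged <- truth$m6a_MII
  hi <- truth$expr_MII > stats::quantile(truth$expr_MII, 0.5)
  obs_lfc <- log2((ip_norm + 0.5) / (in_norm + 0.5))
  # tagged genes are near the configured effect minus the renormalisation
  # shift common to the whole IP library; untagged genes sit at that shift
  shift <- stats::median(obs_lfc[!tagged & hi])
  expect_equal(stats::median(obs_lfc[tagged & hi]) - shift, 3,
               tolerance = 0.25)
})

test_that("doubling the library size leaves normalised means stable", {
  cfg1 <- sim_config(seed = 10, n_genes = 1000, library_size = 1e6)
  cfg2 <- sim_config(seed = 10, n_genes = 1000, library_size = 2e6)
  truth <- simulate_truth(cfg1)
  d1 <- simulate_counts(truth, cfg1)
  d2 <- simulate_counts(truth, cfg2)
  m1 <- d1$counts[, d1$samples$assay == "input"]
  m2 <- d2$counts[, d2$samples$assay == "input"]
  n1 <- sweep(m1, 2, compute_size_factors(m1), "/")
  n2 <- sweep(m2, 2, compute_size_factors(m2), "/")
  hi <- rowMeans(n1) > 50
  ratio <- rowMeans(n2[hi, ]) / rowMeans(n1[hi, ]) / 2
  expect_equal(stats::median(ratio), 1, tolerance = 0.02)
})

test_that("noise-free Cts recover the configured knockdown exactly", {
  cfg <- sim_config(seed = 3, n_genes = 500, ct_sd = 0, kd_lfc = -1)
  truth <- simulate_truth(cfg)
  det <- simulate_detection_and_ct(truth, cfg)
  target <- truth$gene_id[truth$kd_effect != 0][1]
  rq <- ddct_relative_expression(det$ct, target)
  expect_equal(rq$rq[rq$condition == "KD"], 0.5, tolerance = 1e-12)
})

test_that("full-propensity inherited genes are always translation-detected", {
  cfg <- sim_config(seed = 9, n_genes = 400, link_strength = 1)
  truth <- simulate_truth(cfg)
  truth$translation_propensity[truth$category == "inherited"] <- 1
  det <- simulate_detection_and_ct(truth, cfg)
  detected <- detected_gene_set(det$ribo, det$ribo_stages)
  inh <- gene_set("inh", truth$gene_id[truth$category == "inherited"])
  expect_equal(translation_active_ratio(inh, detected)$ratio, 1)
})

test_that("a simulated bundle writes and reloads as plain TSVs", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 5, n_genes = 120)
  out <- simulate_dataset(cfg, dir)
  expect_true(all(file.exists(file.path(
    dir, c("counts.tsv", "samples.tsv", "lengths.tsv", "kd_counts.tsv",
           "kd_samples.tsv", "ribo_tpm.tsv", "protein.tsv", "ct.tsv",
           "truth.tsv")))))
  back <- load_dataset(file.path(dir, "counts.tsv"),
                       file.path(dir, "samples.tsv"),
                       file.path(dir, "lengths.tsv"))
  expect_identical(back$counts, out$dataset$counts)
})
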