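test_that("dispersion estimation recovers simulated truth", {
  grp <- rep(c("input", "IP"), each = 3)
  # Poisson data: median estimate essentially zero
  set.seed(1)
  cnt <- sapply(1:6, function(j) rpois(2000, 500))
  dimnames(cnt) <- list(sprintf("g%04d", 1:2000), sprintf("s%d", 1:6))
  a <- estimate_dispersions(cnt, compute_size_factors(cnt), grp)
  expect_lte(median(a), 0.01)
  # NB alpha = 0.5: median recovered within [0.3, 0.7]
  set.seed(1)
  mu <- rlnorm(2000, log(200), 1)
  cnt2 <- sapply(1:6, function(j) rnbinom(2000, mu = mu, size = 2))
  dimnames(cnt2) <- dimnames(cnt)
  a2 <- estimate_dispersions(cnt2, compute_size_factors(cnt2), grp)
  expect_gte(median(a2), 0.3)
  expect_lte(median(a2), 0.7)
  # constant gene hits the floor
  cnt3 <- rbind(k1 = rep(5L, 6), cnt[1:500, ])
  a3 <- estimate_dispersions(cnt3, rep(1, 6), grp)
  expect_equal(unname(a3["k1"]), 1e-8)
  expect_true(all(a3 >= 1e-8))
})

test_that("NB Wald test recovers a 4x enrichment and flags untestable genes", {
  set.seed(7)
  G <- 1000
  cnt <- cbind(sapply(1:3, function(j) rnbinom(G, mu = 200, size = 100)),
               sapply(1:3, function(j) rnbinom(G, mu = 800, size = 100)))
  dimnames(cnt) <- list(sprintf("g%04d", 1:G), sprintf("s%d", 1:6))
  cnt[1, ] <- 0L  # untestable gene
  grp <- factor(rep(c("input", "IP"), each = 3), levels = c("input", "IP"))
  res <- nb_wald_test(cnt, grp, size_factors = rep(1, 6))
  expect_true(is.na(res$wald_p[1]))
  expect_equal(res$log2fc[1], 0)
  expect_equal(mean(res$log2fc[-1]), 2, tolerance = 0.1)
  expect_gt(mean(res$wald_p[-1] < 0.05), 0.99)
  expect_true(all(res$se[-1] > 0))
})

test_that("Wald p-values are calibrated on exchangeable groups", {
  set.seed(7)
  G <- 2000
  mu <- rlnorm(G, log(200), 1)
  cnt <- sapply(1:6, function(j) rnbinom(G, mu = mu, size = 10))
  dimnames(cnt) <- list(sprintf("g%04d", 1:G), sprintf("s%d", 1:6))
  grp <- factor(rep(c("input", "IP"), each = 3), levels = c("input", "IP"))
  res <- nb_wald_test(cnt, grp)
  frac <- mean(res$wald_p < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.08)
})

test_that("log2FC estimates agree with DESeq2 on a shared fixture", {
  suppressMessages(suppressWarnings(requireNamespace("DESeq2")))
  set.seed(21)
  G <- 300
  enrich <- sample(c(0, 2), G, replace = TRUE)
  cnt <- cbind(sapply(1:3, function(j) rnbinom(G, mu = 100, size = 10)),
               sapply(1:3, function(j) rnbinom(G, mu = 100 * 2^enrich,
                                               size = 10)))
  dimnames(cnt) <- list(sprintf("g%04d", 1:G), sprintf("s%d", 1:6))
  grp <- factor(rep(c("input", "IP"), each = 3), levels = c("input", "IP"))
  res <- nb_wald_test(cnt, grp)

  dds <- DESeq2::DESeqDataSetFromMatrix(
    cnt, S4Vectors::DataFrame(condition = grp), ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  dr <- DESeq2::results(dds)
  expect_gt(cor(res$log2fc, dr$log2FoldChange, use = "complete.obs"), 0.95)
  both <- !is.na(res$wald_p) & !is.na(dr$pvalue)
  agree <- (res$wald_p[both] < 0.05) == (dr$pvalue[both] < 0.05)
  expect_gt(mean(agree), 0.85)
})

test_that("LFC shrinkage is a contraction with the documented limits", {
  res <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                        log2fc = c(2, 3, -4, 5),
                        se = c(1, 1e-6, 10, NA),
                        wald_p = c(0.01, 0.001, 0.5, NA))
  s <- shrink_lfc(res, prior_sd = 1, fallback_lfc = c(0, 0, 0, 1.5))
  expect_equal(s[1], 1.0)                    # closed-form posterior mean
  expect_equal(s[2], 3, tolerance = 1e-9)    # se -> 0 keeps the estimate
  expect_lt(abs(s[3]), 0.1)                  # se >> prior collapses to 0
  expect_equal(s[4], 1.5)                    # undefined p uses the fallback
  ok <- !is.na(res$wald_p)
  expect_true(all(abs(s[ok]) <= abs(res$log2fc[ok])))
  expect_error(shrink_lfc(res, prior_sd = 0), class = "mztm6a_value_error")
})

test_that("knockdown DE labels follow the p and |log2FC| rule", {
  cfg <- sim_config(seed = 5, n_genes = 1500, kd_n_genes = 100)
  truth <- simulate_truth(cfg)
  kd <- simulate_kd_counts(truth, cfg)
  degs <- de_test(kd)
  # status is a pure function of (p, lfc)
  sig_dn <- !is.na(degs$wald_p) & degs$wald_p < 0.05 & degs$log2fc < -1
  expect_identical(degs$status == "down", sig_dn)
  affected <- truth$gene_id[truth$kd_effect != 0]
  rec <- mean(degs$status[match(affected, degs$gene_id)] == "down")
  expect_gte(rec, 0.8)
  # missing group column is an error
  ds <- toy_ipinput_dataset(n_genes = 5, stages = "MII")
  expect_error(de_test(ds), class = "mztm6a_value_error")
})
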