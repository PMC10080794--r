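test_that("per-replicate log2FC follows the pseudocounted normalised ratio", {
  ds <- toy_ipinput_dataset(n_genes = 10, n_rep = 3, stages = "MII")
  pr <- per_replicate_lfc(ds, "MII")
  expect_equal(dim(pr$lfc), c(10, 3))
  # identity: ip == input with unit size factors gives 0
  cnt <- ds$counts
  cnt[] <- 50L
  ds0 <- omics_dataset(cnt, ds$samples, ds$gene_lengths)
  pr0 <- per_replicate_lfc(ds0, "MII")
  expect_true(all(pr0$lfc == 0))
  # hand arithmetic: 31.5 vs 7.5 with c = 0.5 -> log2(32/8) = 2
  expect_equal(log2((31.5 + 0.5) / (7.5 + 0.5)), 2)
  # zero/zero is 0 by pseudocount symmetry
  expect_equal(log2((0 + 0.5) / (0 + 0.5)), 0)
  # unpaired replicate is an error listing the orphan
  drop <- ds$samples$sample_id != "MII_IP_2"
  ds2 <- omics_dataset(ds$counts[, drop], ds$samples[drop, ],
                       ds$gene_lengths)
  expect_error(per_replicate_lfc(ds2, "MII"), "2",
               class = "mztm6a_value_error")
})

test_that("the m6A decision rule fires on exactly the documented branches", {
  # one gene per branch; three replicates with identical values
  lfc_rows <- list(
    sig_pos    = c(1.2, 1.2, 1.2),   # p<0.05, lfc>0, input>1 -> called
    low_input  = c(3.0, 3.0, 3.0),   # input = 1 not > 1 -> not called
    na_hi      = c(2.5, 2.5, 2.5),   # p NA, lfc>2 -> called
    na_lo      = c(1.9, 1.9, 1.9),   # p NA, lfc<=2 -> not called
    sig_neg    = c(-0.5, -0.5, -0.5),# p<0.05 but lfc<0 -> not called
    ns_pos     = c(1.2, 1.2, 1.2))   # p>=0.05 -> not called
  rep_lfc <- do.call(rbind, lfc_rows)
  input <- matrix(5, nrow(rep_lfc), 3, dimnames = dimnames(rep_lfc))
  input["low_input", ] <- 1
  res <- tibble::tibble(
    gene_id = rownames(rep_lfc),
    base_mean = 10, log2fc = 1, se = 0.5,
    wald_p = c(0.01, 0.001, NA, NA, 0.01, 0.2),
    dispersion = 0.1)
  tab <- call_m6a_stage(rep_lfc, input, res, "MII")
  called <- stats::setNames(tab$stage_called, tab$gene_id)
  expect_true(called["sig_pos"])
  expect_false(called["low_input"])
  expect_true(called["na_hi"])
  expect_false(called["na_lo"])
  expect_false(called["sig_neg"])
  expect_false(called["ns_pos"])
})

test_that("stage consensus needs at least two replicate calls", {
  rep_lfc <- rbind(two_of_three = c(1, 1, -1),
                   one_of_three = c(1, -1, -1),
                   three        = c(1, 1, 1))
  input <- matrix(10, 3, 3, dimnames = dimnames(rep_lfc))
  res <- tibble::tibble(gene_id = rownames(rep_lfc), base_mean = 10,
                        log2fc = 1, se = 0.5, wald_p = 0.01, dispersion = 0.1)
  tab <- call_m6a_stage(rep_lfc, input, res, "MII")
  expect_equal(tab$n_rep_called, c(2L, 1L, 3L))
  expect_equal(tab$stage_called, c(TRUE, FALSE, TRUE))
  # dropping any one replicate never un-calls a 3-of-3 gene
  for (drop in 1:3) {
    sub <- call_m6a_stage(rep_lfc[, -drop], input[, -drop], res, "MII")
    expect_true(sub$stage_called[sub$gene_id == "three"])
  }
  # a single replicate cannot reach the consensus, with a warning
  expect_warning(
    one <- call_m6a_stage(rep_lfc[, 1, drop = FALSE],
                          input[, 1, drop = FALSE], res, "MII"),
    "unreachable")
  expect_false(any(one$stage_called))
})

test_that("replicate calls are monotone in the replicate log2FC", {
  input <- matrix(10, 1, 3, dimnames = list("g", NULL))
  res <- tibble::tibble(gene_id = "g", base_mean = 10, log2fc = 1, se = 0.5,
                        wald_p = 0.01, dispersion = 0.1)
  grid <- seq(-2, 4, by = 0.25)
  calls <- vapply(grid, function(l) {
    call_m6a_stage(matrix(l, 1, 3, dimnames = list("g", NULL)),
                   input, res, "MII")$stage_called
  }, logical(1))
  expect_true(all(diff(as.integer(calls)) >= 0))
})

test_that("stronger true enrichment never lowers caller sensitivity", {
  sens <- vapply(c(1.5, 3), function(eff) {
    cfg <- sim_config(seed = 17, n_genes = 800, enrichment_mean = eff,
                      enrichment_sd = 1e-6)
    truth <- simulate_truth(cfg)
    ds <- simulate_counts(truth, cfg)
    sets <- m6a_gene_sets(call_m6a(ds))
    tagged <- truth$gene_id[truth$category != "untagged"]
    mean(tagged %in% sets$m6A_any$members)
  }, numeric(1))
  expect_gte(sens[2], sens[1])
})

test_that("stage sets, union and complement partition the universe", {
  ds <- toy_ipinput_dataset(n_genes = 60, seed = 9,
                            enrich_log2 = rep(c(0, 3), each = 30))
  calls <- call_m6a(ds)
  sets <- m6a_gene_sets(calls)
  expect_named(sets, c("MII", "L1C", "L2C", "m6A_any", "m6A_neg"),
               ignore.order = TRUE)
  union_stages <- unique(unlist(lapply(c("MII", "L1C", "L2C"),
                                       function(s) sets[[s]]$members)))
  expect_setequal(sets$m6A_any$members, union_stages)
  expect_length(intersect(sets$m6A_any$members, sets$m6A_neg$members), 0)
  expect_setequal(c(sets$m6A_any$members, sets$m6A_neg$members),
                  rownames(ds$counts))
})
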