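make_calls <- function(patterns) {
  # patterns: named list gene -> logical c(MII, L1C, L2C)
  rows <- lapply(names(patterns), function(g) {
    tibble::tibble(gene_id = g, stage = c("MII", "L1C", "L2C"),
                   stage_called = patterns[[g]])
  })
  dplyr::bind_rows(rows)
}

test_that("every stage-call pattern maps to its documented category", {
  patterns <- list(
    loss = c(TRUE, FALSE, FALSE),
    inh = c(TRUE, TRUE, TRUE),
    gain_l2c = c(FALSE, FALSE, TRUE),
    gain_l1c_l2c = c(FALSE, TRUE, TRUE),
    trans_l1c = c(FALSE, TRUE, FALSE),
    trans_mii_l2c = c(TRUE, FALSE, TRUE),
    trans_mii_l1c = c(TRUE, TRUE, FALSE),
    none = c(FALSE, FALSE, FALSE))
  dyn <- classify_dynamics(make_calls(patterns))
  cat <- stats::setNames(dyn$records$category, dyn$records$gene_id)
  expect_equal(unname(cat["loss"]), "maternal_loss")
  expect_equal(unname(cat["inh"]), "inherited")
  expect_equal(unname(cat["gain_l2c"]), "de_novo_gain")
  expect_equal(unname(cat["gain_l1c_l2c"]), "de_novo_gain")
  expect_equal(unname(cat[c("trans_l1c", "trans_mii_l2c", "trans_mii_l1c")]),
               rep("transient", 3))
  expect_equal(unname(cat["none"]), "untagged")
  # raw patterns kept for regrouping
  expect_setequal(dyn$records$pattern[dyn$records$category == "transient"],
                  c("010", "101", "110"))
  # categories partition the universe
  expect_equal(sum(table(dyn$records$category)), length(patterns))
  # a gene missing one stage is an error
  bad <- make_calls(patterns)[-1, ]
  expect_error(classify_dynamics(bad), class = "mztm6a_value_error")
})

test_that("sankey transition counts are conserved at each boundary", {
  set.seed(4)
  patterns <- lapply(1:40, function(i) sample(c(TRUE, FALSE), 3, TRUE))
  names(patterns) <- sprintf("g%02d", 1:40)
  dyn <- classify_dynamics(make_calls(patterns))
  sk <- dyn$sankey
  for (i in 1:2) {
    expect_equal(sk$kept[i] + sk$lost[i] + sk$gained[i] + sk$absent[i], 40)
  }
  n_mii <- sum(vapply(patterns, `[`, logical(1), 1))
  expect_equal(sk$kept[1] + sk$lost[1], n_mii)
  n_l1c <- sum(vapply(patterns, `[`, logical(1), 2))
  expect_equal(sk$kept[1] + sk$gained[1], n_l1c)
  expect_equal(sk$kept[2] + sk$lost[2], n_l1c)
})

test_that("ZGA calls use strict pseudocounted fold-change thresholds", {
  tpm <- rbind(minor = c(1, 10, 10),
               major = c(5, 2, 20),
               boundary = c(1, 5.4, 5.4),
               silent = c(0, 0, 0))
  colnames(tpm) <- c("MII", "L1C", "L2C")
  z <- detect_zga(tpm)
  expect_true(z$minor_zga[z$gene_id == "minor"])   # (10.1)/(1.1) ~ 9.2
  expect_true(z$major_zga[z$gene_id == "major"])   # (20.1)/(2.1) ~ 9.6
  # (5.4+0.1)/(1+0.1) = 5 exactly: strict inequality keeps it out
  expect_false(z$minor_zga[z$gene_id == "boundary"])
  expect_false(any(z$minor_zga[z$gene_id == "silent"],
                   z$major_zga[z$gene_id == "silent"]))
  expect_true(all(is.finite(z$fc_l1c_mii)))
  # invariant to a common rescaling of all TPM columns (away from the exact
  # threshold boundary, where floating point decides)
  off <- tpm[c("minor", "major", "silent"), ]
  z1 <- detect_zga(off)
  z2 <- detect_zga(off * 3, pseudocount = 0.3)
  expect_equal(z2$minor_zga, z1$minor_zga)
  expect_equal(z2$major_zga, z1$major_zga)
})

test_that("mRNA coupling emits the loss-down and gain-up sets", {
  patterns <- list(loss_dn = c(TRUE, FALSE, FALSE),
                   loss_flat = c(TRUE, FALSE, FALSE),
                   gain_up = c(FALSE, FALSE, TRUE),
                   gain_dn = c(FALSE, FALSE, TRUE))
  dyn <- classify_dynamics(make_calls(patterns))
  tpm <- rbind(loss_dn = c(10, 4, 4),
               loss_flat = c(10, 10, 10),
               gain_up = c(1, 1, 8),
               gain_dn = c(8, 8, 2))
  colnames(tpm) <- c("MII", "L1C", "L2C")
  loss <- couple_mrna_change(dyn$records, tpm, "MII", "L1C")
  expect_setequal(loss$sets$loss_down$members, "loss_dn")
  gain <- couple_mrna_change(dyn$records, tpm, "L1C", "L2C")
  expect_setequal(gain$sets$gain_up$members, "gain_up")
  dir <- stats::setNames(gain$records$mrna_direction, gain$records$gene_id)
  expect_equal(unname(dir["loss_flat"]), "flat")
  expect_error(couple_mrna_change(dyn$records, tpm, "MII", "E8C"),
               class = "mztm6a_value_error")
  expect_error(couple_mrna_change(dyn$records, tpm, "MII", "L1C",
                                  fc_threshold = 0.5),
               class = "mztm6a_value_error")
})

test_that("ZGA/m6A overlap is exact set algebra", {
  zga <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                        fc_l1c_mii = 1, fc_l2c_l1c = c(9, 9, 9, 1),
                        minor_zga = FALSE, major_zga = c(TRUE, TRUE, TRUE, FALSE))
  ov <- zga_m6a_overlap(zga, gene_set("L2C", c("b", "c", "x")))
  expect_setequal(ov$overlap$members, c("b", "c"))
  expect_equal(ov$n_zga, 3)
  expect_equal(ov$n_without_m6a, 1)
  expect_equal(ov$fraction_m6a, 2 / 3)
  # disjoint sets
  ov0 <- zga_m6a_overlap(zga, gene_set("L2C", "zzz"))
  expect_equal(ov0$n_overlap, 0)
})

test_that("simulated ZGA-m6A coupling is recovered within ten points", {
  cfg <- sim_config(seed = 13, n_genes = 3000)
  truth <- simulate_truth(cfg)
  ds <- simulate_counts(truth, cfg)
  calls <- call_m6a(ds)
  sets <- m6a_gene_sets(calls)
  input_cols <- ds$samples$assay == "input"
  tpm <- counts_to_tpm(ds$counts[, input_cols], ds$gene_lengths)
  st <- stage_mean_tpm(tpm, ds$samples$stage[input_cols])
  zga <- detect_zga(st)
  ov <- zga_m6a_overlap(zga, sets$L2C)
  # truth: fraction of true major-ZGA genes (L1C->L2C burst) carrying L2C m6A
  burst <- truth$expr_L2C / truth$expr_L1C > 5
  truth_frac <- mean(truth$m6a_L2C[burst])
  expect_lt(abs(ov$fraction_m6a - truth_frac), 0.10)
})
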