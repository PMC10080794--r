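# Negative-binomial Wald machinery shared by the IP-vs-input m6A test and the
# knockdown differential-expression test. The observation model is
# count ~ NB(mu, alpha) with variance mu + alpha * mu^2, log link and the log
# size factor as offset; the tested coefficient is the log2 ratio between the
# two sample groups.

#' Per-gene NB dispersion estimates
#'
#' Method-of-moments dispersion on size-factor-normalised counts within each
#' condition, `alpha = (s^2 - mean) / mean^2`, averaged across conditions
#' (weighted by within-condition degrees of freedom), then shrunk 50% (on the
#' log scale) toward a robust log-linear mean--dispersion trend. Genes whose
#' moment estimate is non-positive (no evidence of overdispersion, e.g. a
#' constant gene) are floored at `alpha_min` directly.
#'
#' @param counts Genes-by-samples raw count matrix.
#' @param size_factors Positive per-sample factors (see
#'   [compute_size_factors()]).
#' @param design Factor or vector of condition labels, one per sample
#'   (e.g. IP / input).
#' @param alpha_min Lower dispersion floor (default `1e-8`).
#' @return Numeric vector of dispersions, one per gene, all `>= alpha_min`.
#' @export
estimate_dispersions <- function(counts, size_factors, design,
                                 alpha_min = 1e-8) {
  counts <- as.matrix(counts)
  design <- as.factor(design)
  norm <- sweep(counts, 2, size_factors, "/")

  usable <- levels(design)[table(design) >= 2]
  if (length(usable) == 0) {
    abort_value("dispersion estimation needs >= 2 replicates in some condition")
  }
  if (length(usable) < nlevels(design)) {
    warning("condition(s) with < 2 replicates ignored for dispersion estimation")
  }

  num <- rep(0, nrow(counts))
  wsum <- rep(0, nrow(counts))
  mean_all <- rep(0, nrow(counts))
  var_total <- rep(0, nrow(counts))
  df_total <- 0
  for (cond in usable) {
    nc <- norm[, design == cond, drop = FALSE]
    mu <- rowMeans(nc)
    v <- row_vars(nc)
    w <- ncol(nc) - 1
    df_total <- df_total + w
    ok <- mu > 0
    a <- ifelse(ok, (v - mu) / mu^2, NA_real_)
    num <- num + ifelse(ok, w * a, 0)
    wsum <- wsum + ifelse(ok, w, 0)
    mean_all <- mean_all + mu * ncol(nc)
    var_total <- var_total + v * w
  }
  mean_all <- mean_all / sum(design %in% usable)
  alpha_mom <- ifelse(wsum > 0, num / wsum, NA_real_)

  # Robust log-linear trend fit on genes with informative positive estimates.
  # The log of a few-df variance estimate is biased low by
  # digamma(df/2) - log(df/2); the trend intercept is corrected for this so
  # it tracks the dispersion itself rather than the skewed log-scale median.
  log_bias <- digamma(df_total / 2) - log(df_total / 2)
  fit_idx <- which(!is.na(alpha_mom) & alpha_mom > 0 & mean_all > 0)
  trend <- rep(NA_real_, nrow(counts))
  if (length(fit_idx) >= 10) {
    df <- data.frame(y = log(alpha_mom[fit_idx]), x = log(mean_all[fit_idx]))
    fit <- suppressWarnings(MASS::rlm(y ~ x, data = df, maxit = 50))
    pred_x <- ifelse(mean_all > 0, log(mean_all), mean(df$x))
    trend <- exp(stats::coef(fit)[1] + stats::coef(fit)[2] * pred_x - log_bias)
  } else if (length(fit_idx) > 0) {
    trend <- rep(exp(log(geomean(alpha_mom[fit_idx])) - log_bias),
                 nrow(counts))
  }
  trend <- pmax(trend, alpha_min)

  # Gene-wise estimates get the same log-bias correction, then a 50%
  # geometric shrink toward the trend. Genes with a non-positive moment
  # estimate but real spread fall back to the trend; genes with zero observed
  # variance (constant counts) are floored at alpha_min.
  alpha <- rep(alpha_min, nrow(counts))
  pos <- !is.na(alpha_mom) & alpha_mom > 0
  nonpos <- !is.na(alpha_mom) & alpha_mom <= 0
  zero_var <- nonpos & var_total == 0
  has_trend <- !is.na(trend)
  shrunk <- exp(0.5 * (log(alpha_mom[pos & has_trend]) - log_bias) +
                  0.5 * log(trend[pos & has_trend]))
  # With a handful of residual df, gene-wise estimates below the trend are
  # nearly always sampling noise; moderation is therefore asymmetric and the
  # trend acts as a floor (genes may exceed it on their own evidence).
  alpha[pos & has_trend] <- pmax(shrunk, trend[pos & has_trend])
  alpha[pos & !has_trend] <- exp(log(alpha_mom[pos & !has_trend]) - log_bias)
  idx <- nonpos & !zero_var & has_trend
  alpha[idx] <- trend[idx]
  alpha <- pmax(alpha, alpha_min)
  names(alpha) <- rownames(counts)
  alpha
}

# Vectorised IRLS fit of the two-group NB log-linear model across all genes at
# once. x is the 0/1 group indicator per sample; returns natural-log
# coefficient beta (group effect), its SE, and convergence info.
#' @keywords internal
#' @noRd
nb_irls_two_group <- function(counts, size_factors, x, dispersions,
                              maxit = 30, tol = 1e-8) {
  Y <- as.matrix(counts)
  n <- ncol(Y)
  G <- nrow(Y)
  sf <- rep(size_factors, length.out = n)
  xs <- as.numeric(x)
  log_sf <- log(sf)
  alpha <- rep(dispersions, length.out = G)

  norm <- sweep(Y, 2, sf, "/")
  mu0 <- rowMeans(norm[, xs == 0, drop = FALSE])
  mu1 <- rowMeans(norm[, xs == 1, drop = FALSE])
  b0 <- log(pmax(mu0, 1e-8))
  b1 <- log(pmax(mu1, 1e-8)) - b0

  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  b0 <- clamp(b0, -50, 50)
  b1 <- clamp(b1, -30, 30)

  A11 <- A12 <- A22 <- rep(NA_real_, G)
  for (it in seq_len(maxit)) {
    eta <- outer(b0, rep(1, n)) + outer(b1, xs) +
      matrix(log_sf, G, n, byrow = TRUE)
    eta <- clamp(eta, -60, 60)
    mu <- exp(eta)
    W <- mu / (1 + alpha * mu)
    Z <- (eta - matrix(log_sf, G, n, byrow = TRUE)) + (Y - mu) / mu
    A11 <- rowSums(W)
    A12 <- rowSums(W[, xs == 1, drop = FALSE])
    A22 <- A12
    B1 <- rowSums(W * Z)
    B2 <- rowSums((W * Z)[, xs == 1, drop = FALSE])
    det <- A11 * A22 - A12^2
    det_ok <- is.finite(det) & det > 1e-12
    new_b1 <- ifelse(det_ok, (A11 * B2 - A12 * B1) / det, b1)
    new_b0 <- ifelse(A11 > 0, (B1 - A12 * new_b1) / A11, b0)
    new_b0 <- clamp(new_b0, -50, 50)
    new_b1 <- clamp(new_b1, -30, 30)
    delta <- pmax(abs(new_b0 - b0), abs(new_b1 - b1))
    b0 <- new_b0
    b1 <- new_b1
    if (max(delta, na.rm = TRUE) < tol) break
  }

  det <- A11 * A22 - A12^2
  se <- ifelse(is.finite(det) & det > 1e-12, sqrt(A11 / det), Inf)
  list(beta0 = b0, beta = b1, se = se)
}

#' NB Wald test between two sample groups
#'
#' Fits, per gene, the NB log-linear model with log size-factor offset and a
#' two-level group coefficient; reports the group log2 fold-change, its
#' standard error, the two-sided normal (Wald) p-value, and the dispersion
#' used. Genes with zero counts in every sample are untestable: their p-value
#' is `NA` and their log2 fold-change 0.
#'
#' @param counts Genes-by-samples raw count matrix.
#' @param group Two-level factor/vector over samples; the coefficient is
#'   log2(second level / first level).
#' @param size_factors Optional per-sample factors; computed by
#'   [compute_size_factors()] when `NULL`.
#' @param dispersions Optional per-gene dispersions; estimated by
#'   [estimate_dispersions()] when `NULL`.
#' @return A tibble with columns `gene_id`, `base_mean`, `log2fc`, `se`,
#'   `wald_p`, `dispersion`.
#' @export
nb_wald_test <- function(counts, group, size_factors = NULL,
                         dispersions = NULL) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  if (nlevels(group) != 2) abort_value("group must have exactly two levels")
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, size_factors, group)
  }
  x <- as.integer(group == levels(group)[2])

  testable <- rowSums(counts) > 0
  fit <- nb_irls_two_group(counts[testable, , drop = FALSE],
                           size_factors, x[seq_len(ncol(counts))],
                           dispersions[testable])

  log2fc <- rep(0, nrow(counts))
  se <- rep(NA_real_, nrow(counts))
  wald_p <- rep(NA_real_, nrow(counts))
  log2fc[testable] <- fit$beta / log(2)
  se_t <- fit$se / log(2)
  se[testable] <- se_t
  z <- fit$beta / fit$se
  p <- 2 * stats::pnorm(-abs(z))
  p[!is.finite(z)] <- NA_real_
  wald_p[testable] <- p

  norm <- sweep(counts, 2, size_factors, "/")
  tibble::tibble(
    gene_id = rownames(counts),
    base_mean = rowMeans(norm),
    log2fc = log2fc,
    se = se,
    wald_p = wald_p,
    dispersion = unname(dispersions))
}

#' Stage-level IP-vs-input NB Wald test
#'
#' Subsets one developmental stage's IP and input libraries, computes size
#' factors and dispersions within that subset, and runs [nb_wald_test()] with
#' the coefficient oriented as IP over input.
#'
#' @param dataset An [omics_dataset()] holding IP and input samples.
#' @param stage Stage label, e.g. `"MII"`.
#' @return The [nb_wald_test()] tibble for that stage.
#' @export
nb_wald_stage_test <- function(dataset, stage) {
  stopifnot(inherits(dataset, "omics_dataset"))
  keep <- dataset$samples$stage == stage &
    dataset$samples$assay %in% c("IP", "input")
  if (!any(keep)) abort_value(sprintf("stage '%s' absent from dataset", stage))
  sub <- dataset$samples[keep, , drop = FALSE]
  if (!any(sub$assay == "IP") || !any(sub$assay == "input")) {
    abort_value(sprintf("stage '%s' needs both IP and input samples", stage))
  }
  counts <- dataset$counts[, keep, drop = FALSE]
  group <- factor(sub$assay, levels = c("input", "IP"))
  nb_wald_test(counts, group)
}

#' Shrink log2 fold-changes toward zero
#'
#' Normal-prior posterior mean: `lfc * prior_sd^2 / (prior_sd^2 + se^2)`. This
#' is the "adjusted" fold-change used as the per-stage relative m6A level;
#' noisy estimates (large SE) are pulled to zero, precise ones are left almost
#' untouched, so the result is always a contraction of the raw estimate.
#' Untestable genes (undefined p / SE) fall back to `fallback_lfc` when given,
#' else to the raw estimate.
#'
#' @param result Tibble from [nb_wald_test()] (needs `log2fc`, `se`, `wald_p`).
#' @param prior_sd Prior standard deviation in log2 units (default 1).
#' @param fallback_lfc Optional per-gene vector used where `wald_p` is `NA`
#'   (e.g. the mean per-replicate log2FC).
#' @return Numeric vector of shrunken log2 fold-changes.
#' @export
shrink_lfc <- function(result, prior_sd = 1, fallback_lfc = NULL) {
  if (!is.numeric(prior_sd) || prior_sd <= 0) {
    abort_value("prior_sd must be positive")
  }
  lfc <- result$log2fc
  se <- result$se
  shrunk <- lfc * prior_sd^2 / (prior_sd^2 + se^2)
  undef <- is.na(result$wald_p) | !is.finite(se)
  if (!is.null(fallback_lfc)) {
    shrunk[undef] <- fallback_lfc[undef]
  } else {
    shrunk[undef] <- lfc[undef]
  }
  shrunk
}

#' Knockdown differential-expression test
#'
#' Runs the NB Wald machinery with the sample `group` column as design
#' (knockdown over control) on the `rna` assay, adjusts p-values by
#' Benjamini-Hochberg, and labels genes `up` / `down` / `ns` by the
#' significance rule p < `p_threshold` and |log2FC| > `lfc_threshold`.
#'
#' @param dataset An [omics_dataset()] whose sample sheet has a `group` column
#'   with a control and a treatment level.
#' @param levels Length-2 character: control level then treatment level
#'   (default `c("Ctrl", "KD")`); the fold-change is treatment over control.
#' @param p_threshold,lfc_threshold Significance thresholds (defaults 0.05, 1).
#' @return A tibble (`gene_id`, `base_mean`, `log2fc`, `se`, `wald_p`, `padj`,
#'   `status`).
#' @export
de_test <- function(dataset, levels = c("Ctrl", "KD"),
                    p_threshold = 0.05, lfc_threshold = 1) {
  stopifnot(inherits(dataset, "omics_dataset"))
  if (!"group" %in% names(dataset$samples)) {
    abort_value("sample sheet has no 'group' column")
  }
  keep <- dataset$samples$assay == "rna" & dataset$samples$group %in% levels
  sub <- dataset$samples[keep, , drop = FALSE]
  for (lv in levels) {
    if (sum(sub$group == lv) < 2) {
      abort_value(sprintf("group '%s' needs >= 2 replicates", lv))
    }
  }
  res <- nb_wald_test(dataset$counts[, keep, drop = FALSE],
                      factor(sub$group, levels = levels))
  res$padj <- bh_adjust(res$wald_p)
  res$status <- dplyr::case_when(
    !is.na(res$wald_p) & res$wald_p < p_threshold &
      res$log2fc > lfc_threshold ~ "up",
    !is.na(res$wald_p) & res$wald_p < p_threshold &
      res$log2fc < -lfc_threshold ~ "down",
    TRUE ~ "ns")
  res$dispersion <- NULL
  res
}
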