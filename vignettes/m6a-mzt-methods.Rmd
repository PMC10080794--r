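---
title: "Methods: gene-level m6A calling and multi-omics integration across the MZT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-level m6A calling and multi-omics integration across the MZT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During the maternal-to-zygotic transition (MZT) the mouse embryo switches
from maternally deposited transcripts to its own transcriptional program.
N6-methyladenosine (m6A) marks on mRNA are implicated on both sides of that
handoff: tagging maternal transcripts for decay, and appearing de novo on
zygotically activated genes. Profiling m6A in oocytes and early embryos is a
low-input problem: gene-level immunoprecipitation (IP) libraries are compared
against matched input libraries at three stages — MII oocyte, late 1-cell
(L1C), late 2-cell (L2C) — with three replicates each.

`mztm6a` implements the full downstream analysis from gene-level count
matrices: normalisation, the IP-vs-input enrichment test, replicate-consensus
m6A calling, cross-stage dynamics classification, zygotic genome activation
(ZGA) calls, integration with translation/proteome detection sets through a
resampling null, knockdown differential expression, and qPCR validation
arithmetic — plus a synthetic-data generator with known ground truth so every
step is testable without any external download.

## Observation model and the enrichment test

Counts are modelled as negative binomial with a log link,

$$K_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g), \qquad
\mu_{gj} = s_j \, q_g \, 2^{\beta_g x_j}, \qquad
\mathrm{Var}(K_{gj}) = \mu_{gj} + \alpha_g \mu_{gj}^2,$$

where $s_j$ is the sample's size factor (median-of-ratios over genes with
nonzero counts in all samples; total-count ratios as fallback), $x_j$
indicates the IP libraries within a stage, and $\beta_g$ is the per-gene log2
IP/input enrichment. The coefficient is fit by per-gene IRLS (vectorised
across genes) and tested with a two-sided Wald z; genes with zero counts
across a whole stage are untestable and carry an `NA` p-value.

### Dispersion estimation

$\alpha_g$ is estimated by method of moments on size-factor-normalised counts
within each condition, $\hat\alpha_g = (s^2 - \bar\mu)/\bar\mu^2$, combined
across conditions with df weights. Three numerical choices matter with
triplicate designs:

- **Log-scale bias correction.** A variance estimate with $\nu$ df satisfies
  $E[\log s^2] = \log\sigma^2 + \psi(\nu/2) - \log(\nu/2)$; both the
  mean–dispersion trend (a robust `rlm` fit of $\log\hat\alpha$ on
  $\log\bar\mu$) and the gene-wise estimates are corrected by this digamma
  term. Without it the trend tracks the skewed log-scale median and the Wald
  test is anticonservative (observed null type-I near 0.10 at triplicate
  scale rather than the nominal 0.05).
- **Asymmetric moderation.** Each positive gene-wise estimate is shrunk 50%
  (geometrically) toward the trend, and the trend then acts as a floor. With
  four residual df, below-trend gene-wise values are almost entirely sampling
  noise; letting them pull the working dispersion down inflates false calls.
  Genes may still exceed the trend on their own evidence.
- **Degenerate genes.** A gene whose moment estimate is non-positive but
  whose counts vary falls back to the trend; a truly constant gene (zero
  observed variance at positive mean) is floored at
  $\alpha_{\min} = 10^{-8}$.

### Relative m6A level

The per-stage "relative m6A level" is the shrunken (adjusted) log2
fold-change: a normal-prior posterior mean
$\tilde\beta_g = \hat\beta_g \,\sigma_0^2 / (\sigma_0^2 + \mathrm{se}_g^2)$
with prior SD $\sigma_0 = 1$ log2 unit by default. It is a contraction
($|\tilde\beta| \le |\hat\beta|$ always): precise estimates keep their value,
noisy ones are pulled to zero. Untestable genes fall back to the mean
per-replicate log2FC.

## The m6A calling rule

The published decision rule mixes a stage-level quantity (the p-value, which
needs replication) with a per-replicate one ("identified in at least two of
the three replicates"). The package resolves this as: the **p-value is
stage-level** (the 3-vs-3 Wald test above) while the **fold-change entering
the rule is the per-replicate-pair log2FC**,

$$\mathrm{lfc}_{gr} = \log_2\frac{k^{IP}_{gr}/s^{IP}_r + c}{k^{in}_{gr}/s^{in}_r + c},$$

with pseudocount $c = 0.5$ guarding zero counts. Replicate $r$ calls gene $g$
iff its **raw** input count strictly exceeds 1 in that replicate and either

- the stage p-value is below 0.05 and $\mathrm{lfc}_{gr} > 0$, or
- the stage p-value is `NA` and $\mathrm{lfc}_{gr} > 2$.

A stage call needs at least 2 of 3 replicates; a gene is m6A-tagged overall
if called in at least one stage. "Read count > 1" is interpreted as the raw
count in the replicate being scored (configurable), and `NA` p-values arise
only from all-zero stages — no independent filtering or outlier handling is
layered on top, because nothing beyond that NA path is documented for the
rule. All thresholds are arguments of `call_m6a()` / `pipeline_config()`.

## Dynamics categories, ZGA, and mRNA coupling

With calls at the fixed stage order MII → L1C → L2C, each gene's call triple
maps deterministically to one of five categories: `(1,0,0)` maternal loss,
`(1,1,1)` inherited, `(0,0,1)`/`(0,1,1)` de novo gain, the remaining mixed
patterns transient, `(0,0,0)` untagged. De novo gain is defined as "not
called in MII but called in L2C" (with or without L1C); the raw 8-pattern
string is kept in the output so the narrower "gained between L1C and L2C
only" reading can be regrouped by the user. Sankey-style kept/lost/gained
counts are reported at both stage boundaries.

ZGA calls use stage-mean TPM (counts normalised by gene length and library,
columns summing to $10^6$): minor ZGA when
$(\mathrm{TPM}_{L1C}+c)/(\mathrm{TPM}_{MII}+c) > 5$ strictly, major ZGA for
the L2C/L1C ratio, with TPM pseudocount $c = 0.1$ keeping silent-MII genes —
the dominant ZGA case — finite. mRNA direction over a transition defaults to
the sign of change (threshold 1), since no magnitude threshold is published
for the "decreased/increased at mRNA level" groupings; the coupled sets
(maternal loss ∩ mRNA down, de novo gain ∩ mRNA up) are emitted.

## Multi-omics integration

A gene is "detected" in a ribosome-profiling or proteomic matrix iff at least
2 replicates of at least one stage exceed the detection threshold (default:
any positive, non-missing value — deliberately the minimal reading of
"detected"). Proteomic intensities are upper-quartile normalised first; the
anchor is the geometric mean of the raw per-sample 75th percentiles (the
published description does not fix an anchor; a common scalar keeps the
normalisation scale-free and symmetric across samples).

The translation-active ratio of a gene set is its detected fraction. Its
significance comes from a resampling null: `n_iter` uniform draws without
replacement of equally sized sets from the universe (default: all genes in
the expression matrix), with empirical p
$(1 + \#\{\text{null} \ge \text{observed}\})/(1 + n_{iter})$. Knockdown DEGs
use the same NB Wald machinery with the Ctrl/KD design, BH adjustment, and
status up/down at p < 0.05 and |log2FC| > 1. All 2×2 set enrichments use the
exact hypergeometric test (two-sided, summing tables no more probable than
the observed one) with a Haldane-corrected sample odds ratio; the chi-squared
variant is deliberately not offered, as the exact test dominates at these
table sizes.

## qPCR quantification

Amplification efficiency is fixed at 2 per cycle, and replicate Cts are
averaged before exponentiation (the conventional ΔΔCt procedure):

- relative expression
  $RQ = 2^{-[(Ct_{t} - Ct_{ref})_{cond} - (Ct_{t} - Ct_{ref})_{base}]}$,
  invariant to any constant instrument offset;
- RIP recovery
  $\%input = 100 \cdot 2^{(Ct_{input} - \log_2(1/f)) - Ct_{IP}}$ for an input
  aliquot fraction $f$ (halving $f$ raises the measured input Ct by one
  cycle, leaving the recovery unchanged);
- spike-in selectivity $SN = \%input(\text{m6A}^+)/\%input(\text{m6A}^-)$,
  the standard percent-input ratio of the modified versus unmodified control
  RNA.

## The synthetic-data generator

`sim_config()` fixes the emulated study: 5000 genes, 3 stages × 3 replicates
of paired IP/input plus RNA libraries at $10^6$ reads, NB dispersion 0.10,
and dynamics-category proportions (5.6% maternal loss, 3.5% inherited, 7.2%
de novo gain, 3.2% transient) chosen to mirror the observed partition of a
transcriptome of ~17k genes into ~1k/0.6k/1.2k/3.4k-scale classes. Tagged
genes carry log2 enrichment ~ N(3, 0.5) (truncated at 0.5); baseline
expression is log-normal (median ~10 units, sd 1 log); half of the
maternal-loss genes decay 5-fold after MII and half of the de-novo genes
burst 10-fold at L2C ("about half" of each class moves with the mark), with
an extra 6% of untagged genes getting a pure-ZGA burst. Translation activity
is a gene-level latent state with propensity 0.92 / 0.70 / 0.46 for inherited
/ other tagged / untagged genes at full link strength (0.5 for everyone at
link 0), and per-library dropout 0.1 — keeping detection correlated across
replicates, as in real profiling data. Knockdown affects 200 tagged genes at
log2FC −2. Ct values follow
$Ct = \text{intercept} - \log_2(\text{abundance}) + N(0, 0.2)$, with the
spike-in pair built to a 20-fold true IP selectivity. One global seed expands
into fixed substreams (truth / counts / knockdown / detection / Ct) so
changing one component's draw never reshuffles the others, and every
generator is bit-reproducible given the config.

What the generator deliberately does **not** emulate: positional (peak-level)
m6A, read-level artifacts upstream of counting, batch effects, correlated
gene–gene expression, antibody background that varies by sequence context,
and missing-not-at-random proteomic dropout beyond the detection link.
Passing recovery tests therefore demonstrates that the decision rules and
statistics behave as specified under the stated stochastic model — not that
the thresholds are optimal for any particular real dataset.

## Problem sizes and determinism

The test suite and the acceptance script run calibration at 2000 genes
(null simulations, dispersion recovery) and the end-to-end classification at
the 5000-gene default — sizes chosen so a desk run takes minutes while
binomial noise on the measured rates stays well inside the asserted bands.
Resampling nulls use 999 iterations. All simulation entry points take
explicit seeds; nothing reads global RNG state without restoring it.

## Known limitations

- The NB machinery is a documented, minimal Wald model: no Cook's-distance
  outlier handling, no independent filtering, no GLM ridge priors. It is
  calibrated for the replicate scales tested here, not a general-purpose
  replacement for mature DE frameworks.
- Gene identifiers are opaque strings; annotation (GO/KEGG) enrichment is
  supported only as a generic 2×2 exact test over user-supplied mappings.
- The length normalisation accepts any user-supplied length table; whether
  lengths are effective transcript lengths or annotated gene lengths is the
  caller's decision.
- qPCR efficiency is fixed at perfect doubling; no standard-curve
  calibration.
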