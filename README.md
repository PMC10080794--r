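# mztm6a

Gene-level m6A (N6-methyladenosine) analysis across the mouse
maternal-to-zygotic transition (MZT), for people working with low-input
IP/input immunoprecipitation sequencing of oocytes and early embryos
(MII oocyte → late 1-cell → late 2-cell).

The package implements the complete downstream workflow from gene-level count
matrices:

- **m6A calling.** Counts follow a negative-binomial model
  `K ~ NB(mu, alpha)`, `Var = mu + alpha mu^2`, with median-of-ratios size
  factors as offsets. Per stage, a Wald test of IP vs input gives the stage
  p-value; replicate `r` calls gene `g` iff its raw input count exceeds 1 and
  either `p < 0.05` with per-replicate `log2FC > 0`, or (when `p` is `NA`)
  `log2FC > 2`. A stage call needs ≥ 2 of 3 replicates; a gene is m6A-tagged
  if called in ≥ 1 stage. The per-stage "relative m6A level" is the shrunken
  log2FC (normal-prior posterior mean, prior SD 1).
- **Dynamics and ZGA.** Stage-call triples map to maternal loss `(1,0,0)`,
  inherited `(1,1,1)`, de novo gain `(0,0,1)/(0,1,1)`, transient, or
  untagged, with Sankey transition counts; minor/major ZGA genes have
  stage-mean TPM fold-change strictly above 5 (L1C/MII, L2C/L1C).
- **Integration.** Detection sets (≥ 2 replicates of ≥ 1 stage) from
  ribosome-profiling TPM and upper-quartile-normalised proteomic intensities;
  translation-active ratios with a gene-set resampling null; knockdown DEGs
  (`p < 0.05`, `|log2FC| > 1`, BH-adjusted); exact 2×2 enrichment tests.
- **qPCR.** ΔΔCt relative expression, RIP percent-input with dilution
  adjustment, and spike-in signal-to-noise ratios.
- **Synthetic data.** A fully seeded generator (`sim_config()`,
  `simulate_*()`) producing IP/input/RNA counts, knockdown counts, detection
  matrices and Ct tables with known per-gene ground truth, so every stage is
  testable offline.

See `vignettes/m6a-mzt-methods.Rmd` for the model, parameter defaults, and
numerical choices.

## Worked example

The `analysis/` directory is the narrative workflow; each script is a thin
driver over package functions and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # synthetic study with known truth
Rscript analysis/02_call_m6a.R      # per-stage m6A calls + gene sets
Rscript analysis/03_dynamics_zga.R  # dynamics categories, ZGA, coupling
Rscript analysis/04_integration.R   # translation/proteome integration, DEGs
Rscript analysis/05_qpcr.R          # ddCt and spike-in SN quantification
```

Output of steps 2–4 on the default simulation (5000 genes, 3 stages × 3
replicate pairs, seed 1):

```
MII: 516 m6A-tagged genes
L1C: 395 m6A-tagged genes
L2C: 561 m6A-tagged genes
m6A_any (>=1 stage): 1094 genes
recovery vs truth: sensitivity 99.8%, 105 false positives

minor ZGA: 1 genes; major ZGA: 403 genes
major-ZGA genes with L2C m6A: 183 of 403 (45.4%); 220 without

inherited  translation-active: 168/180 (93.3%)
m6a_pos    translation-active: 781/1094 (71.4%)
m6a_neg    translation-active: 1825/3906 (46.7%)
total      translation-active: 2606/5000 (52.1%)
random sets of 180 genes: mean ratio 52.0%; observed 93.3% (empirical p = 0.001)
down-regulated DEGs carrying m6A: 196/217 (90.3%)
```

Reading this: the caller recovers essentially all simulated m6A-tagged genes;
about 45% of major-ZGA genes carry the L2C mark (the generator's coupling);
and consistently inherited m6A genes are far more translation-active (93.3%)
than equally sized random gene sets (52.0%), with the resampling null putting
that difference at its minimum attainable empirical p (0.001 at 999 draws) —
the same qualitative contrast the workflow is designed to quantify on real
detection matrices.

Equivalent calls from R:

```r
library(mztm6a)
cfg   <- sim_config(seed = 1)
truth <- simulate_truth(cfg)
ds    <- simulate_counts(truth, cfg)
calls <- call_m6a(ds)            # one row per gene x stage
sets  <- m6a_gene_sets(calls)    # per-stage, m6A_any, m6A_neg
dyn   <- classify_dynamics(calls)
table(dyn$records$category)
```

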