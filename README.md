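# prolifmeta

Multi-cohort meta-analysis of proliferation-linked gene-expression
biomarkers in censored survival studies.

## The problem

In multi-cohort tumour transcriptomics (typically breast cancer), a
candidate biomarker gene often predicts early relapse — but so does tumour
proliferation, and many candidate genes are themselves proliferation-driven.
Distinguishing a *direct* prognostic effect from one that is merely
*mediated by proliferation* requires (i) an expression-based estimate of
each tumour's proliferation rate, (ii) per-cohort effect estimates that are
comparable across heterogeneous microarray/RNA-seq platforms, and (iii) a
principled way to pool them. `prolifmeta` implements that workflow
end-to-end:

- **Proliferation signature** — derived as the intersection of genes called
  serum-responsive by a regularized (Cyber-T-style) two-sample *t*-test at
  FDR *q* (Benjamini–Hochberg) with an external cell-cycle gene set; each
  signature gene *g* is weighted by its serum-response log₂ fold change
  *w₉*. Per-sample scores are the |w|-normalized weighted sum of
  cohort-mean-centered expression:
  scoreⱼ = Σ₉ w₉·x̃₉ⱼ / Σ₉ |w₉|.
- **HER2 approximation** — COPA-style outlier calling on ERBB2 expression:
  positive iff x > median + 1.5·MAD (consistency-scaled MAD by default).
- **Per-cohort effects** — Pearson correlations (Fisher z, se = 1/√(n−3))
  and per-SD Cox log hazard ratios (Efron ties, Newton–Raphson, gene
  standardized within cohort, follow-up administratively censored at a
  60-month horizon), optionally adjusted for the proliferation score.
- **Meta-analysis** — inverse-variance pooling; Cochran's Q with
  p < 0.05 gates the switch from the fixed-effect to the
  DerSimonian–Laird random-effects model
  (τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))).
- **Evaluation** — Harrell's concordance index with exact pair accounting,
  pooled across cohorts by sample-size weighting.
- **Synthetic cohorts** — a generator with a latent per-sample
  proliferation score P ~ N(0,1) driving a gene block
  (x₉ⱼ = μ₉ + a₉ + β₉Pⱼ + ε₉ⱼ, per-cohort platform offsets a₉),
  an ERBB2 outlier mixture for HER2+ samples, and exponential survival with
  hazard λ·exp(γP + θx_marker) under uniform censoring — so every pipeline
  stage can be validated against known ground truth, including the
  mediation scenario (θ = 0: the marker's survival effect exists only
  through P).

## Worked example

Five synthetic cohorts of 150 samples, 1000 genes (100 proliferation
genes), hazard slope γ = 0.4 per SD of latent proliferation, marker genes
with loadings 1 (PGRMC1, TMEM97) and 0.3 (LDLR), and *no* direct marker
effect on hazard (θ = 0, the fully mediated scenario):

```r
library(prolifmeta)

cfg <- simulationConfig(n_cohorts = 5, samples_per_cohort = 150,
                        n_genes = 1000, n_proliferation_genes = 100,
                        log_hazard_per_sd = 0.4, seed = 42)
pc  <- pipelineConfig(sim_config = cfg,
                      target_genes = c("PGRMC1", "TMEM97", "LDLR"),
                      strata = list(all = character(),
                                    "ER+" = c(er = "positive")))

assoc <- runAssociationAnalysis(pc)
assoc[assoc$stratum == "all",
      c("gene", "pooled_r", "ci_lo", "ci_hi", "p", "model", "k", "n")]
#>     gene pooled_r ci_lo ci_hi        p model k   n
#> 1 PGRMC1    0.901 0.886 0.914 0.00e+00 fixed 5 750
#> 3 TMEM97    0.910 0.897 0.922 0.00e+00 fixed 5 750
#> 5   LDLR    0.559 0.507 0.607 1.15e-65 fixed 5 750

surv <- runSurvivalAnalysis(pc)
pooled <- surv[surv$cohort_id == "pooled" & surv$stratum == "all", ]
pooled[, c("gene", "adjusted", "hr", "ci_lo", "ci_hi", "model")]
#>      gene adjusted    hr ci_lo ci_hi model
#> 6  PGRMC1    FALSE 1.416 1.254  1.60 fixed
#> 12 PGRMC1     TRUE 1.024 0.778  1.35 fixed
#> 30 TMEM97    FALSE 1.389 1.236  1.56 fixed
#> 36 TMEM97     TRUE 0.954 0.712  1.28 fixed
#> 54   LDLR    FALSE 1.328 1.173  1.50 fixed
#> 60   LDLR     TRUE 1.092 0.942  1.27 fixed
```

Reading the output: the strongly proliferation-loaded markers correlate
r ≈ 0.9 with the derived proliferation score (the weak marker r ≈ 0.56),
and each marker's unadjusted pooled hazard ratio is clearly above 1
(HR ≈ 1.3–1.4 per SD). After adjusting the Cox model for the proliferation
score, every pooled 95% CI covers 1 — the analysis correctly recognizes
that in this simulation the markers' prognostic value is entirely mediated
by proliferation.

## Package layout

- `R/syndata.R` — synthetic cohort and serum-experiment generators
- `R/dataio.R` — TSV readers/writers, cohort assembly, log2 handling
- `R/signature.R` — regularized *t*, BH, signature build, sample scoring
- `R/subtyping.R` — HER2 approximation, nearest-centroid classification,
  baseline normalization
- `R/association.R` — Pearson/Fisher-z effects, correlation meta-analysis,
  pooled ANOVA, transcriptome screening
- `R/survmeta.R` — Cox fitter, horizon restriction, Cochran's Q,
  fixed/random-effects pooling, forest tables
- `R/evaluation.R` — concordance index and score-set comparison
- `R/pipeline.R` — end-to-end orchestration with reproducible outputs
- `vignettes/proliferation-meta-analysis.Rmd` — methods and modelling
  assumptions
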