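---
title: "Proliferation-adjusted biomarker meta-analysis across expression cohorts"
author: "prolifmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proliferation-adjusted biomarker meta-analysis across expression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prolifmeta)
```

# Overview

`prolifmeta` tests whether candidate biomarker genes are associated with
tumour proliferation and with early relapse across a collection of
independent expression cohorts, and whether any survival association
survives adjustment for estimated proliferation. This vignette documents
the statistical model behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical and design choices a maintainer should know about.

# The data model

Each cohort is an `ExpressionCohort` (a `SummarizedExperiment` subclass):
one `exprs` assay of log2 expression (genes x samples) plus a clinical
table in `colData` (ER/PR/HER2 status, grade, node, size class, subtype,
censored follow-up `time_months`/`event`, treatment flag). A cohort carries
its survival endpoint (`RFS`, with `DMFS` and `DSS` as fallbacks, resolved
when the cohort is assembled) because public cohorts differ in which
relapse endpoint they report. A `CohortCollection` is an ordered list of
cohorts with unique ids; analyses are always run per cohort and pooled
afterwards, never on a naively concatenated matrix — per-cohort platform
offsets make raw pooling meaningless.

Input files are deliberately minimal plain text (expression TSV, clinical
TSV, key-value manifest). There is no probe-to-gene mapping layer: gene
identifiers are opaque labels and must already be harmonized across
cohorts. Values already on log2 scale are left alone; a matrix whose
maximum exceeds 50 is treated as linear-scale intensities and transformed
to `log2(x + 1)` (log2 expression rarely exceeds ~16, so 50 separates the
two regimes with a wide margin; the threshold is an argument).

# The proliferation signature

Direct proliferation measurements (Ki-67, mitotic index) are missing from
most public cohorts, so proliferation is estimated from expression. The
signature is built from a two-condition serum-response experiment —
quiescent (low-serum) versus proliferating (high-serum) fibroblast-like
cultures — intersected with an external cell-cycle gene set:

1. **Differential expression** uses a regularized two-sample *t*. With few
   arrays per group, per-gene variances are unstable; each gene's variance
   is shrunk toward a background estimate $\sigma_0^2$, the mean sample
   variance of the `window` genes nearest in rank of mean expression within
   the same group (default `window = 101`, truncated to the largest odd
   number not exceeding the gene count). The moderated variance is the
   inverse-chi-square posterior mean with `nu0` prior degrees of freedom
   (default 10):
   $$\tilde s^2 = \frac{\nu_0\,\sigma_0^2 + (n-1)\,s^2}{\nu_0 + n - 1},$$
   so `nu0 = 0` recovers the ordinary *t* exactly and large `nu0`
   approaches a pure background-variance test. The statistic combines the
   two groups Welch-style, with p-values on $\nu_0 + n_a + n_b - 2$
   degrees of freedom. (Alternative conventions exist that divide by
   $\nu_0 + n - 2$; we use $\nu_0 + n - 1$ precisely so that the
   regularization-off limit is exact.)
2. **FDR control** is Benjamini–Hochberg at level `q` (default 0.10). BH
   was chosen over more conservative procedures because the signature is
   a screening step whose false positives are further filtered by the
   cell-cycle intersection.
3. **The signature** is the intersection of the significant
   serum-responsive genes with the cell-cycle set; each gene's weight is
   its log2 fold change, oriented high-serum minus low-serum so that a
   positive weight means proliferation-up.

**Scoring.** The cited scoring literature does not pin down one formula,
so the package commits to the |w|-normalized weighted sum of
cohort-mean-centered expression,
$$\mathrm{score}_j = \sum_g w_g\,\tilde x_{gj} \Big/ \sum_g |w_g|,$$
for three reasons: it uses the stated log-fold-change weighting, it is
scale-comparable across gene panels of different sizes (scores live on the
log2-expression scale), and it is sign-correct for down-regulated genes.
Centering is within cohort, not global, mirroring the per-dataset
normalization stance of the rest of the pipeline; a `standardize` switch
additionally divides each gene by its cohort SD for users who prefer
z-score aggregation. Scores are invariant to per-gene additive constants
(hence to platform offsets) and to positive rescaling of all weights.

# HER2 approximation

HER2 IHC annotation is missing in many public cohorts, but HER2
amplification makes ERBB2 expression a right-outlier mixture. In the style
of outlier-profile analysis, a sample is called HER2+ when its ERBB2
expression lies strictly above `median + 1.5 * MAD`. The MAD carries the
usual normal-consistency constant 1.4826 (as in `stats::mad`); with the
raw MAD the cutoff sits only ~1 SD above the median of near-normal data
and the false-positive rate is far too high for a prevalence-15% outlier
mixture. On planted mixtures (+4 residual SD, 15% positives, n = 500) the
scaled cutoff operates at roughly 97% sensitivity and 98% specificity —
the regime reported for this family of approximations on annotated
validation cohorts. The raw MAD (`scale_constant = 1`) and the mean
absolute deviation (`spread = "mean"`) remain available.

Because ER and HER2 status are non-randomly associated, the approximation
is skipped in hormone-receptor-homogeneous cohorts (all non-unknown ER
labels identical, or ER entirely unknown): an outlier cutoff calibrated on
such a cohort would systematically miscall. In the pipeline,
`her2_mode = "auto"` uses annotation when present and falls back to the
approximation otherwise, per cohort.

Nearest-centroid subtyping median-centers each gene within the cohort and
assigns each sample the centroid with the highest Spearman correlation
over shared genes — the standard intrinsic-subtype classification recipe.
Rank correlation keeps the assignment robust to platform scale; ties break
by centroid order with a warning. The package ships no centroid matrix
(published centroids are licensed); any genes-x-subtypes matrix works.

# Per-cohort effects and meta-analysis

**Correlations.** Gene-score and gene-gene associations use the Pearson
coefficient with the Fisher transform $z = \operatorname{atanh} r$,
$se = 1/\sqrt{n-3}$, computed per cohort and pooled on the z scale
(back-transformed for reporting). Pooling per-cohort estimates rather than
correlating pooled samples keeps platform offsets out of the estimate.

**Survival.** Within each cohort the gene is standardized to unit SD, so
the Cox coefficient is a per-SD log hazard ratio — the only scale on which
effects from different platforms are comparable (a no-standardization flag
exists). Follow-up is administratively censored at `horizon_months`
(default 60): observations beyond the horizon become censored at the
horizon rather than being dropped, which is the correct way to ask a
"relapse within 5 years" question of whole-follow-up data. The Cox partial
likelihood uses Efron's tie correction (the default of the standard
survival fitters; Breslow by flag) and is maximized by Newton–Raphson from
zero with step halving, declaring convergence when the largest score
component falls below 1e-8 (50-iteration cap). Standard errors come from
the inverse observed information. Degenerate inputs error out explicitly:
no events, constant covariates, collinear covariates (singular
information), and monotone likelihoods (|coef| > 15 is treated as perfect
separation). Proliferation adjustment simply adds the per-sample score as
a second covariate; the reported effect is always the gene's.

**Pooling.** Fixed-effect estimates use inverse-variance weights
$w_i = 1/se_i^2$. Cochran's
$Q = \sum_i w_i (e_i - \hat e)^2$ on $k-1$ degrees of freedom gates the
model: p(Q) < 0.05 is treated as evidence of real between-cohort
heterogeneity and switches pooling to DerSimonian–Laird random effects,
$$\tau^2 = \max\!\Big(0,\ \frac{Q - (k-1)}{\sum w - \sum w^2/\sum w}\Big),
\qquad w_i^* = \frac{1}{se_i^2 + \tau^2}.$$
With $\tau^2 = 0$ the random-effects model reduces exactly to the fixed
one; with $k = 1$ the pooled estimate is the single estimate and Q is
reported as 0 on 0 df. Confidence intervals are normal-approximation
($\pm 1.96\,se$) throughout, matching standard meta-analysis reporting.
Strata (ER/HER2/node/subtype filters) are declarative sample filters
applied before estimation; a stratum with fewer than 10 samples in a
cohort drops that cohort from the stratum, since outlier cutoffs,
standardization and Cox fits are all unstable below that size.

# Concordance evaluation

Risk scores are compared by Harrell's concordance index: a pair is usable
exactly when the strictly shorter observed time is an event; the pair is
concordant when the shorter-time sample carries the higher score; tied
scores count one half; pairs with tied observed times are not usable.
Harrell's estimator (rather than censoring-reweighted variants) is the
convention of the prognosis-challenge literature this evaluation follows.
Cohort C-indices are pooled by sample-size weighting — a pragmatic summary
(per-cohort values are always emitted alongside) since no canonical
pooling rule exists for C.

# The synthetic-data generator

The generator exists so that every claim the pipeline makes can be checked
against ground truth. One configuration draws, per cohort:

- a latent proliferation score $P_j \sim N(0,1)$ per sample;
- expression $x_{gj} = \mu_g + a_g + \beta_g P_j + \varepsilon_{gj}$ with
  per-cohort platform offsets $a_g \sim N(0, \texttt{platform\_sd}^2)$ and
  residual noise $\varepsilon \sim N(0, \texttt{noise\_sd}^2)$; $\beta_g$
  is `proliferation_loading_scale` for the proliferation block, the
  configured loading for marker analogs, 0 otherwise;
- an ERBB2 analog shifted by `her2_shift` in HER2+ samples (drawn with
  probability `her2_fraction`);
- exponential survival with hazard
  $\lambda_0 \exp(\gamma P_j + \theta\,\tilde x_{m j})$ (where
  $\tilde x_m$ is the first marker's centered expression, so
  $\lambda_0$ keeps its events-per-month meaning), censored uniformly on
  $(0, \texttt{censoring\_max})$.

Defaults describe a moderately sized multi-cohort study: 10 cohorts x 200
samples, 1000 genes with a 100-gene proliferation block, loadings of 1
log2 unit per SD, noise 0.5 and platform offsets 0.5 log2 units, 15%
HER2+ with a 2 log2-unit (4 residual-SD) ERBB2 shift, baseline hazard
0.01/month, $\gamma = 0.4$, $\theta = 0$, censoring over 10 years (120
months, so the 60-month horizon restriction is genuinely exercised), 70%
ER+. Time is in months throughout. Exponential survival is the simplest
law satisfying proportional hazards exactly; the Cox stage is agnostic to
the baseline, so nothing downstream depends on that choice.

Two structural choices encode the mediation question as a generative
truth. First, with $\theta = 0$ a marker gene's survival association
exists *only* through its loading on $P$ — regressing out the true $P$
must attenuate the marker's log HR to zero, which is exactly what the
adjusted analysis is asked to detect (and $\theta > 0$ provides the
contrast where adjustment must *not* null the effect). Second, the serum
experiment's planted log fold changes are sign-aligned with the
proliferation loadings for genes in the proliferation block
(serum-induced = proliferation-up): without that alignment the weighted
score would have cancelling signs and no signature could track $P$, which
is a property of the biology being emulated, not of the inference.

Receptor labels are independent of $P$ by default (an `er_coupling` knob
shifts mean $P$ in ER− samples for users who want subtype-proliferation
confounding, mirroring the basal-subtype enrichment seen in real data);
the treated flag is generated but unused by default analyses. The
generator does **not** emulate probe-level structure, batch artifacts
beyond additive offsets, RNA-seq count distributions, non-proportional
hazards, or informative censoring — so passing tests demonstrate the
statistical machinery is correct under its stated assumptions, not that
those assumptions hold in any particular real cohort.

The serum-experiment generator plants `n_de` genes (default: the
proliferation block first, topped up with random fillers at random signs)
with shift `log_fc_scale`, and returns the truth alongside the matrix so
recovery and empirical FDR are directly measurable.

# Reproducibility and numerical notes

- All randomness flows from one root seed through named substreams (per
  cohort, per stage), so the same configuration reproduces byte-identical
  collections and reports, and stages are independently reproducible.
- Fixture TSVs print doubles with 17 significant digits, so
  write-then-read is the identity.
- At $|r| = 1$ the Fisher z is infinite; r is clamped to $1 - 10^{-15}$
  and p-values are floored at the smallest positive double.
- `log2TransformIfNeeded` is idempotent; a matrix with maximum above the
  threshold but negative entries cannot be linear-scale intensities and
  errors out.
- A constant ERBB2 vector has zero spread: with a strict cutoff all
  samples are called negative, with a warning.

The validation suite sizes its simulations to run in minutes on one core:
mediation recovery uses 50 replicates of 10 cohorts x 200 samples
(γ = 0.4, θ = 0, marker loading 1); HER2 recovery 20 replicates of
n = 500 mixtures; signature recovery 20 replicates of 2000-gene serum
experiments with 300 planted genes; BH calibration 500 replicates of
2000 uniform p-values; Cox and concordance fitters are checked for exact
agreement with brute-force oracles (grid-search partial-likelihood
maximization, exhaustive pair counting) on small random instances, and
against the independent `survival` and `metafor` implementations.

# Known limitations

- Gene identifiers are opaque: no probe summarization or symbol mapping.
- No global batch correction beyond per-analysis baseline normalization
  and per-cohort centering/standardization; cross-platform integration
  deeper than that is out of scope.
- No multivariable clinical adjustment (age, stage), time-varying
  effects, or proportional-hazards diagnostics.
- Winsorization or other robustification of expression before Cox fitting
  is not applied (beyond per-SD standardization).
- Published subtype centroids and recurrence-score coefficients are not
  shipped; the classifier and the concordance comparison accept any
  user-supplied centroid matrix or score vectors.
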