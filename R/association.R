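## Per-cohort correlation estimation, correlation meta-analysis, pooled
## ANOVA, and transcriptome-wide correlate screening.

#' Pearson correlation with p-value and Fisher-z effect row
#'
#' Computes the product-moment correlation, a two-sided p-value from
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on n - 2 df, and the Fisher
#' transformation \eqn{z = \operatorname{atanh}(r)} with standard error
#' \eqn{1/\sqrt{n-3}}, packaged as one effect-table row ready for
#' meta-analysis. At |r| = 1 the p-value is floored at the smallest
#' positive double and r is clamped infinitesimally below 1 before the
#' atanh.
#'
#' @param x,y numeric vectors of equal length (n >= 4), neither constant.
#' @param cohort_id,stratum labels carried into the effect row.
#' @return one-row data.frame: `cohort_id`, `stratum`, `n`, `r`, `p`,
#'   `effect` (Fisher z), `se`, `effect_type = "fisher_z"`.
#' @export
pearsonWithP <- function(x, y, cohort_id = "cohort", stratum = "all") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stopf("need n >= 4 complete pairs (got %d)", n)
  if (sd(x) == 0 || sd(y) == 0) stopf("constant input vector")
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- max(2 * pt(-abs(tstat), n - 2), .Machine$double.xmin)
  rc <- min(max(r, -(1 - 1e-15)), 1 - 1e-15)
  data.frame(cohort_id = cohort_id, stratum = stratum, n = n, r = r, p = p,
             effect = atanh(rc), se = 1 / sqrt(n - 3),
             effect_type = "fisher_z", stringsAsFactors = FALSE)
}

#' Meta-analysis of Fisher-z correlations across cohorts
#'
#' Pools per-cohort Fisher-z effects with the same heterogeneity-gated
#' fixed/random machinery as [metaEffect()]; the pooled correlation is
#' recovered as `tanh(pooledEffect)` (the `show` method and
#' [metaSummaryRow()] report it back-transformed).
#'
#' @param estimates effect table of `fisher_z` rows (see [pearsonWithP()]).
#' @param model `"auto"` (random iff Cochran's Q p < 0.05), `"fixed"` or
#'   `"random"`.
#' @return a \linkS4class{MetaResult} with `effectType = "fisher_z"`.
#' @export
metaCorrelation <- function(estimates, model = "auto") {
  checkEffectTable(estimates)
  if (estimates$effect_type[1] != "fisher_z") {
    stopf("metaCorrelation expects fisher_z effects (got %s)",
          estimates$effect_type[1])
  }
  metaEffect(estimates, model = model)
}

#' One-way pooled ANOVA on baseline-normalized expression
#'
#' Baseline-normalizes the gene within each cohort (see
#' [baselineNormalize()]), pools the samples, and runs a fixed-effects
#' one-way ANOVA of normalized expression on the variable's levels.
#'
#' @inheritParams baselineNormalize
#' @return list with `F`, `df_between`, `df_within`, `p`, and the pooled
#'   data.frame (`data`).
#' @export
pooledAnova <- function(collection, gene, variable, baseline_level) {
  df <- baselineNormalize(collection, variable, baseline_level, gene)
  cnt <- table(df$group)
  if (length(cnt) < 2L) stopf("need >= 2 levels of %s (got %d)",
                              variable, length(cnt))
  if (any(cnt < 2L)) {
    stopf("level(s) with < 2 pooled samples: %s",
          paste(names(cnt)[cnt < 2L], collapse = ", "))
  }
  fit <- lm(value ~ factor(group), data = df)
  av <- anova(fit)
  list(F = av[1, "F value"], df_between = av[1, "Df"],
       df_within = av[2, "Df"], p = av[1, "Pr(>F)"], data = df)
}

#' Transcriptome-wide correlate screen for a target gene
#'
#' Correlates the target gene with every other gene in a cohort and keeps
#' genes passing the threshold, sorted by |r| descending.
#'
#' @param dataset an \linkS4class{ExpressionCohort}.
#' @param target_gene gene label present in the cohort.
#' @param threshold correlation threshold (default 0.25).
#' @param signed if FALSE (default) retain `|r| >= threshold`; if TRUE
#'   retain `r >= threshold` only.
#' @return data.frame with columns `gene`, `r` (target excluded).
#' @export
transcriptomeCorrelates <- function(dataset, target_gene, threshold = 0.25,
                                    signed = FALSE) {
  mat <- exprsMatrix(dataset)
  if (!target_gene %in% rownames(mat)) {
    stopf("target gene %s absent from cohort %s", target_gene,
          cohortId(dataset))
  }
  target <- mat[target_gene, ]
  if (sd(target) == 0) stopf("target gene %s is constant", target_gene)
  others <- mat[setdiff(rownames(mat), target_gene), , drop = FALSE]
  keep <- apply(others, 1L, sd) > 0
  r <- drop(cor(t(others[keep, , drop = FALSE]), target))
  pass <- if (signed) r >= threshold else abs(r) >= threshold
  res <- data.frame(gene = names(r)[pass], r = unname(r[pass]),
                    stringsAsFactors = FALSE)
  res[order(-abs(res$r)), , drop = FALSE]
}

#' Flatten a MetaResult into one machine-readable summary row
#'
#' Back-transforms the pooled effect to the reporting scale: `tanh` for
#' Fisher-z correlations (pooled r), `exp` for log hazard ratios (pooled
#' HR).
#'
#' @param meta a \linkS4class{MetaResult}.
#' @param label value of the first column (e.g. the stratum).
#' @return one-row data.frame: `stratum`, `pooled`, `ci_lo`, `ci_hi`, `p`,
#'   `Q`, `p_Q`, `tau2`, `model`, `k`.
#' @export
metaSummaryRow <- function(meta, label = "all") {
  bt <- if (meta@effectType == "log_hr") exp else tanh
  data.frame(stratum = label, pooled = bt(meta@pooledEffect),
             ci_lo = bt(meta@ciLo), ci_hi = bt(meta@ciHi), p = meta@p,
             Q = meta@Q, p_Q = meta@pQ, tau2 = meta@tau2, model = meta@model,
             k = meta@k, stringsAsFactors = FALSE)
}
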