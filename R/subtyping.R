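## HER2 approximation from ERBB2 expression, nearest-centroid subtype
## classification, and baseline normalization for pooled categorical
## analyses.

#' Approximate HER2 status from ERBB2 expression (COPA-style)
#'
#' HER2 amplification makes ERBB2 expression a right-outlier mixture; in
#' the style of Cancer Outlier Profile Analysis a sample is called positive
#' when its ERBB2 expression lies strictly above
#' `median + 1.5 * absolute deviation`, where the absolute-deviation
#' statistic is the median absolute deviation (default, scaled by the usual
#' normal-consistency constant 1.4826 as in [stats::mad()]) or the mean
#' absolute deviation.
#'
#' The call is invariant under adding a constant to all values and
#' equivariant under positive scaling. A constant input yields zero
#' positives (zero spread, strict inequality) with a warning.
#'
#' @param erbb2_values numeric vector (>= 3 finite values) of log2 ERBB2
#'   expression for one cohort.
#' @param spread `"mad"` (median absolute deviation; default) or `"mean"`
#'   (mean absolute deviation).
#' @param scale_constant consistency constant multiplying the MAD (default
#'   1.4826; set to 1 for the raw MAD). Ignored for `spread = "mean"`.
#' @return a \linkS4class{Her2Call}.
#' @export
approximateHer2Status <- function(erbb2_values, spread = c("mad", "mean"),
                                  scale_constant = 1.4826) {
  spread <- match.arg(spread)
  if (length(erbb2_values) < 3L || any(!is.finite(erbb2_values))) {
    stopf("need >= 3 finite ERBB2 values (got %d)", length(erbb2_values))
  }
  ctr <- median(erbb2_values)
  dev <- abs(erbb2_values - ctr)
  spr <- if (spread == "mad") scale_constant * median(dev) else mean(dev)
  cutoff <- ctr + 1.5 * spr
  if (spr == 0) {
    warnf("zero spread in ERBB2 values: all samples called negative")
  }
  status <- factor(ifelse(erbb2_values > cutoff, "positive", "negative"),
                   levels = c("negative", "positive"))
  names(status) <- names(erbb2_values)
  new("Her2Call", status = status, cutoff = cutoff, center = ctr,
      spread = spr)
}

#' Should HER2 approximation be skipped for this cohort?
#'
#' ER and HER2 status are non-randomly associated, so an outlier-based HER2
#' approximation is unreliable in hormone-receptor-homogeneous cohorts:
#' skip (return TRUE) when all non-unknown ER labels are identical, or when
#' ER status is entirely unknown (with a warning).
#'
#' @param dataset an \linkS4class{ExpressionCohort}.
#' @return logical flag: TRUE = do not approximate.
#' @export
skipHer2Approximation <- function(dataset) {
  er <- clinicalData(dataset)$er
  known <- er[!is.na(er) & er != "unknown"]
  if (!length(known)) {
    warnf("cohort %s: ER status entirely unknown; skipping HER2 approximation",
          cohortId(dataset))
    return(TRUE)
  }
  length(unique(known)) <= 1L
}

#' Nearest-centroid subtype classification
#'
#' Genes are median-centered within the cohort; each sample is assigned the
#' centroid with the highest Spearman correlation over the genes shared
#' between cohort and centroid matrix. Ties are broken by centroid column
#' order, with a warning.
#'
#' @param dataset an \linkS4class{ExpressionCohort}.
#' @param centroid_matrix genes x subtypes numeric matrix (>= 2 columns)
#'   with gene row names.
#' @return character vector of subtype labels, one per sample.
#' @export
nearestCentroidClassify <- function(dataset, centroid_matrix) {
  if (ncol(centroid_matrix) < 2L) stopf("need >= 2 centroids")
  mat <- exprsMatrix(dataset)
  shared <- intersect(rownames(mat), rownames(centroid_matrix))
  if (length(shared) < 2L) {
    stopf("only %d gene(s) shared with the centroid matrix (need >= 2)",
          length(shared))
  }
  x <- mat[shared, , drop = FALSE]
  x <- x - apply(x, 1L, median)
  cen <- centroid_matrix[shared, , drop = FALSE]
  cors <- cor(x, cen, method = "spearman")
  best <- apply(cors, 1L, which.max)
  ties <- apply(cors, 1L, function(r) sum(r == max(r)) > 1L)
  if (any(ties)) {
    warnf("%d sample(s) tied between centroids; first centroid kept",
          sum(ties))
  }
  stats::setNames(colnames(cen)[best], colnames(mat))
}

#' Baseline-normalize a gene across cohorts for pooled categorical analysis
#'
#' Within each cohort, subtracts the mean log2 expression of the baseline
#' group from every sample, removing per-cohort additive platform offsets
#' so values can be pooled across cohorts. Cohorts in which the variable is
#' entirely unobserved, or which lack baseline-level samples, are excluded
#' with a warning.
#'
#' @param collection a \linkS4class{CohortCollection}.
#' @param variable clinical column name (e.g. `"er"`, `"grade"`).
#' @param baseline_level level of `variable` defining the baseline group.
#' @param gene gene label.
#' @return data.frame with columns `cohort_id`, `sample_id`, `value`
#'   (normalized log2 expression) and `group` (the variable's level),
#'   pooled over usable cohorts. Samples with unknown level are dropped.
#' @export
baselineNormalize <- function(collection, variable, baseline_level, gene) {
  out <- list()
  anyVariable <- FALSE
  for (coh in as.list(collection)) {
    cd <- clinicalData(coh)
    if (!variable %in% colnames(cd)) next
    g <- as.character(cd[[variable]])
    known <- !is.na(g) & g != "unknown"
    if (!any(known)) next
    anyVariable <- TRUE
    if (!gene %in% rownames(coh)) {
      warnf("cohort %s: gene %s absent; excluded", cohortId(coh), gene)
      next
    }
    base <- known & g == baseline_level
    if (!any(base)) {
      warnf("cohort %s: no '%s' baseline samples for %s; excluded",
            cohortId(coh), baseline_level, variable)
      next
    }
    x <- exprsMatrix(coh)[gene, ]
    xn <- x - mean(x[base])
    out[[cohortId(coh)]] <- data.frame(
      cohort_id = cohortId(coh),
      sample_id = colnames(coh)[known],
      value = unname(xn[known]),
      group = g[known],
      stringsAsFactors = FALSE)
  }
  if (!anyVariable) stopf("variable '%s' is observed in no cohort", variable)
  if (!length(out)) {
    stopf("no cohort usable for baseline normalization of %s by %s",
          gene, variable)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
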