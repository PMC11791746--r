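## Central S4 data model.
##
## ExpressionCohort  -- one cohort: log2 expression + aligned clinical table
## CohortCollection  -- ordered list of cohorts with a shared gene universe
## GeneSignature     -- gene labels with signed log-fold-change weights
## MetaResult        -- pooled effect + heterogeneity diagnostics
## SimulationConfig  -- full generative spec for the synthetic collection
## TwoGroupExperiment-- two-condition (serum-response) experiment w/ truth
## Her2Call          -- COPA-style receptor call with its cutoff

#' @import methods
#' @importClassesFrom S4Vectors SimpleList DataFrame
#' @importFrom S4Vectors DataFrame SimpleList metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

## Clinical columns every cohort must carry (missing values are "unknown"
## for categorical fields, NA for time/event).
.CLINICAL_COLUMNS <- c("er", "pr", "her2", "grade", "node", "size_class",
                       "subtype", "time_months", "event", "treated")

.ENDPOINTS <- c("RFS", "DMFS", "DSS")

#' ExpressionCohort: one expression cohort with aligned clinical data
#'
#' Extends \linkS4class{SummarizedExperiment}. The single assay `"exprs"`
#' holds log2 expression (genes x samples); `colData` holds the clinical
#' table (columns `er`, `pr`, `her2`, `grade`, `node`, `size_class`,
#' `subtype`, `time_months`, `event`, `treated`, plus any extras such as a
#' simulation's ground-truth `latent_prolif`).
#'
#' @slot cohortId single cohort identifier.
#' @slot platform free-text platform label.
#' @slot endpoint survival endpoint: one of `"RFS"`, `"DMFS"`, `"DSS"`.
#' @export
setClass("ExpressionCohort",
  contains = "SummarizedExperiment",
  representation(cohortId = "character", platform = "character",
                 endpoint = "character"))

setValidity("ExpressionCohort", function(object) {
  msg <- character()
  if (length(object@cohortId) != 1L || !nzchar(object@cohortId))
    msg <- c(msg, "cohortId must be a single non-empty string")
  if (length(object@endpoint) != 1L || !object@endpoint %in% .ENDPOINTS)
    msg <- c(msg, sprintf("endpoint must be one of %s",
                          paste(.ENDPOINTS, collapse = ", ")))
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    x <- SummarizedExperiment::assay(object, "exprs")
    if (any(!is.finite(x))) msg <- c(msg, "all expression values must be finite")
    if (anyDuplicated(rownames(x))) msg <- c(msg, "gene labels must be unique")
  }
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(.CLINICAL_COLUMNS, colnames(cd))
  if (length(miss))
    msg <- c(msg, sprintf("clinical table missing column(s): %s",
                          paste(miss, collapse = ", ")))
  if (all(c("time_months", "event") %in% colnames(cd))) {
    tm <- cd$time_months
    ev <- cd$event
    if (any(!is.na(tm) & tm < 0)) msg <- c(msg, "time_months must be >= 0")
    if (any(!is.na(tm) & is.na(ev)))
      msg <- c(msg, "event must be present wherever time_months is present")
    if (any(!is.na(ev) & !ev %in% c(0, 1)))
      msg <- c(msg, "event must be 0/1 (or NA)")
  }
  if (length(msg)) msg else TRUE
})

#' CohortCollection: an ordered list of expression cohorts
#'
#' Extends \linkS4class{SimpleList}; every element is an
#' \linkS4class{ExpressionCohort} and cohort ids are unique.
#' @export
setClass("CohortCollection", contains = "SimpleList")

setValidity("CohortCollection", function(object) {
  msg <- character()
  ok <- vapply(object, function(x) is(x, "ExpressionCohort"), logical(1))
  if (length(ok) && !all(ok))
    msg <- c(msg, "all elements must be ExpressionCohort objects")
  else if (length(object)) {
    ids <- vapply(object, cohortId, character(1))
    if (anyDuplicated(ids)) msg <- c(msg, "cohort ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' GeneSignature: genes with signed log-fold-change weights
#'
#' @slot genes ordered unique gene labels.
#' @slot weights per-gene real weights (no zeros, all finite).
#' @slot name signature label.
#' @export
setClass("GeneSignature",
  representation(genes = "character", weights = "numeric", name = "character"))

setValidity("GeneSignature", function(object) {
  msg <- character()
  if (length(object@genes) < 1L) msg <- c(msg, "at least one gene required")
  if (anyDuplicated(object@genes)) msg <- c(msg, "gene labels must be unique")
  if (length(object@weights) != length(object@genes))
    msg <- c(msg, "weights and genes must have equal length")
  if (any(!is.finite(object@weights))) msg <- c(msg, "weights must be finite")
  if (any(object@weights == 0)) msg <- c(msg, "zero weights are not allowed")
  if (length(msg)) msg else TRUE
})

#' MetaResult: pooled effect with heterogeneity diagnostics
#'
#' @slot pooledEffect pooled effect on the working scale (Fisher z or log HR).
#' @slot se pooled standard error.
#' @slot ciLo,ciHi 95\% confidence limits on the working scale.
#' @slot p two-sided normal p-value for pooled effect = 0.
#' @slot Q Cochran's Q statistic.
#' @slot df degrees of freedom for Q (k - 1; 0 when k = 1).
#' @slot pQ chi-square p-value for Q (1 when k = 1).
#' @slot tau2 DerSimonian-Laird between-study variance (0 under fixed).
#' @slot model `"fixed"` or `"random"`.
#' @slot k number of cohorts pooled.
#' @slot effectType `"fisher_z"` or `"log_hr"`.
#' @export
setClass("MetaResult",
  representation(pooledEffect = "numeric", se = "numeric", ciLo = "numeric",
                 ciHi = "numeric", p = "numeric", Q = "numeric", df = "integer",
                 pQ = "numeric", tau2 = "numeric", model = "character",
                 k = "integer", effectType = "character"))

setValidity("MetaResult", function(object) {
  msg <- character()
  if (!object@model %in% c("fixed", "random")) msg <- c(msg, "bad model")
  if (!object@effectType %in% c("fisher_z", "log_hr"))
    msg <- c(msg, "bad effectType")
  if (object@ciLo > object@pooledEffect || object@pooledEffect > object@ciHi)
    msg <- c(msg, "CI must bracket the pooled effect")
  if (object@tau2 < 0) msg <- c(msg, "tau2 must be >= 0")
  if (object@model == "fixed" && object@tau2 != 0)
    msg <- c(msg, "tau2 must be 0 under the fixed-effect model")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: generative specification for synthetic cohorts
#'
#' Encodes the whole data-generating process: a latent per-sample
#' proliferation score driving a block of genes, marker-gene loadings,
#' per-cohort platform offsets, an ERBB2-analog outlier mixture for HER2+
#' samples, and exponential survival whose hazard depends on the latent
#' score (and optionally directly on a marker gene).
#'
#' @slot nCohorts number of cohorts.
#' @slot samplesPerCohort samples per cohort (scalar or one per cohort).
#' @slot nGenes total genes.
#' @slot nProliferationGenes genes loading on the latent score.
#' @slot proliferationLoadingScale log2 units per SD of the latent score.
#' @slot platformSd SD of per-cohort per-gene additive offsets (log2).
#' @slot noiseSd residual SD (log2).
#' @slot her2Fraction probability a sample is HER2+.
#' @slot her2Shift log2 shift added to the ERBB2 analog in HER2+ samples.
#' @slot markerLoadings named numeric: marker-gene loadings on the latent score.
#' @slot baselineHazard events per month at latent score 0.
#' @slot logHazardPerSd log hazard per SD of the latent score (gamma).
#' @slot directMarkerLogHazard direct log-hazard effect of the first marker
#'   gene's (centered) expression (theta); 0 = fully mediated scenario.
#' @slot censoringMax upper bound of uniform censoring (months).
#' @slot erPositiveFraction probability a sample is ER+.
#' @slot erCoupling shift in mean latent score for ER- samples (0 = off).
#' @slot seed root RNG seed.
#' @export
setClass("SimulationConfig",
  representation(nCohorts = "integer", samplesPerCohort = "integer",
                 nGenes = "integer", nProliferationGenes = "integer",
                 proliferationLoadingScale = "numeric", platformSd = "numeric",
                 noiseSd = "numeric", her2Fraction = "numeric",
                 her2Shift = "numeric", markerLoadings = "numeric",
                 baselineHazard = "numeric", logHazardPerSd = "numeric",
                 directMarkerLogHazard = "numeric", censoringMax = "numeric",
                 erPositiveFraction = "numeric", erCoupling = "numeric",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  chkCount <- function(x, nm) {
    if (any(is.na(x)) || any(x < 1L)) sprintf("%s must be >= 1", nm) else NULL
  }
  msg <- c(msg,
           chkCount(object@nCohorts, "nCohorts"),
           chkCount(object@samplesPerCohort, "samplesPerCohort"),
           chkCount(object@nGenes, "nGenes"),
           chkCount(object@nProliferationGenes, "nProliferationGenes"))
  if (!length(object@samplesPerCohort) %in% c(1L, object@nCohorts))
    msg <- c(msg, "samplesPerCohort must be scalar or one per cohort")
  for (nm in c("platformSd", "noiseSd")) {
    if (slot(object, nm) < 0) msg <- c(msg, sprintf("%s must be >= 0", nm))
  }
  for (nm in c("her2Fraction", "erPositiveFraction")) {
    v <- slot(object, nm)
    if (is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be in [0, 1]", nm))
  }
  if (object@baselineHazard <= 0) msg <- c(msg, "baselineHazard must be > 0")
  if (object@censoringMax <= 0) msg <- c(msg, "censoringMax must be > 0")
  ml <- object@markerLoadings
  if (length(ml)) {
    if (is.null(names(ml)) || any(!nzchar(names(ml))) || anyDuplicated(names(ml)))
      msg <- c(msg, "markerLoadings must have distinct non-empty gene labels")
  }
  ## gene-universe layout: proliferation genes + markers + ERBB2 analog + filler
  if (object@nProliferationGenes + length(ml) + 1L > object@nGenes)
    msg <- c(msg, "nGenes too small for proliferation genes + markers + ERBB2 analog")
  if (length(msg)) msg else TRUE
})

#' TwoGroupExperiment: a two-condition experiment with planted truth
#'
#' @slot exprs genes x arrays matrix of log2 values.
#' @slot groups factor per array with levels `low_serum`, `high_serum`.
#' @slot trueDeGenes labels of genes with a planted group shift.
#' @slot trueLogFc named numeric of planted log fold changes
#'   (high_serum minus low_serum).
#' @export
setClass("TwoGroupExperiment",
  representation(exprs = "matrix", groups = "factor",
                 trueDeGenes = "character", trueLogFc = "numeric"))

setValidity("TwoGroupExperiment", function(object) {
  msg <- character()
  if (ncol(object@exprs) != length(object@groups))
    msg <- c(msg, "groups must align with matrix columns")
  if (!identical(levels(object@groups), c("low_serum", "high_serum")))
    msg <- c(msg, "group levels must be low_serum, high_serum (in that order)")
  if (any(table(object@groups) == 0)) msg <- c(msg, "both groups must be non-empty")
  if (!all(object@trueDeGenes %in% rownames(object@exprs)))
    msg <- c(msg, "every trueDeGene must appear in the matrix")
  if (length(object@trueLogFc) &&
      !all(names(object@trueLogFc) %in% rownames(object@exprs)))
    msg <- c(msg, "trueLogFc names must appear in the matrix")
  if (length(msg)) msg else TRUE
})

#' Her2Call: COPA-style receptor status call
#'
#' @slot status factor per sample with levels `negative`, `positive`.
#' @slot cutoff calling threshold (log2 units): `center + 1.5 * spread`.
#' @slot center the median.
#' @slot spread the absolute-deviation statistic used (MAD by default).
#' @export
setClass("Her2Call",
  representation(status = "factor", cutoff = "numeric", center = "numeric",
                 spread = "numeric"))

## ----------------------------------------------------------------- show ----

setMethod("show", "ExpressionCohort", function(object) {
  cat(sprintf("ExpressionCohort '%s' (%s, endpoint %s): %d genes x %d samples\n",
              object@cohortId, object@platform, object@endpoint,
              nrow(object), ncol(object)))
  ev <- SummarizedExperiment::colData(object)$event
  cat(sprintf("  events: %d / %d with follow-up\n",
              sum(ev == 1, na.rm = TRUE), sum(!is.na(ev))))
})

setMethod("show", "CohortCollection", function(object) {
  cat(sprintf("CohortCollection of %d cohort(s)\n", length(object)))
  for (coh in as.list(object)) {
    cat(sprintf("  %s: %d x %d (%s)\n", cohortId(coh), nrow(coh), ncol(coh),
                endpointType(coh)))
  }
})

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature '%s': %d genes (%d up, %d down)\n",
              object@name, length(object@genes),
              sum(object@weights > 0), sum(object@weights < 0)))
})

setMethod("show", "MetaResult", function(object) {
  lab <- if (object@effectType == "log_hr") "log HR" else "Fisher z"
  cat(sprintf("MetaResult (%s-effect, k = %d, %s scale)\n",
              object@model, object@k, lab))
  cat(sprintf("  pooled = %.4f [%.4f, %.4f], p = %.3g\n",
              object@pooledEffect, object@ciLo, object@ciHi, object@p))
  if (object@effectType == "log_hr") {
    cat(sprintf("  HR = %.3f [%.3f, %.3f]\n", exp(object@pooledEffect),
                exp(object@ciLo), exp(object@ciHi)))
  } else {
    cat(sprintf("  r = %.3f [%.3f, %.3f]\n", tanh(object@pooledEffect),
                tanh(object@ciLo), tanh(object@ciHi)))
  }
  cat(sprintf("  Q = %.3f (df = %d, p = %.3g), tau2 = %.4f\n",
              object@Q, object@df, object@pQ, object@tau2))
})

setMethod("show", "Her2Call", function(object) {
  cat(sprintf("Her2Call: %d positive / %d (cutoff %.3f = %.3f + 1.5 x %.3f)\n",
              sum(object@status == "positive"), length(object@status),
              object@cutoff, object@center, object@spread))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d cohort(s), %s samples, %d genes ",
                     "(%d proliferation, %d marker)\n"),
              object@nCohorts,
              paste(object@samplesPerCohort, collapse = "/"),
              object@nGenes, object@nProliferationGenes,
              length(object@markerLoadings)))
  cat(sprintf("  gamma = %.3f, theta = %.3f, baseline hazard = %.4f/month, seed = %d\n",
              object@logHazardPerSd, object@directMarkerLogHazard,
              object@baselineHazard, object@seed))
})

setMethod("show", "TwoGroupExperiment", function(object) {
  cat(sprintf("TwoGroupExperiment: %d genes x %d arrays (%d planted DE)\n",
              nrow(object@exprs), ncol(object@exprs),
              length(object@trueDeGenes)))
})
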