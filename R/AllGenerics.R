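## Accessor generics for the S4 data model.

#' Cohort identifier
#' @param x an \linkS4class{ExpressionCohort}.
#' @return a single character id.
#' @export
setGeneric("cohortId", function(x) standardGeneric("cohortId"))

#' @rdname cohortId
#' @export
setMethod("cohortId", "ExpressionCohort", function(x) x@cohortId)

#' Platform label
#' @param x an \linkS4class{ExpressionCohort}.
#' @return a single character label.
#' @export
setGeneric("platformName", function(x) standardGeneric("platformName"))

#' @rdname platformName
#' @export
setMethod("platformName", "ExpressionCohort", function(x) x@platform)

#' Survival endpoint of a cohort
#'
#' Which relapse endpoint the cohort's follow-up encodes: relapse-free
#' (`RFS`), distant-metastasis-free (`DMFS`) or disease-specific (`DSS`)
#' survival, resolved at load time in that order of preference.
#' @param x an \linkS4class{ExpressionCohort}.
#' @return one of `"RFS"`, `"DMFS"`, `"DSS"`.
#' @export
setGeneric("endpointType", function(x) standardGeneric("endpointType"))

#' @rdname endpointType
#' @export
setMethod("endpointType", "ExpressionCohort", function(x) x@endpoint)

#' Log2 expression matrix of a cohort
#' @param x an \linkS4class{ExpressionCohort}.
#' @return genes x samples numeric matrix.
#' @export
setGeneric("exprsMatrix", function(x) standardGeneric("exprsMatrix"))

#' @rdname exprsMatrix
#' @export
setMethod("exprsMatrix", "ExpressionCohort",
          function(x) SummarizedExperiment::assay(x, "exprs"))

#' Clinical table of a cohort
#' @param x an \linkS4class{ExpressionCohort}.
#' @return a \linkS4class{DataFrame}, one row per sample, aligned to the
#'   expression columns.
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @rdname clinicalData
#' @export
setMethod("clinicalData", "ExpressionCohort",
          function(x) SummarizedExperiment::colData(x))

#' Shared gene universe of a collection
#' @param x a \linkS4class{CohortCollection}.
#' @param mode `"intersection"` (genes present in every cohort) or
#'   `"union"` (genes present in any cohort).
#' @return character vector of gene labels.
#' @export
setGeneric("geneUniverse",
           function(x, mode = c("intersection", "union"))
             standardGeneric("geneUniverse"))

#' @rdname geneUniverse
#' @export
setMethod("geneUniverse", "CohortCollection", function(x, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  sets <- lapply(as.list(x), function(coh) rownames(coh))
  if (!length(sets)) return(character())
  Reduce(if (mode == "intersection") intersect else union, sets)
})

#' Signature genes and weights
#' @param x a \linkS4class{GeneSignature}.
#' @return `signatureGenes`: character vector; `signatureWeights`: named
#'   numeric vector of log-fold-change weights.
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @rdname signatureGenes
#' @export
setMethod("signatureGenes", "GeneSignature", function(x) x@genes)

#' @rdname signatureGenes
#' @export
setGeneric("signatureWeights", function(x) standardGeneric("signatureWeights"))

#' @rdname signatureGenes
#' @export
setMethod("signatureWeights", "GeneSignature",
          function(x) stats::setNames(x@weights, x@genes))

#' HER2 call status vector
#' @param x a \linkS4class{Her2Call}.
#' @return factor with levels `negative`, `positive`.
#' @export
setGeneric("her2Status", function(x) standardGeneric("her2Status"))

#' @rdname her2Status
#' @export
setMethod("her2Status", "Her2Call", function(x) x@status)
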