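## Reading, validation and assembly of per-cohort expression + clinical data.
##
## External formats (all plain text, tab separated):
##   expression TSV : first column `gene`, one column per sample, log2 values
##   clinical TSV   : one row per sample; columns sample_id, er, pr, her2,
##                    grade, node, size_class, subtype, time_months, event,
##                    treated (missing values as the literal token NA)
##   manifest       : key<TAB>value lines, see writeFixtureBundle()

#' Read an expression matrix from TSV
#'
#' @param path path to a tab-separated file whose first column holds unique
#'   gene labels and whose remaining columns hold numeric log2 values.
#' @return numeric matrix, genes x samples, with dimnames from the file.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stopf("%s: expected a gene column plus >= 1 sample", path)
  genes <- df[[1L]]
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stopf("%s: duplicated gene label(s): %s", path,
          paste(unique(dup), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "NaN")), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("%s: non-numeric value '%s' at line %d (gene %s, sample %s)",
          path, vals[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L,
          genes[bad[1, 1]], colnames(vals)[bad[1, 2]])
  }
  dimnames(num) <- list(genes, colnames(vals))
  num
}

#' Read a clinical annotation table from TSV
#'
#' Character columns are kept as-is (missing = `"unknown"` or `NA`);
#' `time_months` and `latent_prolif` are coerced to numeric, `event` to
#' integer.
#'
#' @param path path to a tab-separated clinical table with a `sample_id`
#'   column.
#' @return a data.frame, one row per sample.
#' @export
readClinicalTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = "NA")
  if (!"sample_id" %in% names(df)) stopf("%s: missing sample_id column", path)
  for (nm in intersect(c("time_months", "latent_prolif"), names(df))) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  if ("event" %in% names(df)) df$event <- as.integer(df$event)
  df
}

#' Log2-transform a matrix when it looks linear scale
#'
#' Microarray intensities left on the linear scale are detected by their
#' range: log2 expression rarely exceeds ~16, so a maximum above
#' `threshold` (default 50) triggers `log2(x + 1)`. The operation is
#' idempotent for any data whose log2 range stays below the threshold.
#'
#' @param mat numeric matrix.
#' @param threshold maximum value above which the matrix is treated as
#'   linear scale (strictly greater than).
#' @return list with elements `matrix` and `transformed` (logical flag).
#' @export
log2TransformIfNeeded <- function(mat, threshold = 50) {
  mx <- max(mat)
  if (mx > threshold) {
    if (any(mat < 0)) {
      stopf(paste0("matrix has maximum %g (> %g) but negative entries: ",
                   "cannot be linear-scale intensities"), mx, threshold)
    }
    list(matrix = log2(mat + 1), transformed = TRUE)
  } else {
    list(matrix = mat, transformed = FALSE)
  }
}

#' Assemble an ExpressionCohort from matrix + clinical table
#'
#' Sample label sets must match exactly; the clinical rows are reordered to
#' the matrix column order.
#'
#' @param matrix genes x samples numeric log2 matrix with dimnames.
#' @param clinical data.frame with a `sample_id` column and the standard
#'   clinical columns.
#' @param cohort_id cohort identifier.
#' @param platform platform label.
#' @param endpoint one of `"RFS"`, `"DMFS"`, `"DSS"`.
#' @return a validated \linkS4class{ExpressionCohort}.
#' @export
assembleDataset <- function(matrix, clinical, cohort_id,
                            platform = "unknown", endpoint = "RFS") {
  if (is.null(colnames(matrix)) || is.null(rownames(matrix))) {
    stopf("matrix must have gene row names and sample column names")
  }
  clinical <- as.data.frame(clinical)
  if (!"sample_id" %in% names(clinical)) {
    stopf("clinical table must have a sample_id column")
  }
  sm <- colnames(matrix)
  sc <- clinical$sample_id
  if (!setequal(sm, sc) || anyDuplicated(sc)) {
    onlyM <- setdiff(sm, sc)
    onlyC <- setdiff(sc, sm)
    stopf(paste0("sample labels differ between matrix and clinical table; ",
                 "matrix-only: {%s}; clinical-only: {%s}"),
          paste(onlyM, collapse = ", "), paste(onlyC, collapse = ", "))
  }
  clinical <- clinical[match(sm, sc), , drop = FALSE]
  cd <- S4Vectors::DataFrame(clinical[, setdiff(names(clinical), "sample_id"),
                                      drop = FALSE],
                             row.names = sm)
  se <- SummarizedExperiment(assays = list(exprs = matrix), colData = cd)
  obj <- new("ExpressionCohort", se, cohortId = cohort_id,
             platform = platform, endpoint = endpoint)
  validObject(obj)
  obj
}

#' Build a CohortCollection from a list of cohorts
#'
#' @param cohorts list of \linkS4class{ExpressionCohort} objects with
#'   unique cohort ids.
#' @return a validated \linkS4class{CohortCollection}.
#' @export
newCohortCollection <- function(cohorts = list()) {
  obj <- new("CohortCollection",
             SimpleList(lapply(cohorts, identity)))
  if (length(cohorts)) {
    names(obj) <- vapply(cohorts, cohortId, character(1))
  }
  validObject(obj)
  obj
}

#' Read a fixture bundle written by writeFixtureBundle
#'
#' @param directory directory containing `manifest.tsv` and the per-cohort
#'   TSVs.
#' @return a \linkS4class{CohortCollection}.
#' @export
readFixtureBundle <- function(directory) {
  mpath <- file.path(directory, "manifest.tsv")
  if (!file.exists(mpath)) stopf("no manifest.tsv in %s", directory)
  kv <- read.delim(mpath, header = FALSE, colClasses = "character",
                   col.names = c("key", "value"))
  man <- stats::setNames(kv$value, kv$key)
  n <- as.integer(man[["n_cohorts"]])
  cohorts <- vector("list", n)
  for (i in seq_len(n)) {
    mat <- readExpressionMatrix(
      file.path(directory, man[[sprintf("cohort_%d_expr", i)]]))
    clin <- readClinicalTable(
      file.path(directory, man[[sprintf("cohort_%d_clin", i)]]))
    cohorts[[i]] <- assembleDataset(
      mat, clin,
      cohort_id = man[[sprintf("cohort_%d_id", i)]],
      platform = man[[sprintf("cohort_%d_platform", i)]],
      endpoint = man[[sprintf("cohort_%d_endpoint", i)]])
  }
  newCohortCollection(cohorts)
}
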