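## Internal helpers shared across modules.

#' @importFrom methods is new validObject slot
#' @importFrom stats anova cor lm median pchisq pnorm pt qnorm rbinom rexp
#'   rnorm runif sd p.adjust quantile
#' @importFrom utils read.delim write.table head
NULL

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so package functions never clobber the caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Deterministic sub-seed derivation: one root seed fans out into named
## substreams (per cohort, per pipeline stage) so stages are independently
## reproducible. Kept below 2^31 - 1 (R integers are 32-bit).
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 3581) %% 2147483629L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Reverse cumulative sum: suffix sums used for Cox risk-set accumulation.
revcumsum <- function(x) rev(cumsum(rev(x)))

## Row-wise sample variances of a matrix (denominator n - 1).
rowVars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

## Validate an effect table (the per-cohort EffectEstimate rows that feed
## meta-analysis). Returns the table invisibly or stops.
checkEffectTable <- function(estimates) {
  if (!is.data.frame(estimates) || nrow(estimates) == 0L) {
    stopf("'estimates' must be a non-empty data.frame of per-cohort effects")
  }
  need <- c("cohort_id", "effect", "se", "n", "effect_type")
  miss <- setdiff(need, names(estimates))
  if (length(miss)) stopf("effect table is missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(!is.finite(estimates$effect))) stopf("non-finite effect values")
  if (any(!is.finite(estimates$se)) || any(estimates$se <= 0)) {
    stopf("all standard errors must be finite and > 0")
  }
  if (length(unique(estimates$effect_type)) != 1L) {
    stopf("mixed effect_type in one meta-analysis: %s",
          paste(unique(estimates$effect_type), collapse = ", "))
  }
  if (estimates$effect_type[1] == "fisher_z" && any(estimates$n < 4)) {
    stopf("fisher_z effects require n >= 4 (se = 1/sqrt(n - 3))")
  }
  invisible(estimates)
}
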