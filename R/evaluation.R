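## Concordance-index evaluation of continuous risk scores against censored
## recurrence data.

#' ConcordanceResult: Harrell's C with its pair counts
#'
#' @slot cIndex concordance index in \[0, 1\].
#' @slot concordant,discordant,tied pair counts (`tied` = tied scores).
#' @slot usablePairs number of usable (comparable) pairs.
#' @export
setClass("ConcordanceResult",
  representation(cIndex = "numeric", concordant = "numeric",
                 discordant = "numeric", tied = "numeric",
                 usablePairs = "numeric"))

setValidity("ConcordanceResult", function(object) {
  msg <- character()
  if (object@concordant + object@discordant + object@tied !=
      object@usablePairs)
    msg <- c(msg, "pair counts must sum to usablePairs")
  if (object@cIndex < 0 || object@cIndex > 1)
    msg <- c(msg, "cIndex must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConcordanceResult", function(object) {
  cat(sprintf("ConcordanceResult: C = %.4f (%d concordant, %d discordant, %d tied of %d usable pairs)\n",
              object@cIndex, object@concordant, object@discordant,
              object@tied, object@usablePairs))
})

#' Harrell's concordance index for censored data
#'
#' A pair of samples is usable exactly when the shorter observed time is an
#' event (ties in observed time are not usable); a usable pair is
#' concordant when the higher risk score belongs to the sample with the
#' shorter time, and tied scores count one half. \eqn{C = (\mathrm{conc} +
#' 0.5\,\mathrm{tied}) / \mathrm{usable}}.
#'
#' @param scores numeric risk scores (higher = higher predicted risk).
#' @param times observed follow-up times.
#' @param events 0/1 event indicators.
#' @return a \linkS4class{ConcordanceResult}.
#' @export
concordanceIndex <- function(scores, times, events) {
  n <- length(scores)
  if (length(times) != n || length(events) != n) stopf("length mismatch")
  keep <- is.finite(scores) & is.finite(times) & !is.na(events)
  scores <- scores[keep]; times <- times[keep]; events <- events[keep]
  n <- length(scores)
  ## usable pair: the strictly shorter observed time is an event
  A <- outer(times, times, "<")            # A[i, j]: t_i < t_j
  E <- matrix(events == 1, n, n)           # E[i, j]: event_i
  up <- upper.tri(A)
  usable <- ((A & E) | (t(A) & t(E))) & up # each unordered pair once
  ds <- outer(scores, scores, "-")         # s_i - s_j
  ## concordant: the shorter-time sample carries the larger score
  conc <- usable & ((A & ds > 0) | (t(A) & ds < 0))
  tied <- usable & ds == 0
  nu <- sum(usable)
  if (nu == 0) stopf("no usable pairs (all censored or tied times)")
  nc <- sum(conc); nt <- sum(tied)
  nd <- nu - nc - nt
  new("ConcordanceResult", cIndex = (nc + 0.5 * nt) / nu,
      concordant = nc, discordant = nd, tied = nt, usablePairs = nu)
}

#' Compare risk-score sets by per-cohort and pooled concordance
#'
#' For each score set and cohort: administratively censors at the horizon,
#' computes Harrell's C, and pools across cohorts by sample-size weighting.
#' Cohorts without scores for a set are skipped with a warning.
#'
#' @param collection a \linkS4class{CohortCollection}.
#' @param score_sets named list; each element is a named list mapping
#'   cohort id -> named numeric vector of per-sample risk scores.
#' @param horizon_months follow-up horizon (default 60).
#' @return data.frame with columns `score_name`, `cohort_id`, `n`,
#'   `usable_pairs`, `c_index`; per-score pooled rows have
#'   `cohort_id = "pooled"`. Rows are grouped by score set, score sets
#'   ordered by decreasing pooled C.
#' @export
compareSignatures <- function(collection, score_sets, horizon_months = 60) {
  if (!length(score_sets)) stopf("need >= 1 score set")
  if (is.null(names(score_sets)) || any(!nzchar(names(score_sets)))) {
    stopf("score_sets must be named")
  }
  blocks <- list()
  for (sn in names(score_sets)) {
    rows <- list()
    for (coh in as.list(collection)) {
      id <- cohortId(coh)
      sc <- score_sets[[sn]][[id]]
      if (is.null(sc)) {
        warnf("score set '%s' missing for cohort %s; skipped", sn, id)
        next
      }
      cd <- clinicalData(coh)
      tm <- as.numeric(cd$time_months)
      ev <- as.integer(cd$event)
      sc <- sc[colnames(coh)]
      keep <- !is.na(tm) & !is.na(ev) & !is.na(sc)
      fu <- restrictFollowup(tm[keep], ev[keep], horizon_months)
      cr <- concordanceIndex(sc[keep], fu$times, fu$events)
      rows[[id]] <- data.frame(score_name = sn, cohort_id = id,
                               n = sum(keep), usable_pairs = cr@usablePairs,
                               c_index = cr@cIndex, stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    pooled <- data.frame(score_name = sn, cohort_id = "pooled",
                         n = sum(tab$n), usable_pairs = sum(tab$usable_pairs),
                         c_index = sum(tab$c_index * tab$n) / sum(tab$n),
                         stringsAsFactors = FALSE)
    blocks[[sn]] <- rbind(tab, pooled)
  }
  if (!length(blocks)) stopf("no score set usable in any cohort")
  pooledC <- vapply(blocks, function(b) b$c_index[b$cohort_id == "pooled"],
                    numeric(1))
  do.call(rbind, c(blocks[order(-pooledC)], list(make.row.names = FALSE)))
}
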