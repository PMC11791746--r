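## Per-cohort Cox estimation, 5-year horizon restriction, and
## heterogeneity-gated inverse-variance meta-analysis.

#' Administrative censoring at a follow-up horizon
#'
#' Observations with follow-up beyond the horizon are censored at the
#' horizon (time set to the horizon, event set to 0); shorter follow-up is
#' untouched. Restricting to a 5-year (60-month) horizon turns
#' whole-follow-up data into a 5-year relapse analysis without discarding
#' any sample.
#'
#' @param times numeric vector of follow-up times (months, >= 0).
#' @param events 0/1 event indicators aligned with `times`.
#' @param horizon_months horizon (default 60).
#' @return list with elements `times` and `events`.
#' @export
restrictFollowup <- function(times, events, horizon_months = 60) {
  if (any(times < 0, na.rm = TRUE)) stopf("negative follow-up time")
  if (length(times) != length(events)) stopf("times/events length mismatch")
  over <- !is.na(times) & times > horizon_months
  times[over] <- horizon_months
  events[over] <- 0L
  list(times = times, events = events)
}

#' Cox proportional-hazards fit by Newton-Raphson
#'
#' Maximizes the Cox partial likelihood with Efron handling of tied event
#' times (Breslow available), starting from zero coefficients, with step
#' halving whenever a Newton step would lower the partial likelihood.
#' Convergence is declared when the largest absolute score component falls
#' below `tol`; standard errors come from the inverse observed information.
#'
#' @param times follow-up times.
#' @param events 0/1 event indicators (>= 1 event required).
#' @param covariates numeric vector or matrix (columns = covariates, none
#'   constant or collinear).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol score convergence tolerance (default 1e-8).
#' @param max_iter maximum Newton iterations (default 50; exceeded = error).
#' @return data.frame with one row per covariate: `term`, `coef`, `se`,
#'   `z`, `p`; attributes `loglik` and `iterations`.
#' @export
coxFit <- function(times, events, covariates, ties = c("efron", "breslow"),
                   tol = 1e-8, max_iter = 50) {
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(times)
  if (nrow(X) != n || length(events) != n) stopf("input length mismatch")
  if (any(!is.finite(times)) || any(!is.finite(X))) stopf("non-finite input")
  if (sum(events == 1) < 1L) stopf("no events: Cox model cannot be fit")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    stopf("constant covariate(s): %s",
          paste(colnames(X)[sds == 0], collapse = ", "))
  }
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  X <- X[ord, , drop = FALSE]
  p <- ncol(X)
  ## event-time groups (ties share a group); only groups with events matter
  grp <- match(times, unique(times))
  firstIdx <- match(unique(grp), grp)
  evGroups <- lapply(which(vapply(split(events, grp), function(e) any(e == 1),
                                  logical(1))),
                     function(g) which(grp == g & events == 1))
  groupStart <- firstIdx[as.integer(names(evGroups))]

  scoreInfo <- function(beta) {
    eta <- drop(X %*% beta)
    c0 <- max(eta)
    w <- exp(eta - c0)
    S0 <- revcumsum(w)
    S1 <- apply(X * w, 2L, revcumsum)
    if (is.null(dim(S1))) S1 <- matrix(S1, nrow = 1L)
    ## S2 stored as n x p(p+1)/2 (upper triangle, column-major)
    pairIdx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    S2 <- apply(pairIdx, 1L, function(ij)
      revcumsum(w * X[, ij[1]] * X[, ij[2]]))
    if (!is.matrix(S2)) S2 <- matrix(S2, ncol = nrow(pairIdx))
    expand <- function(v) {
      m <- matrix(0, p, p)
      m[cbind(pairIdx[, 1], pairIdx[, 2])] <- v
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    }
    U <- numeric(p); H <- matrix(0, p, p); ll <- 0
    for (gi in seq_along(evGroups)) {
      D <- evGroups[[gi]]
      i0 <- groupStart[gi]
      d <- length(D)
      wD <- w[D]
      XD <- X[D, , drop = FALSE]
      S0D <- sum(wD)
      S1D <- colSums(XD * wD)
      S2D <- colSums(matrix(wD * XD[, pairIdx[, 1], drop = FALSE] *
                              XD[, pairIdx[, 2], drop = FALSE], nrow = d))
      U <- U + colSums(XD)
      ll <- ll + sum(eta[D])
      for (k in seq_len(d) - 1L) {
        f <- if (ties == "efron") k / d else 0
        phi <- S0[i0] - f * S0D
        z1 <- (S1[i0, ] - f * S1D) / phi
        z2 <- expand((S2[i0, ] - f * S2D) / phi)
        U <- U - z1
        H <- H + (z2 - tcrossprod(z1))
        ll <- ll - (log(phi) + c0)
      }
    }
    list(U = U, H = H, ll = ll)
  }

  beta <- numeric(p)
  si <- scoreInfo(beta)
  iter <- 0L
  repeat {
    if (max(abs(si$U)) < tol) break
    iter <- iter + 1L
    if (iter > max_iter) {
      stopf("Cox fit did not converge in %d iterations (max |score| = %g)",
            max_iter, max(abs(si$U)))
    }
    delta <- tryCatch(solve(si$H, si$U),
                      error = function(e) stopf(
                        "singular information matrix: collinear covariates?"))
    step <- 1
    repeat {
      cand <- beta + step * delta
      siNew <- scoreInfo(cand)
      if (is.finite(siNew$ll) && siNew$ll >= si$ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) stopf("step halving failed: ill-conditioned fit")
    }
    beta <- cand
    si <- siNew
    if (max(abs(beta)) > 15) {
      stopf(paste0("monotone partial likelihood (|coef| > 15): the ",
                   "covariate perfectly separates event order"))
    }
  }
  cov <- solve(si$H)
  se <- sqrt(diag(cov))
  z <- beta / se
  out <- data.frame(term = colnames(X), coef = beta, se = se, z = z,
                    p = 2 * pnorm(-abs(z)), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "loglik") <- si$ll
  attr(out, "iterations") <- iter
  out
}

#' Per-cohort hazard ratio of a gene, optionally proliferation-adjusted
#'
#' For every cohort: standardizes the gene to unit SD within the cohort (so
#' the hazard ratio is per SD of expression and cross-platform comparable),
#' administratively censors at the horizon, and fits a Cox model with the
#' gene alone or together with a per-sample adjustment score (e.g. a
#' proliferation signature score). Cohorts failing preconditions are
#' skipped with a recorded reason (attribute `"skipped"`).
#'
#' @param collection a \linkS4class{CohortCollection}.
#' @param gene gene label.
#' @param adjust_scores optional named list: cohort id -> named numeric
#'   vector of per-sample adjustment scores.
#' @param horizon_months follow-up horizon (default 60).
#' @param standardize divide the gene by its within-cohort SD (default
#'   TRUE).
#' @param stratum label stored on each effect row.
#' @return effect table (one `log_hr` row per usable cohort) with columns
#'   `cohort_id`, `effect`, `se`, `n`, `events`, `effect_type`, `stratum`;
#'   attribute `"skipped"` is a data.frame of cohort_id/reason.
#' @export
perDatasetGeneHR <- function(collection, gene, adjust_scores = NULL,
                             horizon_months = 60, standardize = TRUE,
                             stratum = "all") {
  rows <- list()
  skipped <- list()
  skip <- function(id, reason) {
    skipped[[length(skipped) + 1L]] <<- data.frame(cohort_id = id,
                                                   reason = reason,
                                                   stringsAsFactors = FALSE)
  }
  presentAnywhere <- FALSE
  for (coh in as.list(collection)) {
    id <- cohortId(coh)
    if (!gene %in% rownames(coh)) { skip(id, "gene_absent"); next }
    presentAnywhere <- TRUE
    cd <- clinicalData(coh)
    tm <- as.numeric(cd$time_months)
    ev <- as.integer(cd$event)
    keep <- !is.na(tm) & !is.na(ev)
    if (!any(keep)) { skip(id, "no_survival_data"); next }
    x <- exprsMatrix(coh)[gene, keep]
    fu <- restrictFollowup(tm[keep], ev[keep], horizon_months)
    if (sum(fu$events) < 1L) { skip(id, "no_events_within_horizon"); next }
    if (sd(x) == 0) { skip(id, "constant_gene"); next }
    if (standardize) x <- (x - mean(x)) / sd(x)
    covs <- cbind(gene = x)
    if (!is.null(adjust_scores)) {
      sc <- adjust_scores[[id]]
      if (is.null(sc)) { skip(id, "no_adjustment_score"); next }
      sc <- sc[colnames(coh)[keep]]
      if (any(is.na(sc))) { skip(id, "adjustment_score_incomplete"); next }
      if (sd(sc) == 0) { skip(id, "constant_adjustment_score"); next }
      covs <- cbind(covs, prolif = (sc - mean(sc)) / sd(sc))
    }
    fit <- tryCatch(coxFit(fu$times, fu$events, covs),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      skip(id, paste0("fit_failed: ", conditionMessage(fit)))
      next
    }
    g <- fit[fit$term == "gene", ]
    rows[[id]] <- data.frame(cohort_id = id, effect = g$coef, se = g$se,
                             n = sum(keep), events = sum(fu$events),
                             effect_type = "log_hr", stratum = stratum,
                             stringsAsFactors = FALSE)
  }
  if (!presentAnywhere) stopf("gene %s absent from every cohort", gene)
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(cohort_id = character(), effect = numeric(), se = numeric(),
               n = integer(), events = integer(), effect_type = character(),
               stratum = character(), stringsAsFactors = FALSE)
  }
  attr(out, "skipped") <- if (length(skipped)) {
    do.call(rbind, c(skipped, list(make.row.names = FALSE)))
  } else {
    data.frame(cohort_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  out
}

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum_i w_i (e_i - \hat e)^2} with inverse-variance weights
#' \eqn{w_i = 1/se_i^2} and \eqn{\hat e} the fixed-effect pooled estimate;
#' the p-value is from the chi-square distribution with k - 1 df.
#'
#' @param estimates effect table with >= 2 rows.
#' @return list with `Q`, `df`, `p_Q`.
#' @export
cochranQ <- function(estimates) {
  checkEffectTable(estimates)
  k <- nrow(estimates)
  if (k < 2L) stopf("Cochran's Q needs >= 2 estimates (got %d)", k)
  w <- 1 / estimates$se^2
  fixed <- sum(w * estimates$effect) / sum(w)
  Q <- sum(w * (estimates$effect - fixed)^2)
  list(Q = Q, df = k - 1L, p_Q = pchisq(Q, k - 1L, lower.tail = FALSE))
}

#' Heterogeneity-gated inverse-variance meta-analysis
#'
#' Fixed effect: \eqn{\hat e = \sum w_i e_i / \sum w_i},
#' \eqn{se = 1/\sqrt{\sum w_i}} with \eqn{w_i = 1/se_i^2}. Random effects
#' (DerSimonian-Laird): \eqn{\tau^2 = \max(0, (Q - (k-1)) /
#' (\sum w - \sum w^2/\sum w))} and weights \eqn{1/(se_i^2 + \tau^2)}.
#' In `"auto"` mode the random-effects model is used exactly when the
#' Cochran's Q p-value is below 0.05, mirroring the convention of treating
#' p < 0.05 as evidence of significant heterogeneity. The 95\% CI is
#' \eqn{\pm 1.96\, se} and the p-value is two-sided normal.
#'
#' @param estimates effect table (>= 1 row, homogeneous effect_type).
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @return a \linkS4class{MetaResult}.
#' @export
metaEffect <- function(estimates, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  checkEffectTable(estimates)
  e <- estimates$effect
  se <- estimates$se
  k <- length(e)
  w <- 1 / se^2
  fixed <- sum(w * e) / sum(w)
  if (k >= 2L) {
    q <- cochranQ(estimates)
    Q <- q$Q; df <- q$df; pQ <- q$p_Q
    tau2dl <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  } else {
    Q <- 0; df <- 0L; pQ <- 1; tau2dl <- 0
  }
  if (model == "auto") model <- if (pQ < 0.05) "random" else "fixed"
  if (model == "random") {
    tau2 <- tau2dl
    wr <- 1 / (se^2 + tau2)
    pooled <- sum(wr * e) / sum(wr)
    seP <- sqrt(1 / sum(wr))
  } else {
    tau2 <- 0
    pooled <- fixed
    seP <- sqrt(1 / sum(w))
  }
  new("MetaResult", pooledEffect = pooled, se = seP,
      ciLo = pooled - 1.96 * seP, ciHi = pooled + 1.96 * seP,
      p = 2 * pnorm(-abs(pooled) / seP), Q = Q, df = as.integer(df), pQ = pQ,
      tau2 = tau2, model = model, k = as.integer(k),
      effectType = estimates$effect_type[1])
}

#' Subset a cohort to a clinical stratum
#'
#' A stratum is a named character vector of clinical filters, e.g.
#' `c(er = "positive", her2 = "negative")`; samples with unknown or missing
#' values for a filtered variable are excluded. An empty stratum keeps all
#' samples.
#'
#' @param dataset an \linkS4class{ExpressionCohort}.
#' @param stratum named character vector of clinical level filters.
#' @return the filtered \linkS4class{ExpressionCohort}.
#' @export
filterStratum <- function(dataset, stratum = character()) {
  if (!length(stratum)) return(dataset)
  cd <- clinicalData(dataset)
  keep <- rep(TRUE, ncol(dataset))
  for (v in names(stratum)) {
    if (!v %in% colnames(cd)) {
      keep <- rep(FALSE, ncol(dataset))
      break
    }
    g <- as.character(cd[[v]])
    keep <- keep & !is.na(g) & g != "unknown" & g == stratum[[v]]
  }
  dataset[, keep]
}

#' Forest-plot data table for a meta-analyzed gene
#'
#' Machine-readable analog of a forest plot: one row per cohort with its
#' hazard ratio, CI and inverse-variance weight, plus a pooled footer row.
#'
#' @param estimates `log_hr` effect table (from [perDatasetGeneHR()]).
#' @param meta the matching \linkS4class{MetaResult}.
#' @return data.frame with columns `cohort_id`, `n`, `events`, `log_hr`,
#'   `se`, `hr`, `ci_lo`, `ci_hi`, `weight_pct`, `model`.
#' @export
forestTable <- function(estimates, meta) {
  w <- 1 / (estimates$se^2 + meta@tau2)
  data.frame(
    cohort_id = c(estimates$cohort_id, "pooled"),
    n = c(estimates$n, sum(estimates$n)),
    events = c(estimates$events, sum(estimates$events)),
    log_hr = c(estimates$effect, meta@pooledEffect),
    se = c(estimates$se, meta@se),
    hr = exp(c(estimates$effect, meta@pooledEffect)),
    ci_lo = exp(c(estimates$effect - 1.96 * estimates$se, meta@ciLo)),
    ci_hi = exp(c(estimates$effect + 1.96 * estimates$se, meta@ciHi)),
    weight_pct = c(100 * w / sum(w), 100),
    model = c(rep("", nrow(estimates)), meta@model),
    stringsAsFactors = FALSE)
}
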