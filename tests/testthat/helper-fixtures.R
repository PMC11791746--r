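# Shared fixtures and independent oracles, all built in code.

# Minimal clinical table with sensible defaults.
makeClinical <- function(ids, er = "positive", time = NULL, event = NULL) {
  n <- length(ids)
  data.frame(sample_id = ids,
             er = rep_len(er, n), pr = "unknown", her2 = "unknown",
             grade = "2", node = "unknown", size_class = "unknown",
             subtype = "unknown",
             time_months = if (is.null(time)) rep(NA_real_, n) else time,
             event = if (is.null(event)) rep(NA_integer_, n) else event,
             treated = "unknown", stringsAsFactors = FALSE)
}

# Small hand-built cohort: a matrix plus defaulted clinical rows.
makeCohort <- function(mat, id = "C1", er = "positive", time = NULL,
                       event = NULL, endpoint = "RFS") {
  assembleDataset(mat, makeClinical(colnames(mat), er = er, time = time,
                                    event = event),
                  cohort_id = id, endpoint = endpoint)
}

# Efron partial log-likelihood, written independently of the package
# fitter: plain loops over distinct event times, vectorized over a grid of
# coefficient values for a single covariate.
efronLogLikGrid <- function(beta, times, events, x) {
  ll <- numeric(length(beta))
  W <- exp(outer(x, beta))                      # n x B
  for (t in sort(unique(times[events == 1]))) {
    D <- which(events == 1 & times == t)
    R <- which(times >= t)
    d <- length(D)
    S0R <- colSums(W[R, , drop = FALSE])
    S0D <- colSums(W[D, , drop = FALSE])
    ll <- ll + sum(x[D]) * beta
    for (k in seq_len(d) - 1) ll <- ll - log(S0R - (k / d) * S0D)
  }
  ll
}

# Grid-search maximizer of the Efron partial likelihood over [-5, 5],
# two-stage refinement down to 1e-4 resolution.
gridCoxOracle <- function(times, events, x) {
  coarse <- seq(-5, 5, by = 0.01)
  b0 <- coarse[which.max(efronLogLikGrid(coarse, times, events, x))]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-4)
  fine[which.max(efronLogLikGrid(fine, times, events, x))]
}

# Brute-force Harrell C by explicit double loop (independent oracle).
bruteForceC <- function(scores, times, events) {
  n <- length(scores)
  conc <- disc <- tied <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (times[i] == times[j]) next
    short <- if (times[i] < times[j]) i else j
    long <- if (times[i] < times[j]) j else i
    if (events[short] != 1) next
    if (scores[short] > scores[long]) conc <- conc + 1
    else if (scores[short] < scores[long]) disc <- disc + 1
    else tied <- tied + 1
  }
  list(c = (conc + 0.5 * tied) / (conc + disc + tied),
       usable = conc + disc + tied)
}

# Inverse-variance / DerSimonian-Laird formulas recomputed from scratch.
handMeta <- function(e, se) {
  w <- 1 / se^2
  fixed <- sum(w * e) / sum(w)
  k <- length(e)
  Q <- sum(w * (e - fixed)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  list(fixed = fixed, se_fixed = sqrt(1 / sum(w)), Q = Q,
       p_Q = stats::pchisq(Q, k - 1, lower.tail = FALSE), tau2 = tau2,
       random = sum(wr * e) / sum(wr), se_random = sqrt(1 / sum(wr)))
}

effectTableOf <- function(e, se, type = "log_hr") {
  data.frame(cohort_id = sprintf("C%02d", seq_along(e)), effect = e, se = se,
             n = 50L, effect_type = type, stringsAsFactors = FALSE)
}
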