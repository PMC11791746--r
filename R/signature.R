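## Proliferation-signature derivation and per-sample scoring.
##
## The signature is the intersection of (i) genes called serum-responsive by
## a regularized (Cyber-T-style) two-sample t-test at a chosen FDR and
## (ii) an external cell-cycle gene set; each signature gene is weighted by
## its serum-response log2 fold change (high-serum minus low-serum, so a
## positive weight means proliferation-up).

#' Regularized (Cyber-T-style) two-sample t-test per gene
#'
#' Small-sample array experiments have unstable per-gene variances; each
#' gene's variance is shrunk toward a background variance estimated from the
#' `window` genes nearest in rank of mean expression within the same group.
#' The moderated variance is the inverse-chi-square posterior mean with
#' `nu0` prior degrees of freedom (the pseudo-count weight):
#' \deqn{\tilde s^2 = \frac{\nu_0 \sigma_0^2 + (n - 1) s^2}{\nu_0 + n - 1}}
#' The statistic is the Welch-style combination
#' \eqn{t = (\bar x_b - \bar x_a)/\sqrt{\tilde s_a^2/n_a + \tilde s_b^2/n_b}}
#' with p-values from the t distribution on \eqn{\nu_0 + n_a + n_b - 2}
#' degrees of freedom. With `nu0 = 0` the ordinary per-gene t-test is
#' recovered.
#'
#' @param mat genes x arrays log2 matrix.
#' @param groups factor of two levels; the second level is the "high"
#'   condition (log_fc = mean(second) - mean(first)).
#' @param nu0 pseudo-count weight of the background variance (default 10).
#' @param window odd window width for the background variance (default 101,
#'   truncated to the number of genes when larger).
#' @param q FDR level at which the `significant` flags are set.
#' @return data.frame with one row per gene: `gene`, `mean_a`, `mean_b`,
#'   `log_fc`, `t_stat`, `p_value`, `fdr_adjusted_p`, `significant`.
#' @export
regularizedTwoSampleT <- function(mat, groups, nu0 = 10, window = 101,
                                  q = 0.10) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stopf("exactly two groups required")
  if (length(groups) != ncol(mat)) stopf("groups must align with columns")
  cnt <- table(groups)
  if (any(cnt < 2L)) {
    stopf("each group needs >= 2 arrays (got %s)",
          paste(cnt, collapse = ", "))
  }
  if (window %% 2L == 0L) stopf("window must be odd")
  if (window > nrow(mat)) {
    window <- nrow(mat) - (1L - nrow(mat) %% 2L)  # largest odd <= n_genes
  }
  if (nu0 < 0) stopf("nu0 must be >= 0")
  a <- mat[, groups == levels(groups)[1L], drop = FALSE]
  b <- mat[, groups == levels(groups)[2L], drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  statsFor <- function(x) {
    n <- ncol(x)
    m <- rowMeans(x)
    s2 <- rowVars(x)
    sigma0 <- windowedMean(s2[order(m)], window)[order(order(m))]
    list(mean = m, reg = (nu0 * sigma0 + (n - 1) * s2) / (nu0 + n - 1))
  }
  sa <- statsFor(a)
  sb <- statsFor(b)
  denom <- sqrt(sa$reg / na + sb$reg / nb)
  if (any(denom == 0)) {
    stopf("zero regularized variance for %d gene(s); constant data with nu0 = 0?",
          sum(denom == 0))
  }
  tstat <- (sb$mean - sa$mean) / denom
  df <- nu0 + na + nb - 2
  p <- 2 * pt(-abs(tstat), df)
  bh <- benjaminiHochberg(p, q = q)
  data.frame(gene = rownames(mat), mean_a = sa$mean, mean_b = sb$mean,
             log_fc = sb$mean - sa$mean, t_stat = tstat, p_value = p,
             fdr_adjusted_p = bh$adjusted_p, significant = bh$significant,
             row.names = NULL, stringsAsFactors = FALSE)
}

## Running mean of x over a centered window of exactly `window` positions,
## clamped at the edges (the first/last window positions reuse the first/last
## full window). x is assumed already ordered by rank.
windowedMean <- function(x, window) {
  n <- length(x)
  if (window >= n) return(rep(mean(x), n))
  h <- (window - 1L) %/% 2L
  start <- pmin(pmax(seq_len(n) - h, 1L), n - window + 1L)
  cs <- c(0, cumsum(x))
  (cs[start + window] - cs[start]) / window
}

#' Benjamini-Hochberg step-up multiple-testing procedure
#'
#' Rejects all p-values up to the largest k with \eqn{p_{(k)} \le k q / m};
#' adjusted p-values are the usual monotone step-up values, so
#' `significant` is equivalent to `adjusted_p <= q`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return list with `significant` (logical) and `adjusted_p` (numeric).
#' @export
benjaminiHochberg <- function(p, q = 0.10) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  if (q <= 0 || q >= 1) stopf("q must lie in (0, 1)")
  adj <- p.adjust(p, method = "BH")
  list(significant = adj <= q, adjusted_p = adj)
}

#' Build a proliferation signature from DE results and a cell-cycle set
#'
#' Signature genes are the intersection of the significant serum-responsive
#' genes with the cell-cycle gene set; each is weighted by its log fold
#' change.
#'
#' @param cycle_gene_set character vector of cell-cycle-regulated gene
#'   labels.
#' @param de_result data.frame from [regularizedTwoSampleT()] (computed at
#'   the intended FDR level).
#' @param name signature label.
#' @return a \linkS4class{GeneSignature}.
#' @export
buildProliferationSignature <- function(cycle_gene_set, de_result,
                                        name = "proliferation") {
  sig <- de_result$gene[de_result$significant]
  genes <- intersect(sig, cycle_gene_set)
  if (!length(genes)) {
    stopf(paste0("empty intersection of significant serum-responsive genes ",
                 "(%d) with the cell-cycle set (%d); review the FDR level, ",
                 "gene identifiers, or input experiment"),
          length(sig), length(cycle_gene_set))
  }
  w <- de_result$log_fc[match(genes, de_result$gene)]
  if (any(w == 0)) {
    warnf("dropping %d signature gene(s) with zero log fold change",
          sum(w == 0))
    genes <- genes[w != 0]
    w <- w[w != 0]
  }
  new("GeneSignature", genes = genes, weights = w, name = name)
}

#' Read / write a gene signature as TSV (columns gene, weight)
#'
#' @param path TSV path.
#' @param name signature label on read.
#' @return `readSignature`: a \linkS4class{GeneSignature};
#'   `writeSignature`: invisibly, the path.
#' @export
readSignature <- function(path, name = "signature") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  new("GeneSignature", genes = df$gene, weights = as.numeric(df$weight),
      name = name)
}

#' @rdname readSignature
#' @param signature a \linkS4class{GeneSignature}.
#' @export
writeSignature <- function(signature, path) {
  write.table(data.frame(gene = signature@genes,
                         weight = formatC(signature@weights, digits = 17,
                                          format = "g")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score samples of a cohort with a weighted gene signature
#'
#' Each signature gene present in the cohort is centered on its cohort mean
#' (optionally standardized to unit SD); the per-sample score is the
#' weighted sum normalized by the total absolute weight:
#' \deqn{\mathrm{score}_j = \sum_g w_g \tilde x_{gj} \big/ \sum_g |w_g|}
#' Scores are therefore invariant to per-gene additive constants and to a
#' positive rescaling of all weights.
#'
#' @param dataset an \linkS4class{ExpressionCohort}.
#' @param signature a \linkS4class{GeneSignature}.
#' @param standardize also divide each centered gene by its cohort SD
#'   (default FALSE: mean-centering only).
#' @return named numeric vector of per-sample scores.
#' @export
scoreSamples <- function(dataset, signature, standardize = FALSE) {
  mat <- exprsMatrix(dataset)
  present <- intersect(signature@genes, rownames(mat))
  nMissing <- length(signature@genes) - length(present)
  if (!length(present)) {
    stopf("no signature gene present in cohort %s", cohortId(dataset))
  }
  if (nMissing > 0L) {
    message(sprintf("scoreSamples: %d/%d signature gene(s) absent from %s",
                    nMissing, length(signature@genes), cohortId(dataset)))
  }
  w <- signatureWeights(signature)[present]
  x <- mat[present, , drop = FALSE]
  x <- x - rowMeans(x)
  if (standardize) {
    sds <- sqrt(rowVars(x))
    sds[sds == 0] <- 1
    x <- x / sds
  }
  colSums(w * x) / sum(abs(w))
}
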