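## End-to-end orchestration: simulate/load -> derive signature -> score ->
## stratify -> correlate and survival meta-analysis, with reproducible
## plain-text outputs.

#' PipelineConfig: one configuration for a full analysis run
#'
#' @slot inputMode `"simulate"` (use `simConfig`) or `"load"` (use
#'   `manifestDir`, a directory written by [writeFixtureBundle()]).
#' @slot simConfig a \linkS4class{SimulationConfig} (simulate mode).
#' @slot manifestDir fixture-bundle directory (load mode).
#' @slot signatureSource `"derive"` (from a serum-response experiment) or
#'   `"file"` (read `signatureFile`).
#' @slot signatureFile TSV path with columns gene, weight (file mode).
#' @slot targetGenes genes to test (e.g. marker analogs).
#' @slot strata named list of clinical filters, e.g.
#'   `list(all = character(), "ER+" = c(er = "positive"))`.
#' @slot horizonMonths follow-up horizon for survival analyses.
#' @slot fdrQ FDR level for signature derivation.
#' @slot her2Mode `"annotated"`, `"approximate"` or `"auto"` (use annotated
#'   HER2 status when present, otherwise approximate from ERBB2).
#' @slot seed root seed for every stochastic stage.
#' @export
setClass("PipelineConfig",
  representation(inputMode = "character", simConfig = "ANY",
                 manifestDir = "character", signatureSource = "character",
                 signatureFile = "character", targetGenes = "character",
                 strata = "list", horizonMonths = "numeric", fdrQ = "numeric",
                 her2Mode = "character", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (!object@inputMode %in% c("simulate", "load"))
    msg <- c(msg, "inputMode must be 'simulate' or 'load'")
  if (object@inputMode == "simulate" && !is(object@simConfig, "SimulationConfig"))
    msg <- c(msg, "simulate mode requires a SimulationConfig")
  if (object@inputMode == "load" && !nzchar(object@manifestDir))
    msg <- c(msg, "load mode requires manifestDir")
  if (!object@signatureSource %in% c("derive", "file"))
    msg <- c(msg, "signatureSource must be 'derive' or 'file'")
  if (object@signatureSource == "file" && !nzchar(object@signatureFile))
    msg <- c(msg, "file signature source requires signatureFile")
  if (object@horizonMonths <= 0) msg <- c(msg, "horizonMonths must be > 0")
  if (object@fdrQ <= 0 || object@fdrQ >= 1)
    msg <- c(msg, "fdrQ must lie in (0, 1)")
  if (!object@her2Mode %in% c("annotated", "approximate", "auto"))
    msg <- c(msg, "her2Mode must be annotated/approximate/auto")
  if (!length(object@targetGenes)) msg <- c(msg, "need >= 1 target gene")
  if (length(msg)) msg else TRUE
})

#' Build a pipeline configuration
#'
#' @param sim_config a \linkS4class{SimulationConfig} (simulate mode), or
#'   NULL with `manifest_dir` set (load mode).
#' @param manifest_dir fixture-bundle directory for load mode.
#' @param signature_source `"derive"` or `"file"`.
#' @param signature_file signature TSV for `"file"` mode.
#' @param target_genes genes to test; defaults to the simulation's marker
#'   analogs in simulate mode.
#' @param strata named list of clinical filters (see
#'   \linkS4class{PipelineConfig}); default: all samples plus ER strata.
#' @param horizon_months follow-up horizon (default 60).
#' @param fdr_q FDR level for signature derivation (default 0.10).
#' @param her2_mode `"annotated"`, `"approximate"` or `"auto"`.
#' @param seed root seed; defaults to the simulation seed in simulate mode.
#' @return a validated \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(sim_config = NULL, manifest_dir = "",
                           signature_source = "derive", signature_file = "",
                           target_genes = NULL, strata = NULL,
                           horizon_months = 60, fdr_q = 0.10,
                           her2_mode = "auto", seed = NULL) {
  mode <- if (is.null(sim_config)) "load" else "simulate"
  if (is.null(target_genes)) {
    if (mode != "simulate") stopf("target_genes required in load mode")
    target_genes <- names(sim_config@markerLoadings)
  }
  if (is.null(strata)) {
    strata <- list(all = character(),
                   "ER+" = c(er = "positive"), "ER-" = c(er = "negative"))
  }
  if (is.null(seed)) {
    seed <- if (mode == "simulate") sim_config@seed else 1L
  }
  cfg <- new("PipelineConfig", inputMode = mode,
             simConfig = sim_config, manifestDir = manifest_dir,
             signatureSource = signature_source,
             signatureFile = signature_file,
             targetGenes = as.character(target_genes), strata = strata,
             horizonMonths = as.numeric(horizon_months),
             fdrQ = as.numeric(fdr_q), her2Mode = her2_mode,
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

resolveCollection <- function(config) {
  if (config@inputMode == "simulate") {
    simulateCohortCollection(config@simConfig)
  } else {
    readFixtureBundle(config@manifestDir)
  }
}

resolveSignature <- function(config) {
  if (config@signatureSource == "file") {
    return(readSignature(config@signatureFile))
  }
  if (config@inputMode != "simulate") {
    stopf("signature derivation needs simulate mode or a signature file")
  }
  sim <- config@simConfig
  serum <- simulateSerumExperiment(sim, n_per_group = 10,
                                   n_de = min(2L * sim@nProliferationGenes,
                                              sim@nGenes))
  ## cell-cycle gene set: the proliferation block plus an equal number of
  ## non-responsive decoys (deterministic: first fillers outside the
  ## planted set)
  prol <- proliferationGenes(sim)
  decoys <- head(setdiff(setdiff(geneLayout(sim)$genes, prol),
                         serum@trueDeGenes), length(prol))
  de <- regularizedTwoSampleT(serum@exprs, serum@groups, q = config@fdrQ)
  buildProliferationSignature(c(prol, decoys), de)
}

## Replace the her2 clinical column per the configured mode. In
## "approximate"/"auto" modes the COPA call on the ERBB2 analog stands in
## for missing annotation; hormone-receptor-homogeneous cohorts are left
## untouched (their samples drop out of HER2 strata).
resolveHer2 <- function(cohort, mode, erbb2_gene = "ERBB2") {
  if (mode == "annotated") return(cohort)
  her2 <- as.character(clinicalData(cohort)$her2)
  annotated <- any(!is.na(her2) & her2 != "unknown")
  if (mode == "auto" && annotated) return(cohort)
  if (skipHer2Approximation(cohort)) return(cohort)
  if (!erbb2_gene %in% rownames(cohort)) return(cohort)
  call <- approximateHer2Status(exprsMatrix(cohort)[erbb2_gene, ])
  SummarizedExperiment::colData(cohort)$her2 <- as.character(her2Status(call))
  cohort
}

## Strata with fewer than min_n samples in a cohort are dropped from that
## cohort (small-stratum estimates are unstable and were not pooled).
stratumCollection <- function(collection, stratum, her2_mode, min_n = 10L) {
  kept <- list()
  for (coh in as.list(collection)) {
    if ("her2" %in% names(stratum)) coh <- resolveHer2(coh, her2_mode)
    sub <- filterStratum(coh, stratum)
    if (ncol(sub) >= min_n) kept[[cohortId(sub)]] <- sub
  }
  newCohortCollection(kept)
}

#' Run the cross-cohort proliferation-association analysis
#'
#' For every target gene and stratum: scores each cohort with the
#' proliferation signature, correlates the gene with the score per cohort,
#' and meta-analyzes the Fisher-z correlations (heterogeneity-gated
#' fixed/random). One report row per gene x stratum; strata empty in every
#' cohort yield an NA row with a reason.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param out_dir optional output directory; when set, writes
#'   `association_report.tsv` and `run_manifest.json`.
#' @return the report data.frame (columns `gene`, `stratum`, `pooled_r`,
#'   `ci_lo`, `ci_hi`, `p`, `Q`, `p_Q`, `tau2`, `model`, `k`, `n`,
#'   `reason`).
#' @export
runAssociationAnalysis <- function(config, out_dir = NULL) {
  validObject(config)
  collection <- resolveCollection(config)
  signature <- resolveSignature(config)
  scores <- lapply(as.list(collection), function(coh)
    scoreSamples(coh, signature))
  names(scores) <- vapply(as.list(collection), cohortId, character(1))
  rows <- list()
  for (gene in config@targetGenes) {
    for (sname in names(config@strata)) {
      sub <- stratumCollection(collection, config@strata[[sname]],
                               config@her2Mode)
      ests <- list()
      for (coh in as.list(sub)) {
        id <- cohortId(coh)
        if (!gene %in% rownames(coh)) next
        sc <- scores[[id]][colnames(coh)]
        x <- exprsMatrix(coh)[gene, ]
        if (sd(x) == 0 || sd(sc) == 0) next
        ests[[id]] <- pearsonWithP(x, sc, cohort_id = id, stratum = sname)
      }
      if (!length(ests)) {
        rows[[paste(gene, sname)]] <- data.frame(
          gene = gene, stratum = sname, pooled_r = NA_real_,
          ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_, Q = NA_real_,
          p_Q = NA_real_, tau2 = NA_real_, model = NA_character_,
          k = 0L, n = 0L, reason = "stratum_empty_in_all_cohorts",
          stringsAsFactors = FALSE)
        next
      }
      tab <- do.call(rbind, c(ests, list(make.row.names = FALSE)))
      meta <- metaCorrelation(tab)
      sr <- metaSummaryRow(meta, label = sname)
      rows[[paste(gene, sname)]] <- data.frame(
        gene = gene, stratum = sname, pooled_r = sr$pooled,
        ci_lo = sr$ci_lo, ci_hi = sr$ci_hi, p = sr$p, Q = sr$Q,
        p_Q = sr$p_Q, tau2 = sr$tau2, model = sr$model, k = sr$k,
        n = sum(tab$n), reason = "", stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(report, file.path(out_dir, "association_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeRunManifest(config, out_dir, stage = "association")
  }
  report
}

#' Run the cross-cohort survival meta-analysis
#'
#' For every target gene and stratum: per-cohort per-SD hazard ratios at
#' the configured horizon, unadjusted and adjusted for the proliferation
#' signature score, each pooled by heterogeneity-gated meta-analysis. The
#' report is a long forest table (one row per cohort plus a pooled footer
#' per gene x stratum x adjustment).
#'
#' @inheritParams runAssociationAnalysis
#' @return the forest report data.frame (columns `gene`, `stratum`,
#'   `adjusted`, plus the [forestTable()] columns).
#' @export
runSurvivalAnalysis <- function(config, out_dir = NULL) {
  validObject(config)
  collection <- resolveCollection(config)
  signature <- resolveSignature(config)
  scores <- lapply(as.list(collection), function(coh)
    scoreSamples(coh, signature))
  names(scores) <- vapply(as.list(collection), cohortId, character(1))
  rows <- list()
  skipped <- list()
  for (gene in config@targetGenes) {
    for (sname in names(config@strata)) {
      sub <- stratumCollection(collection, config@strata[[sname]],
                               config@her2Mode)
      if (!length(sub)) next
      for (adj in c(FALSE, TRUE)) {
        ests <- perDatasetGeneHR(
          sub, gene,
          adjust_scores = if (adj) scores else NULL,
          horizon_months = config@horizonMonths, stratum = sname)
        sk <- attr(ests, "skipped")
        if (nrow(sk)) {
          sk$gene <- gene; sk$stratum <- sname; sk$adjusted <- adj
          skipped[[length(skipped) + 1L]] <- sk
        }
        if (!nrow(ests)) next
        meta <- metaEffect(ests)
        ft <- forestTable(ests, meta)
        rows[[paste(gene, sname, adj)]] <-
          cbind(gene = gene, stratum = sname, adjusted = adj, ft,
                stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stopf("no gene/stratum combination could be analyzed")
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(report, "skipped") <- if (length(skipped)) {
    do.call(rbind, c(skipped, list(make.row.names = FALSE)))
  } else {
    data.frame(cohort_id = character(), reason = character(),
               gene = character(), stratum = character(),
               adjusted = logical(), stringsAsFactors = FALSE)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(report, file.path(out_dir, "survival_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sk <- attr(report, "skipped")
    write.table(sk, file.path(out_dir, "survival_skipped.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeRunManifest(config, out_dir, stage = "survival")
  }
  report
}

writeRunManifest <- function(config, out_dir, stage) {
  manifest <- list(
    package = "prolifmeta",
    version = as.character(utils::packageVersion("prolifmeta")),
    stage = stage,
    input_mode = config@inputMode,
    seed = config@seed,
    horizon_months = config@horizonMonths,
    fdr_q = config@fdrQ,
    her2_mode = config@her2Mode,
    target_genes = config@targetGenes,
    strata = names(config@strata))
  jsonlite::write_json(manifest,
                       file.path(out_dir, sprintf("run_manifest_%s.json",
                                                  stage)),
                       auto_unbox = TRUE, pretty = TRUE)
}
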