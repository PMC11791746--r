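## Synthetic multi-cohort generator.
##
## Generative model (one cohort d with n samples, G genes):
##   P_j ~ Normal(0, 1)                         latent proliferation score
##   a_g^(d) ~ Normal(0, platformSd^2)          per-cohort platform offset
##   x_gj = mu_g + a_g^(d) + beta_g * P_j + eps_gj,  eps ~ N(0, noiseSd^2)
##   beta_g = proliferationLoadingScale for proliferation-block genes,
##            markerLoadings[g] for marker analogs, 0 otherwise
##   ERBB2 analog: + her2Shift for HER2+ samples (drawn w.p. her2Fraction)
##   T_j ~ Exponential(rate = baselineHazard * exp(gamma * P_j + theta * xm_j))
##     where xm_j is the first marker gene's within-cohort-centered expression
##   C_j ~ Uniform(0, censoringMax); time = min(T, C); event = [T <= C]
##
## With theta = 0 a marker gene's survival association exists only through
## its loading on P: the mediation structure the downstream analysis is
## designed to detect and remove.

#' Build a simulation configuration
#'
#' All arguments have defaults chosen to emulate a moderately sized
#' multi-cohort breast-cancer expression study: 10 cohorts of 200 samples,
#' 1000 genes of which 100 load on a latent proliferation score, residual
#' noise of 0.5 log2 units, platform offsets of 0.5 log2 units, 15\% HER2+
#' with a 2 log2-unit (4 residual-SD) ERBB2 shift, exponential survival in
#' months with a hazard of 0.01/month at average proliferation rising by
#' exp(0.4) per SD of the latent score, and uniform censoring over 10 years.
#'
#' @param n_cohorts number of cohorts.
#' @param samples_per_cohort scalar or vector of per-cohort sample counts.
#' @param n_genes total number of genes.
#' @param n_proliferation_genes number of genes loading on the latent score.
#' @param proliferation_loading_scale log2 units per SD of the latent score.
#' @param platform_sd SD of per-cohort per-gene additive offsets (log2).
#' @param noise_sd residual SD (log2).
#' @param her2_fraction probability a sample is HER2+.
#' @param her2_shift log2 units added to the ERBB2 analog in HER2+ samples.
#' @param marker_loadings named numeric vector of marker-gene loadings.
#' @param baseline_hazard events per month at latent score 0.
#' @param log_hazard_per_sd gamma, log hazard per SD of the latent score.
#' @param direct_marker_log_hazard theta, direct log-hazard effect of the
#'   first marker gene's centered expression (0 = fully mediated scenario).
#' @param censoring_max upper bound (months) of uniform censoring.
#' @param er_positive_fraction probability a sample is ER+.
#' @param er_coupling added to the mean latent score of ER- samples
#'   (0 = receptor labels independent of proliferation, the default).
#' @param seed root RNG seed; the same seed yields byte-identical output.
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(n_cohorts = 2, samples_per_cohort = 50, seed = 7)
#' coll <- simulateCohortCollection(cfg)
#' coll
#' @export
simulationConfig <- function(n_cohorts = 10, samples_per_cohort = 200,
                             n_genes = 1000, n_proliferation_genes = 100,
                             proliferation_loading_scale = 1,
                             platform_sd = 0.5, noise_sd = 0.5,
                             her2_fraction = 0.15, her2_shift = 2,
                             marker_loadings = c(PGRMC1 = 1, TMEM97 = 1,
                                                 LDLR = 0.3),
                             baseline_hazard = 0.01, log_hazard_per_sd = 0.4,
                             direct_marker_log_hazard = 0, censoring_max = 120,
                             er_positive_fraction = 0.7, er_coupling = 0,
                             seed = 1) {
  cfg <- new("SimulationConfig",
             nCohorts = as.integer(n_cohorts),
             samplesPerCohort = as.integer(samples_per_cohort),
             nGenes = as.integer(n_genes),
             nProliferationGenes = as.integer(n_proliferation_genes),
             proliferationLoadingScale = as.numeric(proliferation_loading_scale),
             platformSd = as.numeric(platform_sd),
             noiseSd = as.numeric(noise_sd),
             her2Fraction = as.numeric(her2_fraction),
             her2Shift = as.numeric(her2_shift),
             markerLoadings = marker_loadings,
             baselineHazard = as.numeric(baseline_hazard),
             logHazardPerSd = as.numeric(log_hazard_per_sd),
             directMarkerLogHazard = as.numeric(direct_marker_log_hazard),
             censoringMax = as.numeric(censoring_max),
             erPositiveFraction = as.numeric(er_positive_fraction),
             erCoupling = as.numeric(er_coupling),
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

## Gene-universe layout shared by the cohort and serum generators:
## proliferation block, then marker analogs, then the ERBB2 analog, then
## unassociated filler genes.
geneLayout <- function(config) {
  markers <- names(config@markerLoadings)
  if ("ERBB2" %in% markers) {
    stopf("marker_loadings must not use the reserved label 'ERBB2'")
  }
  nProl <- config@nProliferationGenes
  nFill <- config@nGenes - nProl - length(markers) - 1L
  genes <- c(sprintf("PRLF%04d", seq_len(nProl)), markers, "ERBB2",
             if (nFill > 0L) sprintf("GENE%04d", seq_len(nFill)))
  beta <- stats::setNames(numeric(config@nGenes), genes)
  beta[seq_len(nProl)] <- config@proliferationLoadingScale
  beta[markers] <- config@markerLoadings
  list(genes = genes, beta = beta,
       proliferation = genes[seq_len(nProl)], markers = markers)
}

#' Names of the proliferation-block genes of a configuration
#'
#' These genes (and only these, apart from marker analogs) load on the
#' latent proliferation score; they play the role of an external cell-cycle
#' gene set when validating signature derivation.
#' @param config a \linkS4class{SimulationConfig}.
#' @return character vector of gene labels.
#' @export
proliferationGenes <- function(config) geneLayout(config)$proliferation

#' Simulate a collection of expression cohorts with known ground truth
#'
#' Draws `n_cohorts` cohorts under the generative model described above.
#' Each cohort's clinical table carries receptor/grade/node/size labels, the
#' observed censored follow-up (`time_months`, `event`), and the ground-truth
#' latent proliferation score as column `latent_prolif` (available to
#' validation code, never to the analysis under test unless asked for).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{CohortCollection}.
#' @export
simulateCohortCollection <- function(config) {
  validObject(config)
  lay <- geneLayout(config)
  nPer <- rep(config@samplesPerCohort, length.out = config@nCohorts)
  ## Baseline means are a property of the gene universe, shared by cohorts.
  mu <- withSeed(deriveSeed(config@seed, 0L),
                 stats::setNames(runif(config@nGenes, 5, 12), lay$genes))
  endpoints <- rep(c("RFS", "RFS", "DMFS", "DSS"),
                   length.out = config@nCohorts)
  cohorts <- vector("list", config@nCohorts)
  for (d in seq_len(config@nCohorts)) {
    cohorts[[d]] <- withSeed(deriveSeed(config@seed, d), {
      simulateOneCohort(config, lay, mu, n = nPer[d],
                        cohortId = sprintf("COH%02d", d),
                        platform = sprintf("platform_%d", (d - 1L) %% 3L + 1L),
                        endpoint = endpoints[d])
    })
  }
  newCohortCollection(cohorts)
}

simulateOneCohort <- function(config, lay, mu, n, cohortId, platform, endpoint) {
  G <- config@nGenes
  sampleIds <- sprintf("%s_S%04d", cohortId, seq_len(n))
  er <- ifelse(rbinom(n, 1L, config@erPositiveFraction) == 1L,
               "positive", "negative")
  P <- rnorm(n) + config@erCoupling * (er == "negative")
  her2 <- ifelse(rbinom(n, 1L, config@her2Fraction) == 1L,
                 "positive", "negative")
  offsets <- rnorm(G, 0, config@platformSd)
  X <- matrix(rnorm(G * n, 0, config@noiseSd), G, n,
              dimnames = list(lay$genes, sampleIds))
  X <- X + mu + offsets + outer(lay$beta, P)
  X["ERBB2", her2 == "positive"] <- X["ERBB2", her2 == "positive"] +
    config@her2Shift
  ## Survival: exponential with log-linear hazard in P (and optionally the
  ## first marker's centered expression), uniform administrative censoring.
  xm <- if (length(lay$markers)) {
    v <- X[lay$markers[1L], ]
    v - mean(v)
  } else 0
  rate <- config@baselineHazard *
    exp(config@logHazardPerSd * P + config@directMarkerLogHazard * xm)
  tEvent <- rexp(n, rate)
  tCens <- runif(n, 0, config@censoringMax)
  time <- pmin(tEvent, tCens)
  event <- as.integer(tEvent <= tCens)
  pr <- ifelse(rbinom(n, 1L, 0.8) == 1L, er,
               ifelse(er == "positive", "negative", "positive"))
  clin <- data.frame(
    sample_id = sampleIds,
    er = er, pr = pr, her2 = her2,
    grade = as.character(sample(1:3, n, replace = TRUE,
                                prob = c(0.2, 0.45, 0.35))),
    node = ifelse(rbinom(n, 1L, 0.4) == 1L, "positive", "negative"),
    size_class = sample(c("T1", "T2", "T3"), n, replace = TRUE,
                        prob = c(0.45, 0.4, 0.15)),
    subtype = as.character(cut(P, c(-Inf, -0.5, 0.5, Inf),
                               labels = c("lumA", "lumB", "basal"))),
    time_months = time, event = event,
    treated = ifelse(rbinom(n, 1L, 0.5) == 1L, "yes", "no"),
    latent_prolif = P,
    stringsAsFactors = FALSE)
  assembleDataset(X, clin, cohort_id = cohortId, platform = platform,
                  endpoint = endpoint)
}

#' Simulate a two-condition serum-response experiment
#'
#' Generates a genes x arrays log2 matrix with `n_per_group` arrays per
#' serum condition and `n_de` genes carrying a planted mean shift of
#' magnitude `log_fc_scale` between conditions. Planted genes default to the
#' configuration's proliferation block first (their shift is sign-aligned
#' with their loading on the latent score: serum-induced genes are the
#' proliferation-up genes), topped up with randomly chosen filler genes with
#' random shift signs.
#'
#' @param config a \linkS4class{SimulationConfig}; supplies the gene
#'   universe, noise SD and root seed.
#' @param n_per_group arrays per condition (>= 2).
#' @param n_de number of genes with a planted shift (<= n_genes).
#' @param log_fc_scale magnitude of the planted log2 fold change.
#' @param de_genes optional explicit labels of planted genes (overrides the
#'   default choice; length must equal `n_de`).
#' @return a \linkS4class{TwoGroupExperiment}.
#' @export
simulateSerumExperiment <- function(config, n_per_group = 10, n_de = 300,
                                    log_fc_scale = 1, de_genes = NULL) {
  validObject(config)
  if (n_per_group < 2) stopf("n_per_group must be >= 2")
  if (n_de > config@nGenes) {
    stopf("n_de (%d) exceeds n_genes (%d)", n_de, config@nGenes)
  }
  lay <- geneLayout(config)
  withSeed(deriveSeed(config@seed, 900001L), {
    if (is.null(de_genes)) {
      nFromProl <- min(n_de, length(lay$proliferation))
      extraPool <- setdiff(lay$genes, lay$proliferation)
      de_genes <- c(lay$proliferation[seq_len(nFromProl)],
                    if (n_de > nFromProl)
                      sample(extraPool, n_de - nFromProl))
    } else {
      if (length(de_genes) != n_de) stopf("length(de_genes) must equal n_de")
      if (!all(de_genes %in% lay$genes)) stopf("unknown gene in de_genes")
    }
    signs <- ifelse(de_genes %in% lay$proliferation,
                    sign(config@proliferationLoadingScale),
                    sample(c(-1, 1), length(de_genes), replace = TRUE))
    trueLogFc <- stats::setNames(signs * log_fc_scale, de_genes)
    if (n_de == 0L) trueLogFc <- stats::setNames(numeric(0), character(0))
    nArr <- 2L * n_per_group
    groups <- factor(rep(c("low_serum", "high_serum"), each = n_per_group),
                     levels = c("low_serum", "high_serum"))
    mu <- runif(config@nGenes, 5, 12)
    X <- matrix(rnorm(config@nGenes * nArr, 0, config@noiseSd),
                config@nGenes, nArr,
                dimnames = list(lay$genes,
                                sprintf("array_%02d", seq_len(nArr))))
    X <- X + mu
    if (n_de > 0L) {
      X[de_genes, groups == "high_serum"] <-
        X[de_genes, groups == "high_serum"] + trueLogFc
    }
    new("TwoGroupExperiment", exprs = X, groups = groups,
        trueDeGenes = as.character(de_genes), trueLogFc = trueLogFc)
  })
}

#' Write a cohort collection to plain-text fixture files
#'
#' One expression TSV and one clinical TSV per cohort, plus a plain-text
#' key-value manifest. Numeric values are written with 17 significant
#' digits so [readFixtureBundle()] round-trips doubles exactly.
#'
#' @param collection a \linkS4class{CohortCollection}.
#' @param directory output directory (created if absent).
#' @return invisibly, a data.frame manifest of written files.
#' @seealso [readFixtureBundle()]
#' @export
writeFixtureBundle <- function(collection, directory) {
  if (!is(collection, "CohortCollection")) {
    stopf("'collection' must be a CohortCollection")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  lines <- c(sprintf("n_cohorts\t%d", length(collection)))
  files <- character()
  for (i in seq_along(collection)) {
    coh <- collection[[i]]
    id <- cohortId(coh)
    exprFile <- sprintf("%s_expr.tsv", id)
    clinFile <- sprintf("%s_clinical.tsv", id)
    writeExpressionMatrix(exprsMatrix(coh), file.path(directory, exprFile))
    writeClinicalTable(clinicalData(coh), file.path(directory, clinFile))
    lines <- c(lines,
               sprintf("cohort_%d_id\t%s", i, id),
               sprintf("cohort_%d_expr\t%s", i, exprFile),
               sprintf("cohort_%d_clin\t%s", i, clinFile),
               sprintf("cohort_%d_platform\t%s", i, platformName(coh)),
               sprintf("cohort_%d_endpoint\t%s", i, endpointType(coh)))
    files <- c(files, exprFile, clinFile)
  }
  writeLines(lines, file.path(directory, "manifest.tsv"))
  invisible(data.frame(file = c(files, "manifest.tsv"),
                       stringsAsFactors = FALSE))
}

writeExpressionMatrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat),
                   apply(mat, 2, function(v) formatC(v, digits = 17,
                                                     format = "g")),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

writeClinicalTable <- function(cd, path) {
  df <- as.data.frame(cd)
  if (!"sample_id" %in% names(df)) df <- cbind(sample_id = rownames(df), df)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- formatC(df[[nm]], digits = 17, format = "g")
      df[[nm]][df[[nm]] == " NA" | df[[nm]] == "NA"] <- NA
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
}
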