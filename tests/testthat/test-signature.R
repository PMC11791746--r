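test_that("regularized t reduces to the ordinary t when nu0 = 0", {
  set.seed(4)
  m <- matrix(rnorm(60, 8, 1), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("a%d", 1:6)))
  grp <- factor(rep(c("low_serum", "high_serum"), each = 3),
                levels = c("low_serum", "high_serum"))
  de <- regularizedTwoSampleT(m, grp, nu0 = 0, window = 3)
  for (g in 1:10) {
    tt <- t.test(m[g, 4:6], m[g, 1:3], var.equal = TRUE)
    expect_equal(de$t_stat[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(de$p_value[g], tt$p.value, tolerance = 1e-12)
  }
})

test_that("regularized t matches direct evaluation of the shrinkage formula", {
  # 3 genes x (3 + 3) arrays, nu0 = 10, window = 3: the background variance
  # is the mean of all three per-gene variances within each group.
  m <- rbind(g1 = c(1, 2, 3, 5, 6, 7),
             g2 = c(2, 2, 5, 4, 4, 4.5),
             g3 = c(10, 11, 9, 14, 15, 16))
  colnames(m) <- sprintf("a%d", 1:6)
  grp <- factor(rep(c("low_serum", "high_serum"), each = 3),
                levels = c("low_serum", "high_serum"))
  nu0 <- 10
  expected_t <- numeric(3)
  for (g in 1:3) {
    a <- m[g, 1:3]; b <- m[g, 4:6]
    s0a <- mean(apply(m[, 1:3], 1, var))   # window 3 covers all genes
    s0b <- mean(apply(m[, 4:6], 1, var))
    rega <- (nu0 * s0a + 2 * var(a)) / (nu0 + 2)
    regb <- (nu0 * s0b + 2 * var(b)) / (nu0 + 2)
    expected_t[g] <- (mean(b) - mean(a)) / sqrt(rega / 3 + regb / 3)
  }
  de <- regularizedTwoSampleT(m, grp, nu0 = 10, window = 3)
  expect_equal(de$t_stat, expected_t, tolerance = 1e-12)
  expect_equal(de$log_fc, rowMeans(m[, 4:6]) - rowMeans(m[, 1:3]),
               ignore_attr = TRUE)
  expect_equal(de$p_value, 2 * pt(-abs(expected_t), nu0 + 3 + 3 - 2),
               tolerance = 1e-12)
})

test_that("identical noise-free group means give t = 0 and p = 1", {
  m <- rbind(g1 = c(5, 6, 7, 5, 6, 7), g2 = c(1, 2, 3, 1, 2, 3))
  colnames(m) <- sprintf("a%d", 1:6)
  grp <- factor(rep(c("low_serum", "high_serum"), each = 3),
                levels = c("low_serum", "high_serum"))
  de <- regularizedTwoSampleT(m, grp, nu0 = 5, window = 1)
  expect_equal(de$t_stat, c(0, 0))
  expect_equal(de$p_value, c(1, 1))
})

test_that("regularized t converges to the ordinary t as nu0 shrinks", {
  set.seed(8)
  m <- matrix(rnorm(48, 8, 1), 8, 6,
              dimnames = list(sprintf("g%d", 1:8), sprintf("a%d", 1:6)))
  grp <- factor(rep(c("low_serum", "high_serum"), each = 3),
                levels = c("low_serum", "high_serum"))
  t0 <- regularizedTwoSampleT(m, grp, nu0 = 0, window = 3)$t_stat
  for (nu0 in c(1, 0.1, 1e-3, 1e-6)) {
    tn <- regularizedTwoSampleT(m, grp, nu0 = nu0, window = 3)$t_stat
    expect_lt(max(abs(tn - t0)), max(1e-5, nu0 * 10))
  }
  expect_error(regularizedTwoSampleT(m, factor(rep("a", 6))), "two groups")
  expect_error(
    regularizedTwoSampleT(m[, 1:4],
                          factor(c("low_serum", "low_serum", "low_serum",
                                   "high_serum"),
                                 levels = c("low_serum", "high_serum")),
                          nu0 = 0, window = 3),
    ">= 2 arrays")
})

test_that("Benjamini-Hochberg applies the step-up rule", {
  r <- benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04), q = 0.1)
  expect_true(all(r$significant))          # p(4) = 0.04 <= 4 * 0.1 / 4
  r2 <- benjaminiHochberg(c(0.5, 0.6), q = 0.1)
  expect_false(any(r2$significant))
  r3 <- benjaminiHochberg(c(0.001, 0.9), q = 0.1)
  expect_identical(r3$significant, c(TRUE, FALSE))
  expect_equal(r3$adjusted_p, c(0.002, 0.9))
  expect_error(benjaminiHochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("signature construction intersects DE calls with the cycle set", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log_fc = c(1.2, -0.8, 0.5, 2),
                   significant = c(TRUE, TRUE, FALSE, TRUE),
                   stringsAsFactors = FALSE)
  expect_error(buildProliferationSignature(c("x", "y"), de), "intersection")
  sig <- buildProliferationSignature(c("a", "b", "c", "d", "e"), de)
  expect_identical(signatureGenes(sig), c("a", "b", "d"))
  expect_equal(unname(signatureWeights(sig)), c(1.2, -0.8, 2))
  sub <- buildProliferationSignature(c("b"), de)
  expect_identical(signatureGenes(sub), "b")
})

test_that("signature files round-trip through TSV", {
  sig <- new("GeneSignature", genes = c("a", "b"), weights = c(1.25, -0.5),
             name = "s")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSignature(sig, path)
  back <- readSignature(path, name = "s")
  expect_identical(signatureGenes(back), signatureGenes(sig))
  expect_equal(signatureWeights(back), signatureWeights(sig))
})

test_that("scoring is the |w|-normalized weighted mean of centered expression", {
  m <- rbind(up = c(6, 8, 10), down = c(4, 5, 3))
  colnames(m) <- c("s1", "s2", "s3")
  coh <- makeCohort(m)
  # single positive gene: score is just that gene centered
  sig1 <- new("GeneSignature", genes = "up", weights = 1, name = "one")
  expect_equal(unname(scoreSamples(coh, sig1)), c(-2, 0, 2))
  # weights {+1, -1}: hand arithmetic on centered values
  sig2 <- new("GeneSignature", genes = c("up", "down"), weights = c(1, -1),
              name = "two")
  centered <- m - rowMeans(m)
  expect_equal(unname(scoreSamples(coh, sig2)),
               unname((centered["up", ] - centered["down", ]) / 2))
  # missing genes are tolerated with a message; all missing errors
  sig3 <- new("GeneSignature", genes = c("up", "absent"), weights = c(1, 1),
              name = "three")
  expect_message(scoreSamples(coh, sig3), "absent")
  sig4 <- new("GeneSignature", genes = "nope", weights = 1, name = "none")
  expect_error(scoreSamples(coh, sig4), "no signature gene")
})

test_that("scores are invariant to per-gene offsets and weight rescaling", {
  set.seed(12)
  m <- matrix(rnorm(50, 8, 1), 5, 10,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:10)))
  sig <- new("GeneSignature", genes = rownames(m),
             weights = c(1.5, -0.5, 2, -1, 0.25), name = "s")
  base <- scoreSamples(makeCohort(m), sig)
  shifted <- scoreSamples(makeCohort(m + rnorm(5)), sig)  # per-gene constants
  expect_equal(shifted, base, tolerance = 1e-12)
  sig2 <- new("GeneSignature", genes = sig@genes, weights = sig@weights * 7,
              name = "s")
  expect_equal(scoreSamples(makeCohort(m), sig2), base, tolerance = 1e-12)
})

test_that("planted serum-response genes are recovered through the full stage", {
  # single-replicate version of the recovery simulation (the multi-replicate
  # calibration lives in the acceptance suite)
  cfg <- simulationConfig(n_cohorts = 1, samples_per_cohort = 10,
                          n_genes = 800, n_proliferation_genes = 80,
                          noise_sd = 0.5, seed = 41)
  ex <- simulateSerumExperiment(cfg, n_per_group = 10, n_de = 160,
                                log_fc_scale = 1)
  de <- regularizedTwoSampleT(ex@exprs, ex@groups, q = 0.1)
  cyc <- c(proliferationGenes(cfg),
           head(setdiff(setdiff(rownames(ex@exprs), proliferationGenes(cfg)),
                        ex@trueDeGenes), 100))
  sig <- buildProliferationSignature(cyc, de)
  recovered <- length(intersect(signatureGenes(sig), proliferationGenes(cfg)))
  expect_gte(recovered / 80, 0.8)
})
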