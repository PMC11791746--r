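test_that("pearsonWithP matches closed forms and cor.test", {
  # orthogonal by construction
  est0 <- pearsonWithP(c(-1, 0, 1, 0), c(1, -2, 1, 0))
  expect_equal(est0$r, 0)
  expect_equal(est0$effect, 0)
  # identity: r = 1 with a representable p
  est1 <- pearsonWithP(1:5, 1:5)
  expect_equal(est1$r, 1)
  expect_gt(est1$p, 0)
  expect_true(is.finite(est1$effect))
  # random data: agrees with cor.test, effect = atanh(r), se = 1/sqrt(n-3)
  set.seed(19)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  est <- pearsonWithP(x, y)
  ct <- cor.test(x, y)
  expect_equal(est$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(est$p, ct$p.value, tolerance = 1e-12)
  expect_equal(est$effect, atanh(est$r))
  expect_equal(est$se, 1 / sqrt(27))
  expect_equal(atanh(0.5), 0.5493061443, tolerance = 1e-9)
  expect_error(pearsonWithP(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearsonWithP(1:3, 1:3), "n >= 4")
})

test_that("Fisher z of null correlations has the textbook sampling distribution", {
  set.seed(23)
  z <- replicate(1000, pearsonWithP(rnorm(30), rnorm(30))$effect)
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(sd(z) - 1 / sqrt(27)) / (1 / sqrt(27)), 0.10)
})

test_that("correlation meta-analysis reduces correctly for k = 1 and equal inputs", {
  one <- pearsonWithP(rnorm(20), rnorm(20), cohort_id = "C1")
  m1 <- metaCorrelation(one)
  expect_equal(m1@pooledEffect, one$effect)
  expect_equal(m1@se, one$se)
  expect_identical(m1@model, "fixed")
  expect_equal(m1@Q, 0)
  # two cohorts with identical z and n pool to that z with Q = 0
  two <- rbind(one, transform(one, cohort_id = "C2"))
  m2 <- metaCorrelation(two)
  expect_equal(m2@pooledEffect, one$effect)
  expect_equal(m2@Q, 0)
  expect_equal(tanh(m2@pooledEffect), metaSummaryRow(m2)$pooled)
  bad <- rbind(one, data.frame(cohort_id = "C3", stratum = "all", n = 50,
                               r = NA, p = NA, effect = 0.2, se = 0.1,
                               effect_type = "log_hr"))
  expect_error(metaCorrelation(bad), "mixed")
})

test_that("pooled correlation recovers a homogeneous true correlation", {
  set.seed(27)
  ests <- do.call(rbind, lapply(1:10, function(k) {
    x <- rnorm(200)
    y <- 0.5 / sqrt(1 - 0.5^2) * x + rnorm(200)  # true r = 0.5
    pearsonWithP(x, y, cohort_id = sprintf("C%02d", k))
  }))
  m <- metaCorrelation(ests)
  trueZ <- atanh(0.5)
  expect_lt(abs(m@pooledEffect - trueZ), 2 * m@se)
})

test_that("pooled ANOVA matches the hand-computed F on [1,2,3] vs [4,5,6]", {
  m <- rbind(G = c(1, 2, 3, 4, 5, 6)); colnames(m) <- sprintf("s%d", 1:6)
  er <- rep(c("negative", "positive"), each = 3)
  coll <- newCohortCollection(list(makeCohort(m, er = er)))
  a <- pooledAnova(coll, "G", "er", "negative")
  expect_equal(a$F, 13.5)                  # SSB = 13.5, SSW = 4, df (1, 4)
  expect_equal(a$df_between, 1L)
  expect_equal(a$df_within, 4L)
  expect_equal(a$p, pf(13.5, 1, 4, lower.tail = FALSE))
})

test_that("pooled ANOVA separates shifted groups and errors on tiny levels", {
  set.seed(31)
  m <- rbind(G = c(rnorm(20, 8), rnorm(20, 8 + 10)))
  colnames(m) <- sprintf("s%d", 1:40)
  er <- rep(c("negative", "positive"), each = 20)
  coll <- newCohortCollection(list(makeCohort(m, er = er)))
  expect_lt(pooledAnova(coll, "G", "er", "negative")$p, 1e-6)
  m2 <- rbind(G = rnorm(3)); colnames(m2) <- sprintf("s%d", 1:3)
  coll2 <- newCohortCollection(list(
    makeCohort(m2, er = c("negative", "negative", "positive"))))
  expect_error(pooledAnova(coll2, "G", "er", "negative"), "< 2")
})

test_that("ANOVA F is invariant to per-cohort additive platform offsets", {
  set.seed(33)
  mats <- lapply(1:3, function(i) {
    m <- rbind(G = rnorm(30, 8) + 0.8 * rep(c(0, 1), 15))
    colnames(m) <- sprintf("c%d_s%02d", i, 1:30)
    m
  })
  er <- rep(c("negative", "positive"), 15)
  mk <- function(ms, ids) newCohortCollection(
    Map(function(m, id) makeCohort(m, id = id, er = er), ms, ids))
  f0 <- pooledAnova(mk(mats, c("A", "B", "C")), "G", "er", "negative")$F
  shifted <- Map(function(m, off) m + off, mats, c(5, -3, 11))
  f1 <- pooledAnova(mk(shifted, c("A", "B", "C")), "G", "er", "negative")$F
  expect_equal(f1, f0, tolerance = 1e-12)
})

test_that("null ANOVA p-values are approximately uniform", {
  set.seed(35)
  ps <- replicate(200, {
    m <- rbind(G = rnorm(24, 8)); colnames(m) <- sprintf("s%d", 1:24)
    er <- sample(rep(c("negative", "positive"), each = 12))
    pooledAnova(newCohortCollection(list(makeCohort(m, er = er))),
                "G", "er", "negative")$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("transcriptome screen ranks, filters and excludes the target", {
  set.seed(37)
  n <- 60
  base <- rnorm(n)
  m <- rbind(TARGET = base,
             TWIN = base,                       # duplicate under another label
             NOISE1 = rnorm(n), NOISE2 = rnorm(n),
             ANTI = -base + rnorm(n, 0, 0.1))
  colnames(m) <- sprintf("s%02d", 1:n)
  coh <- makeCohort(m)
  tab <- transcriptomeCorrelates(coh, "TARGET", threshold = 0.25)
  expect_identical(tab$gene[1], "TWIN")
  expect_equal(tab$r[1], 1)
  expect_false("TARGET" %in% tab$gene)
  expect_true("ANTI" %in% tab$gene)            # absolute-value filter
  signedTab <- transcriptomeCorrelates(coh, "TARGET", threshold = 0.25,
                                       signed = TRUE)
  expect_false("ANTI" %in% signedTab$gene)
  expect_equal(nrow(transcriptomeCorrelates(coh, "TARGET",
                                            threshold = 1 + 1e-9)), 0L)
  m2 <- m; m2["TARGET", ] <- 5
  expect_error(transcriptomeCorrelates(makeCohort(m2), "TARGET"), "constant")
})

test_that("transcriptome screen recovers co-regulated genes", {
  cfg <- simulationConfig(n_cohorts = 1, samples_per_cohort = 500,
                          n_genes = 200, n_proliferation_genes = 50,
                          proliferation_loading_scale = 1, noise_sd = 0.25,
                          platform_sd = 0, seed = 39)
  coh <- simulateCohortCollection(cfg)[[1]]
  tab <- transcriptomeCorrelates(coh, "PRLF0001", threshold = 0.25)
  hits <- intersect(tab$gene, proliferationGenes(cfg))
  expect_gte(length(hits) / (50 - 1), 0.9)
})
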