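test_that("follow-up restriction censors administratively at the horizon", {
  r <- restrictFollowup(c(80, 40, 60), c(1L, 1L, 1L), 60)
  expect_equal(r$times, c(60, 40, 60))
  expect_equal(r$events, c(0L, 1L, 1L))
  # no-op when all times are within the horizon
  r2 <- restrictFollowup(c(10, 59.9), c(0L, 1L), 60)
  expect_equal(r2$times, c(10, 59.9))
  expect_equal(r2$events, c(0L, 1L))
  expect_error(restrictFollowup(c(-1, 5), c(1L, 0L)), "negative")
})

test_that("restriction never lengthens follow-up nor creates events", {
  set.seed(43)
  for (i in 1:20) {
    t <- runif(50, 0, 150); e <- rbinom(50, 1, 0.5)
    r <- restrictFollowup(t, e, 60)
    expect_true(all(r$times <= t))
    expect_true(all(r$events <= e))
  }
})

test_that("Cox fit matches the grid-search partial-likelihood oracle", {
  # hand example: 4 subjects, all events, binary covariate
  t4 <- c(1, 2, 3, 4); e4 <- rep(1L, 4); x4 <- c(1, 0, 1, 0)
  fit <- coxFit(t4, e4, cbind(x = x4))
  expect_lt(abs(fit$coef - gridCoxOracle(t4, e4, x4)), 1e-4)
  # random small instances, including tied event times
  set.seed(45)
  done <- 0
  while (done < 25) {
    n <- sample(4:8, 1)
    t <- sample(1:5, n, replace = TRUE)
    e <- rbinom(n, 1, 0.7)
    x <- rbinom(n, 1, 0.5)
    if (sum(e) < 1 || var(x) == 0) next
    fit <- tryCatch(coxFit(t, e, cbind(x = x)), error = function(err) err)
    if (inherits(fit, "error")) next     # separated instances error out
    expect_lt(abs(fit$coef - gridCoxOracle(t, e, x)), 1e-4)
    done <- done + 1
  }
})

test_that("Cox fit agrees with survival::coxph on continuous covariates with ties", {
  skip_if_not_installed("survival")
  set.seed(47)
  for (i in 1:10) {
    n <- 60
    t <- sample(1:12, n, replace = TRUE)
    x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
    e <- rbinom(n, 1, plogis(0.5 * x1))
    if (sum(e) < 3 || var(x2) == 0) next
    fit <- coxFit(t, e, cbind(a = x1, b = x2))
    ref <- survival::coxph(survival::Surv(t, e) ~ x1 + x2, ties = "efron")
    expect_equal(fit$coef, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  }
})

test_that("Cox fit is reparameterization-equivariant and validates input", {
  set.seed(49)
  t <- rexp(60); e <- rbinom(60, 1, 0.7); x <- rnorm(60)
  f1 <- coxFit(t, e, cbind(x = x))
  f2 <- coxFit(t, e, cbind(x = 10 * x))
  expect_equal(f2$coef, f1$coef / 10, tolerance = 1e-7)
  expect_equal(f2$z, f1$z, tolerance = 1e-7)
  expect_error(coxFit(t, rep(0L, 60), cbind(x = x)), "no events")
  expect_error(coxFit(t, e, cbind(x = rep(2, 60))), "constant")
  # perfect separation: the lone early event has the extreme covariate
  expect_error(coxFit(c(1, 2, 3, 4, 5), c(1L, 1L, 1L, 0L, 0L),
                      cbind(x = c(3, 2, 1, -1, -2))), "monotone|separat")
})

test_that("null covariates rarely reach |z| > 3", {
  set.seed(51)
  zs <- replicate(500, {
    t <- rexp(80); e <- rbinom(80, 1, 0.6); x <- rnorm(80)
    coxFit(t, e, cbind(x = x))$z
  })
  expect_gte(mean(abs(zs) < 3), 0.99)
})

test_that("Cochran's Q matches hand computation", {
  expect_error(cochranQ(effectTableOf(1, 1)), ">= 2")
  qa <- cochranQ(effectTableOf(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(qa$Q, 0)
  expect_equal(qa$p_Q, 1)
  qb <- cochranQ(effectTableOf(c(0, 2), c(1, 1)))
  expect_equal(qb$Q, 2)
  expect_equal(qb$df, 1L)
  expect_equal(qb$p_Q, 0.15729921, tolerance = 1e-7)
  qc <- cochranQ(effectTableOf(rep(0.7, 5), rep(0.2, 5)))
  expect_equal(qc$Q, 0)
})

test_that("meta-analysis matches hand-computed fixed and random pooling", {
  m1 <- metaEffect(effectTableOf(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(m1@pooledEffect, 1)
  expect_equal(m1@se, 1 / sqrt(3))
  expect_equal(m1@Q, 0)
  expect_identical(m1@model, "fixed")
  m2 <- metaEffect(effectTableOf(c(0, 2), c(1, 1)))
  expect_equal(m2@pooledEffect, 1)      # p_Q = 0.157 -> fixed retained
  expect_equal(m2@se, 1 / sqrt(2))
  expect_identical(m2@model, "fixed")
  m3 <- metaEffect(effectTableOf(0.4, 0.1))
  expect_equal(m3@pooledEffect, 0.4)
  expect_equal(m3@se, 0.1)
  expect_identical(m3@model, "fixed")
  expect_equal(m3@Q, 0)
  expect_equal(m3@df, 0L)
  expect_error(metaEffect(data.frame()), "non-empty")
})

test_that("random-effects pooling equals DerSimonian-Laird by hand and metafor", {
  skip_if_not_installed("metafor")
  set.seed(53)
  for (i in 1:10) {
    k <- sample(3:12, 1)
    e <- rnorm(k, 0.3, 0.4)
    se <- runif(k, 0.05, 0.5)
    mine <- metaEffect(effectTableOf(e, se), model = "random")
    hand <- handMeta(e, se)
    expect_equal(mine@pooledEffect, hand$random, tolerance = 1e-12)
    expect_equal(mine@se, hand$se_random, tolerance = 1e-12)
    expect_equal(mine@tau2, hand$tau2, tolerance = 1e-12)
    ref <- metafor::rma(yi = e, sei = se, method = "DL")
    expect_equal(mine@pooledEffect, unname(ref$beta[1]), tolerance = 1e-10)
    expect_equal(mine@tau2, ref$tau2, tolerance = 1e-10)
  }
})

test_that("random-effects reduces exactly to fixed when tau2 = 0", {
  e <- c(0.5, 0.52, 0.48); se <- c(0.3, 0.3, 0.3)  # Q < k - 1 -> tau2 = 0
  stopifnot(handMeta(e, se)$tau2 == 0)
  mf <- metaEffect(effectTableOf(e, se), model = "fixed")
  mr <- metaEffect(effectTableOf(e, se), model = "random")
  expect_equal(mr@pooledEffect, mf@pooledEffect, tolerance = 1e-15)
  expect_equal(mr@se, mf@se, tolerance = 1e-15)
})

test_that("per-cohort gene HRs skip unusable cohorts with reasons", {
  cfg <- simulationConfig(n_cohorts = 3, samples_per_cohort = 60,
                          n_genes = 40, n_proliferation_genes = 8, seed = 55)
  coll <- simulateCohortCollection(cfg)
  ests <- perDatasetGeneHR(coll, "PGRMC1")
  expect_equal(nrow(ests), 3L)
  expect_identical(unique(ests$effect_type), "log_hr")
  expect_true(all(ests$se > 0))
  # a cohort without survival data is skipped, not fatal
  m <- matrix(rnorm(40 * 5, 8), 40, 5,
              dimnames = list(rownames(coll[[1]]), sprintf("x%d", 1:5)))
  noSurv <- makeCohort(m, id = "NOSURV")
  coll2 <- newCohortCollection(c(as.list(coll), list(noSurv)))
  ests2 <- perDatasetGeneHR(coll2, "PGRMC1")
  expect_equal(nrow(ests2), 3L)
  sk <- attr(ests2, "skipped")
  expect_identical(sk$cohort_id, "NOSURV")
  expect_identical(sk$reason, "no_survival_data")
  expect_error(perDatasetGeneHR(coll, "ABSENT"), "absent from every cohort")
})

test_that("gene standardization makes the HR per-SD (scale invariant)", {
  cfg <- simulationConfig(n_cohorts = 2, samples_per_cohort = 80,
                          n_genes = 30, n_proliferation_genes = 5, seed = 57)
  coll <- simulateCohortCollection(cfg)
  e1 <- perDatasetGeneHR(coll, "PGRMC1")
  # rescale the gene by 10x in a copied collection: per-SD log HR unchanged
  rescaled <- lapply(as.list(coll), function(coh) {
    m <- exprsMatrix(coh)
    m["PGRMC1", ] <- 10 * m["PGRMC1", ]
    clin <- cbind(sample_id = colnames(coh),
                  as.data.frame(clinicalData(coh)))
    assembleDataset(m, clin, cohortId(coh), platformName(coh),
                    endpointType(coh))
  })
  e2 <- perDatasetGeneHR(newCohortCollection(rescaled), "PGRMC1")
  expect_equal(e2$effect, e1$effect, tolerance = 1e-9)
})

test_that("stratum filters subset samples and keep the cohort class", {
  cfg <- simulationConfig(n_cohorts = 1, samples_per_cohort = 50,
                          n_genes = 20, n_proliferation_genes = 4, seed = 59)
  coh <- simulateCohortCollection(cfg)[[1]]
  sub <- filterStratum(coh, c(er = "positive"))
  expect_s4_class(sub, "ExpressionCohort")
  expect_true(all(clinicalData(sub)$er == "positive"))
  expect_equal(ncol(filterStratum(coh, character())), 50L)
  expect_equal(ncol(filterStratum(coh, c(no_such = "x"))), 0L)
})

test_that("forest tables carry per-cohort rows plus a pooled footer", {
  ests <- effectTableOf(c(0.2, 0.3, 0.25), c(0.1, 0.12, 0.09))
  ests$n <- c(100L, 120L, 90L); ests$events <- c(40L, 50L, 30L)
  meta <- metaEffect(ests)
  ft <- forestTable(ests, meta)
  expect_equal(nrow(ft), 4L)
  expect_identical(ft$cohort_id[4], "pooled")
  expect_equal(ft$hr, exp(ft$log_hr))
  expect_equal(sum(ft$weight_pct[1:3]), 100)
})
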