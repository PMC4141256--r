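test_that("Kaplan-Meier steps match the product-limit formula by hand", {
  # times (1,2,3), events (1,0,1): S = 2/3 after t=1, unchanged at the
  # censoring, drops to 0 at t=3 (1 at risk, 1 event)
  km <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  s1 <- km$surv[km$time == 1]
  s3 <- km$surv[km$time == 3]
  expect_equal(s1, 2 / 3)
  expect_equal(s3, 0)
  # all censored: S stays 1
  km0 <- kmEstimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # curves are non-increasing, start from probabilities in [0,1]
  expect_true(all(diff(km$surv) <= 0))
  # duplicating every patient leaves the curve unchanged
  km2 <- kmEstimate(rep(c(1, 2, 3), 2), rep(c(1, 0, 1), 2))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)
})

test_that("log-rank equals brute-force O-E/V accumulation and is symmetric", {
  withr::with_seed(17, {
    for (r in 1:5) {
      tt <- sample(1:50, 10)
      ev <- rbinom(10, 1, 0.7)
      gr <- rep(c("a", "b"), 5)
      if (sum(ev) == 0) ev[1] <- 1
      lr <- logrankTest(tt, ev, gr)
      expect_equal(lr$chisq, bruteLogrank(tt, ev, gr), tolerance = 1e-10)
      swap <- logrankTest(tt, ev, ifelse(gr == "a", "b", "a"))
      expect_equal(swap$chisq, lr$chisq, tolerance = 1e-12)
      expect_equal(sum(lr$observed - lr$expected), 0, tolerance = 1e-10)
    }
  })
  # both groups identical copies of the same patients: no difference
  lr0 <- logrankTest(c(2, 5, 9, 2, 5, 9), c(1, 1, 0, 1, 1, 0),
                     rep(c("a", "b"), each = 3))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)
  expect_error(logrankTest(c(1, 2), c(1, 1), c("a", "a")))
})

test_that("Cox fits agree with the score-test/log-rank identity and a grid
          search", {
  withr::with_seed(23, {
    tt <- runif(20, 1, 100)          # tie-free
    ev <- rbinom(20, 1, 0.8)
    gr <- rep(c(0, 1), 10)
  })
  fit <- coxFit(tt, ev, data.frame(g = gr), tiesMethod = "breslow")
  lr <- logrankTest(tt, ev, gr)
  expect_equal(attr(fit, "scoreTest"), lr$chisq, tolerance = 1e-8)

  # covariate negation: beta flips, HR inverts, p unchanged
  fitNeg <- coxFit(tt, ev, data.frame(g = 1 - gr), tiesMethod = "breslow")
  expect_equal(fitNeg$beta, -fit$beta, tolerance = 1e-8)
  expect_equal(fitNeg$HR, 1 / fit$HR, tolerance = 1e-8)
  expect_equal(fitNeg$p, fit$p, tolerance = 1e-10)

  # 6-patient toy: beta matches brute-force partial-likelihood maximization
  t6 <- c(3, 5, 7, 11, 13, 17); e6 <- c(1, 1, 0, 1, 1, 1)
  x6 <- c(0, 1, 0, 1, 1, 0)
  fit6 <- coxFit(t6, e6, data.frame(x = x6), tiesMethod = "breslow")
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, partialLogLik, numeric(1), time = t6, event = e6,
               x = x6)
  expect_equal(fit6$beta, grid[which.max(ll)], tolerance = 1e-4)
  expect_equal(fit6$z, fit6$beta / fit6$se)
  expect_true(fit6$ciLow < fit6$HR && fit6$HR < fit6$ciHigh)
})

test_that("Cox guards: constant covariates, no events, separation surfaced", {
  expect_error(coxFit(c(1, 2, 3), c(1, 1, 0), data.frame(x = c(1, 1, 1))),
               "constant")
  expect_error(coxFit(c(1, 2, 3), c(0, 0, 0), data.frame(x = c(1, 2, 3))),
               "event")
  # monotone likelihood (perfect separation) is reported, not silent
  tt <- c(1, 2, 3, 4, 10, 11, 12, 13)
  ev <- rep(1, 8)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)   # all early events in group 1
  expect_warning(fitSep <- coxFit(tt, ev, data.frame(x = x)), "converge")
  expect_false(attr(fitSep, "converged"))
})

test_that("stratified analysis keys strata and carries whole-cohort groups", {
  study <- simulateStudy(seed = 83, nGenes = 150, nPlanted = 8,
                         betaPerGene = 0.6, nTrain = 120, nValidation = 160)
  model <- fitScoringModel(study$train, GeneSignature(names(study$planted)))
  risk <- riskStratify(model, study$validation)
  age <- SummarizedExperiment::colData(study$validation)$age
  ageGrp <- factor(ifelse(age < 60, "<60", ">=60"),
                   levels = c("<60", ">=60"))
  strat <- stratifiedAnalysis(study$validation, ageGrp, risk)
  expect_setequal(names(strat), c("<60", ">=60"))
  for (s in strat) {
    expect_false(isTRUE(s$unevaluable))
    expect_identical(s$cox$covariate[1], "riskpositive")
  }
  # one-level factor reproduces the unstratified analysis exactly
  whole <- stratifiedAnalysis(study$validation,
                              rep("all", ncol(study$validation)), risk)
  direct <- coxByRiskGroup(study$validation, risk)
  expect_equal(whole$all$cox$beta, direct$beta, tolerance = 1e-12)
  expect_equal(whole$all$logrank$chisq,
               logrankTest(survTime(study$validation),
                           survEvent(study$validation),
                           riskGroup(risk))$chisq)
  # a stratum with a single risk group is flagged unevaluable
  oneGroup <- factor(ifelse(riskGroup(risk) == "positive", "P", "M"))
  strat2 <- stratifiedAnalysis(study$validation, oneGroup, risk)
  expect_true(strat2$P$unevaluable)
})

test_that("multivariate Cox adjusts the risk group for clinical covariates", {
  study <- simulateStudy(seed = 97, nGenes = 150, nPlanted = 8,
                         betaPerGene = 0.6, nTrain = 120, nValidation = 200)
  model <- fitScoringModel(study$train, GeneSignature(names(study$planted)))
  risk <- riskStratify(model, study$validation)
  cd <- SummarizedExperiment::colData(study$validation)
  fit <- coxFit(survTime(study$validation), survEvent(study$validation),
                data.frame(risk = riskGroup(risk), age = cd$age,
                           male = cd$male, stage = cd$stage))
  expect_equal(nrow(fit), 4L)
  expect_true(all(fit$HR > 0))
  expect_gt(fit$HR[fit$covariate == "riskpositive"], 1)
})
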