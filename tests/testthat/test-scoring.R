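test_that("risk scores match the weighted standardized sum by hand", {
  model1 <- new("ScoringModel", genes = "gA", weights = 1, center = 5,
                scale = 2, thresholdRule = "median", dropped = NULL,
                provenance = list())
  mat <- matrix(7, 1, 1, dimnames = list("gA", "p1"))
  expect_equal(as.vector(scorePatients(model1, mat)), 1)   # (7-5)/2

  model2 <- new("ScoringModel", genes = c("gA", "gB"), weights = c(2, -1),
                center = c(0, 0), scale = c(1, 1), thresholdRule = "median",
                dropped = NULL, provenance = list())
  mat2 <- matrix(c(1, 1), 2, 1, dimnames = list(c("gA", "gB"), "p1"))
  s <- scorePatients(model2, mat2)
  # independent dot-product evaluation
  expect_equal(as.vector(s), sum(c(2, -1) * (c(1, 1) - 0) / 1))

  modelZero <- new("ScoringModel", genes = c("gA", "gB"), weights = c(0, 0),
                   center = c(3, 4), scale = c(1, 2),
                   thresholdRule = "median", dropped = NULL,
                   provenance = list())
  mat3 <- matrix(rnorm(6), 2, 3,
                 dimnames = list(c("gA", "gB"), c("p1", "p2", "p3")))
  expect_equal(as.vector(scorePatients(modelZero, mat3)), rep(0, 3))
})

test_that("fitted Wald weights are affine-invariant and sign-recovering", {
  sim <- simulateSurvivalCohort(nGenes = 6, nPatients = 120,
                                beta = c(G0002 = 0.8), noiseSd = 1,
                                seed = 31)
  cohort <- sim$cohort
  model <- fitScoringModel(cohort, c("G0001", "G0002", "G0003"))
  expect_gt(unname(modelWeights(model)["G0002"]), 0)  # planted positive

  # scaling one gene's expression by 10: Z unchanged, mu/tau scale, scores
  # unchanged
  mat <- SummarizedExperiment::assay(cohort)
  mat10 <- mat; mat10["G0001", ] <- 10 * mat10["G0001", ]
  cohort10 <- SurvivalCohort(
    mat10, survTime(cohort), survEvent(cohort))
  model10 <- fitScoringModel(cohort10, c("G0001", "G0002", "G0003"))
  expect_equal(modelWeights(model10), modelWeights(model), tolerance = 1e-6)
  expect_equal(unname(modelCenter(model10)["G0001"]),
               10 * unname(modelCenter(model)["G0001"]))
  expect_equal(unname(modelScale(model10)["G0001"]),
               10 * unname(modelScale(model)["G0001"]))
  expect_equal(scorePatients(model10, cohort10),
               scorePatients(model, cohort), tolerance = 1e-6)
})

test_that("the model is frozen: validation scoring reuses training constants", {
  sim <- simulateSurvivalCohort(nGenes = 5, nPatients = 80,
                                beta = c(G0001 = 0.6), seed = 41)
  model <- fitScoringModel(sim$cohort, c("G0001", "G0002"))
  before <- list(modelWeights(model), modelCenter(model), modelScale(model))
  val <- simulateSurvivalCohort(nGenes = 5, nPatients = 60,
                                beta = c(G0001 = 0.6), seed = 42)$cohort
  sVal <- scorePatients(model, val)
  expect_identical(list(modelWeights(model), modelCenter(model),
                        modelScale(model)), before)
  # shifting the validation expression shifts scores: proof that training
  # (not per-cohort) standardization was applied
  matShift <- SummarizedExperiment::assay(val) + 1
  valShift <- SurvivalCohort(matShift, survTime(val), survEvent(val))
  sShift <- scorePatients(model, valShift)
  expect_false(isTRUE(all.equal(unname(sVal), unname(sShift))))
  # per-cohort mode is invariant to that shift
  expect_equal(unname(scorePatients(model, valShift, standardize = "cohort")),
               unname(scorePatients(model, val, standardize = "cohort")),
               tolerance = 1e-12)
})

test_that("classification uses a strict threshold exactly as documented", {
  s <- setNames(c(1, 2, 3, 4), paste0("p", 1:4))
  cls <- classifyRisk(s, "median")
  expect_identical(as.character(riskGroup(cls)),
                   c("negative", "negative", "positive", "positive"))
  expect_equal(riskThreshold(cls), 2.5)
  # group sizes differ by <= 1 under distinct scores
  expect_lte(abs(diff(table(riskGroup(cls)))), 1)

  allEq <- classifyRisk(setNames(rep(2, 4), paste0("p", 1:4)), "median")
  expect_true(all(riskGroup(allEq) == "negative"))  # none strictly above

  zero <- classifyRisk(setNames(c(-1, 0.5), c("a", "b")), "zero")
  expect_identical(as.character(riskGroup(zero)), c("negative", "positive"))
})

test_that("missing and zero-variance genes are dropped with a report", {
  sim <- simulateSurvivalCohort(nGenes = 5, nPatients = 60, seed = 51)
  mat <- SummarizedExperiment::assay(sim$cohort)
  mat["G0002", ] <- 7   # zero variance
  cohort <- SurvivalCohort(mat, survTime(sim$cohort), survEvent(sim$cohort))
  expect_warning(
    expect_warning(
      model <- fitScoringModel(cohort, c("G0001", "G0002", "NOPE")),
      "absent"),
    "zero-variance")
  expect_identical(modelGenes(model), "G0001")
  expect_setequal(model@dropped, c("NOPE", "G0002"))
  # scoring never renormalizes for missing genes
  matVal <- mat[c("G0001", "G0003"), , drop = FALSE]
  m2 <- new("ScoringModel", genes = c("G0001", "MISSING"),
            weights = c(1, 5), center = c(0, 0), scale = c(1, 1),
            thresholdRule = "median", dropped = NULL, provenance = list())
  expect_warning(s <- scorePatients(m2, matVal), "missing")
  expect_equal(as.vector(s), unname(matVal["G0001", ]))
  expect_error(scorePatients(m2, matVal[integer(0), , drop = FALSE]))
})

test_that("positive risk groups carry more events on aligned cohorts", {
  study <- simulateStudy(seed = 61, nGenes = 200, nPlanted = 10,
                         betaPerGene = 0.5, nTrain = 120, nValidation = 150)
  sig <- GeneSignature(names(study$planted))
  model <- fitScoringModel(study$train, sig)
  risk <- riskStratify(model, study$validation)
  ev <- survEvent(study$validation)
  expect_gt(mean(ev[riskGroup(risk) == "positive"]),
            mean(ev[riskGroup(risk) == "negative"]))
})

test_that("scoring models survive a JSON round trip", {
  sim <- simulateSurvivalCohort(nGenes = 4, nPatients = 50, seed = 71)
  model <- fitScoringModel(sim$cohort, c("G0001", "G0002"),
                           thresholdRule = "zero")
  path <- file.path(withr::local_tempdir(), "model.json")
  writeScoringModel(model, path)
  back <- readScoringModel(path)
  expect_equal(modelWeights(back), modelWeights(model))
  expect_equal(modelScale(back), modelScale(model))
  expect_identical(back@thresholdRule, "zero")
  s1 <- scorePatients(model, sim$cohort)
  s2 <- scorePatients(back, sim$cohort)
  expect_equal(s1, s2)
})
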