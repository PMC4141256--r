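# End-to-end orchestration on synthetic data: simulate -> preprocess ->
# differential expression -> signature derivation -> scoring -> survival
# validation -> resampling -> enrichment, with a deterministic run
# directory (no timestamps, so identical configs give identical bytes).

.annotateGenes <- function(se, nDupPairs = 15L, nSex = 30L) {
  genes <- rownames(se)
  n <- length(genes)
  symbol <- genes
  chromosome <- as.character(rep(1:22, length.out = n))
  if (nSex > 0 && n > nSex) {
    sexIdx <- seq(n - nSex + 1L, n)
    chromosome[sexIdx] <- rep(c("chrX", "Y"), length.out = nSex)
  }
  if (nDupPairs > 0 && n > nSex + 2L * nDupPairs) {
    dupIdx <- seq(n - nSex - 2L * nDupPairs + 1L, n - nSex)
    symbol[dupIdx] <- rep(sprintf("DUP%03d", seq_len(nDupPairs)), each = 2L)
  }
  SummarizedExperiment::rowData(se)$symbol <- symbol
  SummarizedExperiment::rowData(se)$chromosome <- chromosome
  se
}

#' Simulate a complete signature-derivation study
#'
#' Generates the full synthetic input bundle sharing one gene universe and
#' one planted truth: two small-n knockdown datasets, four paired
#' tumor/normal datasets whose planted shifts are aligned in sign with the
#' knockdown effects, and training/validation survival cohorts whose
#' hazard increases with the planted genes' (direction-aligned)
#' expression. A block of low-baseline "absent" genes, duplicated symbols
#' and sex-chromosome genes are planted among the unaffected genes so the
#' preprocessing filters have real work.
#'
#' @param seed master seed; every dataset uses a named sub-stream.
#' @param nGenes gene universe size.
#' @param nPlanted number of planted signature genes (the first
#'   \code{nPlanted} gene IDs, alternating up/down).
#' @param kdEffect absolute log2 knockdown shift.
#' @param kdNoiseSd,kdPerGroup knockdown noise SD and per-arm size.
#' @param tumorShift absolute log2 tumor-vs-normal shift for planted genes.
#' @param pairedPatients patients per paired dataset (length 4 recycled).
#' @param pairedNoiseSd,patientEffectSd paired-design noise components.
#' @param betaPerGene absolute per-gene log-hazard coefficient for planted
#'   genes in the survival cohorts.
#' @param nTrain,nValidation survival cohort sizes.
#' @param survivalNoiseSd log2 expression SD in the survival cohorts.
#' @return list: kd (2 SEs), paired (4 lists of se/pairing), train,
#'   validation (\linkS4class{SurvivalCohort}s), planted (named signed
#'   effects), baselines.
#' @export
simulateStudy <- function(seed = 1, nGenes = 2000, nPlanted = 40,
                          kdEffect = 1, kdNoiseSd = 0.25, kdPerGroup = 5,
                          tumorShift = 1, pairedPatients = c(24, 19, 24, 22),
                          pairedNoiseSd = 0.3, patientEffectSd = 1,
                          betaPerGene = 0.25, nTrain = 150,
                          nValidation = 200, survivalNoiseSd = 1) {
  genes <- .geneIds(nGenes)
  base <- withSeed(substreamSeed(seed, "study_baseline"),
                   runif(nGenes, 6, 12))
  nAbsent <- min(30L, max(0L, nGenes - nPlanted - 100L))
  if (nAbsent > 0) {
    base[seq(nPlanted + 1L, nPlanted + nAbsent)] <- 2  # undetected block
  }
  signs <- rep(c(1, -1), length.out = nPlanted)
  planted <- setNames(kdEffect * signs, genes[seq_len(nPlanted)])

  kd <- lapply(1:2, function(i) {
    sim <- simulateKnockdownPair(
      nGenes = nGenes, nPerGroup = kdPerGroup, deGenes = names(planted),
      kdEffect = unname(planted), noiseSd = kdNoiseSd, baselineMean = base,
      seed = substreamSeed(seed, paste0("kd", i)))
    .annotateGenes(sim$se)
  })
  pairedPatients <- rep_len(pairedPatients, 4L)
  paired <- lapply(1:4, function(i) {
    sim <- simulatePairedTumorNormal(
      nGenes = nGenes, nPatients = pairedPatients[i],
      concordantGenes = names(planted),
      tumorShift = unname(planted) / kdEffect * tumorShift,
      patientEffectSd = patientEffectSd, noiseSd = pairedNoiseSd,
      baselineMean = base, seed = substreamSeed(seed, paste0("tumor", i)))
    list(se = .annotateGenes(sim$se), pairing = sim$pairing)
  })
  beta <- setNames(betaPerGene * signs, names(planted))
  train <- simulateSurvivalCohort(
    nGenes = nGenes, nPatients = nTrain, beta = beta,
    noiseSd = survivalNoiseSd, baselineMean = base,
    seed = substreamSeed(seed, "train"))$cohort
  validation <- simulateSurvivalCohort(
    nGenes = nGenes, nPatients = nValidation, beta = beta,
    noiseSd = survivalNoiseSd, baselineMean = base,
    seed = substreamSeed(seed, "validation"))$cohort
  list(kd = kd, paired = paired, train = train, validation = validation,
       planted = planted, beta = beta, baselines = base)
}

#' Default demo run configuration
#'
#' Every threshold defaults to the workflow's standard value: FDR 0.05,
#' fold change 1.1, support 3 of 4 tumor contrasts, median split, 200
#' resamples for the demo (1000 in a full analysis).
#'
#' @param seed master seed.
#' @return nested configuration list accepted by \code{\link{runPipeline}}.
#' @export
demoConfig <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(nGenes = 2000, nPlanted = 40, kdEffect = 1,
                    kdNoiseSd = 0.25, kdPerGroup = 5, tumorShift = 1,
                    pairedPatients = c(24, 19, 24, 22),
                    pairedNoiseSd = 0.3, patientEffectSd = 1,
                    betaPerGene = 0.25, nTrain = 150, nValidation = 200,
                    survivalNoiseSd = 1),
    preprocess = list(detectionThreshold = 4, minFraction = 2 / 3,
                      dedupMode = "strict"),
    de = list(nPermutations = 200, fdrThreshold = 0.05, fcThreshold = 1.1,
              s0 = "auto"),
    signature = list(minSupport = 3, tumorConcordance = "same"),
    scoring = list(thresholdRule = "median", standardize = "training",
                   tiesMethod = "efron"),
    resampling = list(nResamples = 200, excludeSignature = FALSE,
                      mode = "train-test"),
    enrichment = list(nRandomSets = 5, randomSetSize = 50)
  )
}

.validateConfig <- function(config) {
  for (sec in c("seed", "simulate", "preprocess", "de", "signature",
                "scoring", "resampling")) {
    if (is.null(config[[sec]])) stop("config is missing section '", sec, "'")
  }
  if (config$signature$minSupport > 4) {
    stop("minSupport exceeds the number of tumor contrasts (4)")
  }
  invisible(config)
}

#' Run the demo workflow end-to-end
#'
#' Simulates the study bundle, preprocesses every expression matrix,
#' derives the signature from the two knockdown contrasts and four
#' tumor/normal contrasts, fits the frozen scoring model on the training
#' cohort, validates it (median split, Cox, Kaplan-Meier, log-rank) on the
#' validation cohort, runs the size-matched resampling null and a Fisher
#' enrichment of the derived signature against a planted gene set. All
#' stages are deterministic functions of the config.
#'
#' @param config configuration list (see \code{\link{demoConfig}}) or a
#'   path to a YAML file holding one.
#' @param outDir optional run directory; when given, every stage output,
#'   a JSON manifest (config echo + counts) and a log file are written.
#' @return list with the derived signature, scoring model, per-cohort risk
#'   scores and Cox/KM/log-rank results, resampling and enrichment
#'   results, recovery metrics against the planted truth, and the run
#'   manifest.
#' @export
runPipeline <- function(config = demoConfig(), outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validateConfig(config)
  logLines <- character(0)
  note <- function(...) {
    logLines <<- c(logLines, sprintf(...))
  }

  sim <- do.call(simulateStudy, c(list(seed = config$seed),
                                  config$simulate))
  note("simulated: %d genes, %d planted", config$simulate$nGenes,
       config$simulate$nPlanted)

  pp <- config$preprocess
  prep <- function(se) preprocessMatrix(
    se, detectionThreshold = pp$detectionThreshold,
    minFraction = pp$minFraction, dedupMode = pp$dedupMode)
  kd <- lapply(sim$kd, prep)
  paired <- lapply(sim$paired, function(x) {
    list(se = prep(x$se), pairing = x$pairing)
  })
  note("preprocess: %d genes retained in KD1", nrow(kd[[1]]))

  de <- config$de
  kdDE <- lapply(seq_along(kd), function(i) {
    samDE(kd[[i]], SummarizedExperiment::colData(kd[[i]])$group,
          s0 = de$s0, nPermutations = de$nPermutations,
          fdrThreshold = de$fdrThreshold, fcThreshold = de$fcThreshold,
          groups = c("WT", "KD"),
          seed = substreamSeed(config$seed, paste0("samde", i)))
  })
  note("knockdown DE: %d and %d significant genes",
       length(significantGenes(kdDE[[1]])),
       length(significantGenes(kdDE[[2]])))
  tumorDE <- lapply(paired, function(x) {
    pairedDE(x$se, x$pairing, fdrThreshold = de$fdrThreshold)
  })

  sigCfg <- config$signature
  signature <- deriveSignature(kdDE[[1]], kdDE[[2]], tumorDE,
                               minSupport = sigCfg$minSupport,
                               tumorConcordance = sigCfg$tumorConcordance)
  note("signature: %d genes", length(signatureGenes(signature)))
  plantedGenes <- names(sim$planted)
  sg <- signatureGenes(signature)
  recovery <- list(
    nSignature = length(sg),
    sensitivity = if (length(plantedGenes))
      mean(plantedGenes %in% sg) else NA_real_,
    offTargetFraction = if (length(sg))
      mean(!sg %in% plantedGenes) else 0)

  sc <- config$scoring
  model <- fitScoringModel(sim$train, signature,
                           thresholdRule = sc$thresholdRule,
                           tiesMethod = sc$tiesMethod)
  riskTrain <- riskStratify(model, sim$train, standardize = sc$standardize)
  riskVal <- riskStratify(model, sim$validation,
                          standardize = sc$standardize)
  survRes <- lapply(list(train = list(sim$train, riskTrain),
                         validation = list(sim$validation, riskVal)),
                    function(x) {
    cohort <- x[[1]]; risk <- x[[2]]
    list(cox = coxByRiskGroup(cohort, risk, tiesMethod = sc$tiesMethod),
         km = kmEstimate(survTime(cohort), survEvent(cohort),
                         riskGroup(risk)),
         logrank = logrankTest(survTime(cohort), survEvent(cohort),
                               riskGroup(risk)))
  })
  note("validation HR = %.2f (log-rank p = %.3g)",
       survRes$validation$cox$HR[1], survRes$validation$logrank$p)

  rs <- config$resampling
  resampling <- randomSignatureNull(
    sim$train, sim$validation, signature, nResamples = rs$nResamples,
    excludeSignature = isTRUE(rs$excludeSignature), mode = rs$mode,
    standardize = sc$standardize, tiesMethod = sc$tiesMethod,
    seed = substreamSeed(config$seed, "null"))
  note("resampling: observed Z = %.2f, right-tail p = %.4g",
       observedZ(resampling), resamplingP(resampling))

  universe <- rownames(kd[[1]])
  en <- config$enrichment
  sets <- withSeed(substreamSeed(config$seed, "genesets"), {
    s <- list(planted = intersect(plantedGenes, universe))
    for (i in seq_len(en$nRandomSets)) {
      s[[sprintf("random%02d", i)]] <-
        sample(universe, min(en$randomSetSize, length(universe)))
    }
    s
  })
  enrichment <- if (length(sg)) {
    fisherEnrichment(intersect(sg, universe), sets, universe)
  } else NULL

  manifest <- list(
    package = "survSig",
    version = as.character(packageVersion("survSig")),
    seed = config$seed,
    config = config,
    counts = list(
      genesSimulated = config$simulate$nGenes,
      genesAfterPreprocess = nrow(kd[[1]]),
      signatureSize = length(sg)),
    recovery = recovery)

  result <- list(signature = signature, model = model,
                 riskTrain = riskTrain, riskValidation = riskVal,
                 survival = survRes, resampling = resampling,
                 enrichment = enrichment, recovery = recovery,
                 kdDE = kdDE, tumorDE = tumorDE, sim = sim,
                 manifest = manifest, log = logLines)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeSignature(signature, file.path(outDir, "signature.tsv"))
    writeScoringModel(model, file.path(outDir, "scoring_model.json"))
    for (nm in c("train", "validation")) {
      risk <- if (nm == "train") riskTrain else riskVal
      write.table(
        data.frame(sample = names(riskScore(risk)),
                   score = sprintf("%.10g", riskScore(risk)),
                   group = as.character(riskGroup(risk))),
        file.path(outDir, paste0("scores_", nm, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      cox <- survRes[[nm]]$cox
      cox$beta <- sprintf("%.10g", cox$beta)
      write.table(cox[, c("covariate", "HR", "ciLow", "ciHigh", "p")],
                  file.path(outDir, paste0("cox_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(survRes[[nm]]$km,
                  file.path(outDir, paste0("km_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(data.frame(z = sprintf("%.10g", nullZ(resampling))),
                file.path(outDir, "resampling_null.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(observedZ = observedZ(resampling),
           p = resamplingP(resampling),
           redraws = resampling@redraws,
           config = resampling@config),
      file.path(outDir, "resampling.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    if (!is.null(enrichment)) {
      write.table(enrichment, file.path(outDir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(logLines, file.path(outDir, "run.log"))
  }
  result
}
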