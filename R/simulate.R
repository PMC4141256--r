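# Synthetic-data generators with planted, recoverable ground truth.
#
# All matrices are log2-scale Gaussian around per-gene baselines; survival
# follows a Weibull proportional-hazards model on standardized expression.
# A single master seed fans out into named sub-streams (baseline, noise,
# survival, ...) so adding one generated object never shifts another's draws.

.geneIds <- function(n) sprintf("G%04d", seq_len(n))

.baselines <- function(nGenes, baselineMean, seed) {
  if (is.null(baselineMean)) {
    withSeed(substreamSeed(seed, "baseline"), runif(nGenes, 6, 12))
  } else {
    rep_len(baselineMean, nGenes)
  }
}

.resolvePlanted <- function(planted, effect, genes) {
  if (is.null(planted) || length(planted) == 0L) {
    return(setNames(numeric(0), character(0)))
  }
  if (is.numeric(planted) && length(planted) == 1L && is.null(names(planted))) {
    planted <- head(genes, planted)           # first k genes by convention
  }
  planted <- as.character(planted)
  if (!all(planted %in% genes)) {
    stop("planted gene IDs not in the gene universe: ",
         paste(setdiff(planted, genes), collapse = ", "))
  }
  setNames(rep_len(effect, length(planted)), planted)
}

#' Simulate a wild-type vs knockdown expression pair
#'
#' Generates a two-arm log2 expression matrix emulating a small-n gene
#' knockdown experiment: every gene has a Gaussian baseline; planted genes
#' are shifted by \code{kdEffect} log2 units in the knockdown arm.
#'
#' @param nGenes number of genes.
#' @param nPerGroup samples per arm (>= 1).
#' @param deGenes planted genes: a count (first k genes) or gene IDs.
#' @param kdEffect signed log2 shift applied to planted genes in the KD arm;
#'   recycled over the planted set.
#' @param noiseSd residual SD on the log2 scale (> 0 unless exactly 0 for
#'   noise-free constructions).
#' @param baselineMean optional per-gene log2 baseline; default draws one
#'   uniformly in [6, 12].
#' @param seed master seed.
#' @return list with \code{se} (a SummarizedExperiment; colData column
#'   \code{group} in \{"WT","KD"\}), \code{labels}, and \code{truth}
#'   (named vector of planted effects).
#' @export
simulateKnockdownPair <- function(nGenes = 1000, nPerGroup = 5, deGenes = 0,
                                  kdEffect = 1, noiseSd = 0.3,
                                  baselineMean = NULL, seed = 1) {
  .assertScalarNum(nGenes, "nGenes", positive = TRUE)
  .assertScalarNum(noiseSd, "noiseSd", nonneg = TRUE)
  if (nPerGroup < 1) stop("nPerGroup must be positive")
  genes <- .geneIds(nGenes)
  planted <- .resolvePlanted(deGenes, kdEffect, genes)
  base <- .baselines(nGenes, baselineMean, seed)
  nS <- 2L * nPerGroup
  mat <- matrix(base, nGenes, nS)
  if (noiseSd > 0) {
    mat <- mat + withSeed(substreamSeed(seed, "noise"),
                          matrix(rnorm(nGenes * nS, 0, noiseSd), nGenes, nS))
  }
  labels <- rep(c("WT", "KD"), each = nPerGroup)
  kd_cols <- which(labels == "KD")
  if (length(planted)) {
    mat[match(names(planted), genes), kd_cols] <-
      mat[match(names(planted), genes), kd_cols] + planted
  }
  dimnames(mat) <- list(genes, sprintf("S%02d_%s", seq_len(nS), labels))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    colData = S4Vectors::DataFrame(group = labels,
                                   row.names = colnames(mat)))
  S4Vectors::metadata(se)$truth <- planted
  list(se = se, labels = labels, truth = planted)
}

#' Simulate paired tumor/normal expression with a patient random effect
#'
#' Each patient contributes one normal and one tumor sample sharing a
#' patient-level random intercept; planted genes carry a signed
#' tumor-minus-normal log2 shift. The random intercept cancels exactly in
#' paired differences.
#'
#' @param nGenes number of genes.
#' @param nPatients number of patients (>= 2); the matrix has 2 x nPatients
#'   columns.
#' @param concordantGenes planted genes: a count or gene IDs.
#' @param tumorShift signed log2 tumor-vs-normal shift for planted genes,
#'   recycled.
#' @param patientEffectSd SD of the per-patient random intercept (>= 0).
#' @param noiseSd residual log2 SD.
#' @param baselineMean optional per-gene baseline (see
#'   \code{\link{simulateKnockdownPair}}).
#' @param seed master seed.
#' @return list with \code{se} (colData: \code{patient}, \code{tissue}),
#'   \code{pairing} (data.frame normal/tumor sample IDs), \code{truth}.
#' @export
simulatePairedTumorNormal <- function(nGenes = 1000, nPatients = 20,
                                      concordantGenes = 0, tumorShift = 1,
                                      patientEffectSd = 1, noiseSd = 0.3,
                                      baselineMean = NULL, seed = 1) {
  if (nPatients < 2) stop("nPatients must be >= 2")
  .assertScalarNum(patientEffectSd, "patientEffectSd", nonneg = TRUE)
  genes <- .geneIds(nGenes)
  planted <- .resolvePlanted(concordantGenes, tumorShift, genes)
  base <- .baselines(nGenes, baselineMean, seed)
  nS <- 2L * nPatients
  pat <- rep(seq_len(nPatients), each = 2L)
  tissue <- rep(c("normal", "tumor"), nPatients)
  mat <- matrix(base, nGenes, nS)
  if (patientEffectSd > 0) {
    intercepts <- withSeed(substreamSeed(seed, "patient"),
                           rnorm(nPatients, 0, patientEffectSd))
    mat <- mat + matrix(intercepts[pat], nGenes, nS, byrow = TRUE)
  }
  if (noiseSd > 0) {
    mat <- mat + withSeed(substreamSeed(seed, "noise"),
                          matrix(rnorm(nGenes * nS, 0, noiseSd), nGenes, nS))
  }
  if (length(planted)) {
    tumor_cols <- which(tissue == "tumor")
    mat[match(names(planted), genes), tumor_cols] <-
      mat[match(names(planted), genes), tumor_cols] + planted
  }
  dimnames(mat) <- list(genes, sprintf("P%02d_%s", pat, tissue))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    colData = S4Vectors::DataFrame(patient = pat, tissue = tissue,
                                   row.names = colnames(mat)))
  S4Vectors::metadata(se)$truth <- planted
  pairing <- data.frame(patient = seq_len(nPatients),
                        normal = colnames(mat)[tissue == "normal"],
                        tumor = colnames(mat)[tissue == "tumor"])
  list(se = se, pairing = pairing, truth = planted)
}

#' Simulate a survival cohort with expression-driven hazard
#'
#' Expression is Gaussian log2 noise around per-gene baselines; the event
#' time is Weibull with proportional hazards on the linear predictor
#' sum(beta_g * z_g), where z_g is the cohort-standardized expression of
#' gene g. Observed time is the minimum of event time, an independent
#' exponential censoring time and an administrative horizon.
#'
#' @param nGenes number of genes.
#' @param nPatients cohort size.
#' @param beta named numeric of signed log-hazard coefficients per planted
#'   gene (names must be gene IDs).
#' @param shape,scale Weibull baseline parameters (> 0); scale in months.
#' @param censorRate rate of the independent exponential censoring process
#'   (>= 0; 0 disables it).
#' @param adminTime administrative censoring horizon in months (> 0; Inf
#'   disables it).
#' @param noiseSd log2 expression SD around the baseline (> 0).
#' @param covariateHazard named numeric of log-hazard coefficients for the
#'   simulated clinical covariates (\code{age}, \code{male},
#'   \code{smoking}, \code{stage}); defaults to no covariate effect, the
#'   optional confounding knob.
#' @param baselineMean optional per-gene baseline.
#' @param seed master seed.
#' @return list with \code{cohort} (a \linkS4class{SurvivalCohort} carrying
#'   age/male/smoking/stage covariates) and \code{truth} (beta, per-patient
#'   linear predictor, latent event times).
#' @export
simulateSurvivalCohort <- function(nGenes = 1000, nPatients = 200,
                                   beta = numeric(0), shape = 1.2,
                                   scale = 60, censorRate = 1 / 80,
                                   adminTime = 120, noiseSd = 1,
                                   covariateHazard = numeric(0),
                                   baselineMean = NULL, seed = 1) {
  .assertScalarNum(shape, "shape", positive = TRUE)
  .assertScalarNum(scale, "scale", positive = TRUE)
  .assertScalarNum(censorRate, "censorRate", nonneg = TRUE)
  if (!(is.numeric(adminTime) && length(adminTime) == 1L && adminTime > 0)) {
    stop("adminTime must be > 0 (use Inf to disable)")
  }
  genes <- .geneIds(nGenes)
  if (length(beta)) {
    if (is.null(names(beta)) || !all(names(beta) %in% genes)) {
      stop("beta must be named with gene IDs present in the matrix")
    }
  }
  base <- .baselines(nGenes, baselineMean, seed)
  mat <- matrix(base, nGenes, nPatients) +
    withSeed(substreamSeed(seed, "noise"),
             matrix(rnorm(nGenes * nPatients, 0, max(noiseSd, 0)),
                    nGenes, nPatients))
  dimnames(mat) <- list(genes, sprintf("PT%03d", seq_len(nPatients)))

  cov <- withSeed(substreamSeed(seed, "covariates"), data.frame(
    age = round(rnorm(nPatients, 62, 9), 1),
    male = rbinom(nPatients, 1, 0.5),
    smoking = rbinom(nPatients, 1, 0.45),
    stage = sample(1:3, nPatients, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  ))

  lp <- rep(0, nPatients)
  if (length(beta)) {
    z <- t(base::scale(t(mat[names(beta), , drop = FALSE])))
    lp <- lp + colSums(z * beta)   # beta recycles over rows (genes)
  }
  if (length(covariateHazard)) {
    bad <- setdiff(names(covariateHazard), colnames(cov))
    if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
    for (nm in names(covariateHazard)) {
      x <- cov[[nm]]
      lp <- lp + covariateHazard[[nm]] * as.numeric(base::scale(x))
    }
  }

  draws <- withSeed(substreamSeed(seed, "survival"), {
    u <- runif(nPatients)
    cens <- if (censorRate > 0) rexp(nPatients, censorRate) else
      rep(Inf, nPatients)
    list(u = u, cens = cens)
  })
  # Weibull PH inversion: S(t) = exp(-(t/scale)^shape * exp(lp))
  eventTime <- scale * (-log(draws$u) * exp(-lp))^(1 / shape)
  eventTime <- pmax(eventTime, .Machine$double.eps)
  obsTime <- pmin(eventTime, draws$cens, adminTime)
  event <- as.numeric(eventTime <= pmin(draws$cens, adminTime))

  cohort <- SurvivalCohort(mat, time = obsTime, event = event,
                           covariates = cov)
  truth <- list(beta = beta, linearPredictor = setNames(lp, colnames(mat)),
                eventTime = setNames(eventTime, colnames(mat)))
  S4Vectors::metadata(cohort)$truth <- truth
  list(cohort = cohort, truth = truth)
}
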