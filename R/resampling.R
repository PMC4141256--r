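# Non-randomness test for a signature's prognostic power: compare its Cox
# Wald statistic against a null distribution built from size-matched random
# gene signatures pushed through the identical scoring pipeline.

#' Wald statistic of a gene set's risk split
#'
#' The shared evaluation pipeline used for both the observed signature and
#' every resampled one: fit the Wald-weighted scoring model on the training
#' cohort, score and median-split the evaluation cohort, then take the
#' Wald Z of the univariate Cox fit of positive-vs-negative group. In
#' "in-cohort" mode the weights are fitted on the evaluation cohort itself.
#'
#' @param genes character vector of gene symbols.
#' @param train training \linkS4class{SurvivalCohort}.
#' @param test evaluation \linkS4class{SurvivalCohort}.
#' @param mode "train-test" (default) or "in-cohort".
#' @param standardize passed to \code{\link{scorePatients}}.
#' @param tiesMethod Cox ties handling.
#' @return Wald Z, or NA for a degenerate split (a risk group without
#'   events, or a failed fit).
#' @export
signatureWaldZ <- function(genes, train, test,
                           mode = c("train-test", "in-cohort"),
                           standardize = "training", tiesMethod = "efron") {
  mode <- match.arg(mode)
  fitOn <- if (mode == "train-test") train else test
  z <- tryCatch({
    model <- suppressWarnings(
      fitScoringModel(fitOn, genes, tiesMethod = tiesMethod))
    risk <- riskStratify(model, test, standardize = standardize)
    grp <- riskGroup(risk)
    ev <- survEvent(test)
    if (nlevels(droplevels(grp)) < 2L ||
        min(tapply(ev, grp, sum)) < 1) return(NA_real_)
    cf <- suppressWarnings(coxByRiskGroup(test, risk,
                                          tiesMethod = tiesMethod))
    cf$z[1L]
  }, error = function(e) NA_real_)
  z
}

#' Size-matched random-signature resampling null
#'
#' Draws \code{nResamples} random gene signatures of the same size as the
#' tested one (sampling without replacement from the gene pool), runs each
#' through the identical scoring pipeline (\code{\link{signatureWaldZ}}),
#' and compares the observed Wald Z against the null distribution with a
#' right-tailed add-one empirical p:
#' p = (1 + #\{Z_null >= Z_obs\}) / (1 + nResamples), so p is never 0.
#'
#' @param train,test training and evaluation \linkS4class{SurvivalCohort}s.
#' @param signature a \linkS4class{GeneSignature} or character vector.
#' @param nResamples number of random signatures (default 1000).
#' @param pool gene pool to draw from; default all genes shared by both
#'   cohorts. The tested signature's genes are kept in the pool unless
#'   \code{excludeSignature}.
#' @param excludeSignature drop the tested genes from the pool (default
#'   FALSE).
#' @param signatureSize random-signature size; defaults to the tested
#'   signature's size.
#' @param mode,standardize,tiesMethod see \code{\link{signatureWaldZ}}.
#' @param seed RNG seed (reproducible null vector).
#' @param maxRedrawFactor degenerate draws are redrawn; at most
#'   \code{maxRedrawFactor * nResamples} extra draws before erroring.
#' @return a \linkS4class{ResamplingResult}.
#' @export
randomSignatureNull <- function(train, test, signature, nResamples = 1000,
                                pool = NULL, excludeSignature = FALSE,
                                signatureSize = NULL,
                                mode = "train-test",
                                standardize = "training",
                                tiesMethod = "efron", seed = 1,
                                maxRedrawFactor = 10) {
  genes <- if (is(signature, "GeneSignature")) signatureGenes(signature)
           else as.character(signature)
  if (is.null(pool)) {
    pool <- intersect(rownames(train), rownames(test))
  }
  if (excludeSignature) pool <- setdiff(pool, genes)
  size <- if (is.null(signatureSize)) length(genes) else signatureSize
  if (size > length(pool)) {
    stop("gene pool (", length(pool), ") smaller than signature size (",
         size, ")")
  }
  if (nResamples < 1) stop("nResamples must be >= 1")

  obs <- signatureWaldZ(genes, train, test, mode = mode,
                        standardize = standardize, tiesMethod = tiesMethod)
  if (is.na(obs)) stop("degenerate risk split for the tested signature")

  redraws <- 0L
  nullZ <- withSeed(substreamSeed(seed, "resampling"), {
    out <- numeric(nResamples)
    maxDraws <- nResamples * (1 + maxRedrawFactor)
    drawn <- 0L
    b <- 1L
    while (b <= nResamples) {
      if (drawn >= maxDraws) {
        stop("too many degenerate resamples (", redraws, " redraws)")
      }
      g <- sample(pool, size)
      drawn <- drawn + 1L
      z <- signatureWaldZ(g, train, test, mode = mode,
                          standardize = standardize,
                          tiesMethod = tiesMethod)
      if (is.na(z)) { redraws <- redraws + 1L; next }
      out[b] <- z
      b <- b + 1L
    }
    out
  })
  p <- (1 + sum(nullZ >= obs)) / (1 + nResamples)
  new("ResamplingResult", observedZ = obs, nullZ = nullZ, pValue = p,
      redraws = redraws,
      config = list(nResamples = nResamples, signatureSize = size,
                    poolSize = length(pool),
                    excludeSignature = excludeSignature, mode = mode,
                    standardize = standardize, tiesMethod = tiesMethod,
                    seed = seed, pEstimator = "add-one right tail"))
}
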