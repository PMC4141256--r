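# Risk scoring: per-gene univariate Cox Wald weights fitted on a training
# cohort, frozen together with the training standardization constants, then
# applied to any cohort. S = sum_i Z_i * (e_i - mu_i) / tau_i; a higher
# score implies a poorer outcome.

#' Fit the Wald-weighted scoring model on a training cohort
#'
#' For each signature gene, a univariate Cox proportional-hazards
#' regression of survival on that gene's expression gives the Wald
#' statistic Z_i = beta_i / SE(beta_i); mu_i and tau_i are the mean and
#' sample SD of the gene across all training samples. The model (weights
#' and scaling constants) is frozen at fit time and never recomputed when
#' scoring validation cohorts.
#'
#' @param cohort a \linkS4class{SurvivalCohort} (training).
#' @param signature a \linkS4class{GeneSignature} or character vector of
#'   gene symbols.
#' @param thresholdRule default classification rule stored with the model:
#'   "median" (cohort median split) or "zero" (absolute cutoff).
#' @param tiesMethod Cox ties handling, "efron" (default) or "breslow".
#' @return a \linkS4class{ScoringModel}. Signature genes missing from the
#'   cohort or with zero variance are dropped with a warning and recorded.
#' @export
fitScoringModel <- function(cohort, signature,
                            thresholdRule = c("median", "zero"),
                            tiesMethod = c("efron", "breslow")) {
  thresholdRule <- match.arg(thresholdRule)
  tiesMethod <- match.arg(tiesMethod)
  stopifnot(is(cohort, "SurvivalCohort"))
  genes <- if (is(signature, "GeneSignature")) signatureGenes(signature)
           else as.character(signature)
  if (sum(survEvent(cohort)) < 2) {
    stop("training cohort must contain at least 2 events")
  }
  mat <- .exprsAssay(cohort)
  missing <- setdiff(genes, rownames(mat))
  if (length(missing)) {
    warning(length(missing), " signature gene(s) absent from training: ",
            paste(head(missing, 5L), collapse = ", "))
  }
  genes <- intersect(genes, rownames(mat))
  tau <- apply(mat[genes, , drop = FALSE], 1L, sd)
  zerovar <- genes[tau == 0 | !is.finite(tau)]
  if (length(zerovar)) {
    warning(length(zerovar), " zero-variance gene(s) dropped: ",
            paste(head(zerovar, 5L), collapse = ", "))
  }
  genes <- setdiff(genes, zerovar)
  if (!length(genes)) stop("no usable signature genes in the training cohort")
  srv <- survival::Surv(survTime(cohort), survEvent(cohort))
  Z <- vapply(genes, function(g) {
    fit <- survival::coxph(srv ~ x, data = data.frame(x = mat[g, ]),
                           ties = tiesMethod)
    unname(coef(fit) / sqrt(fit$var[1, 1]))
  }, numeric(1))
  new("ScoringModel",
      genes = genes,
      weights = unname(Z),
      center = unname(rowMeans(mat[genes, , drop = FALSE])),
      scale = unname(apply(mat[genes, , drop = FALSE], 1L, sd)),
      thresholdRule = thresholdRule,
      dropped = c(missing, zerovar),
      provenance = list(nTrain = ncol(cohort),
                        nEvents = sum(survEvent(cohort)),
                        tiesMethod = tiesMethod))
}

#' Apply a frozen scoring model to a cohort
#'
#' Computes S = sum_i Z_i * (e_i - mu_i) / tau_i per patient. By default
#' mu and tau are the frozen training constants; \code{standardize =
#' "cohort"} re-standardizes within the scored cohort instead (the
#' leak-prone alternative reading; its use is recorded in the result
#' attributes). Model genes missing from the cohort are dropped without
#' renormalizing the remaining weights.
#'
#' @param model a \linkS4class{ScoringModel}.
#' @param cohort a \linkS4class{SurvivalCohort} or SummarizedExperiment.
#' @param standardize "training" (default) or "cohort".
#' @return named numeric vector of scores with attributes
#'   \code{droppedGenes} and \code{standardize}.
#' @export
scorePatients <- function(model, cohort,
                          standardize = c("training", "cohort")) {
  standardize <- match.arg(standardize)
  mat <- .exprsAssay(cohort)
  genes <- modelGenes(model)
  present <- genes %in% rownames(mat)
  if (!any(present)) stop("all model genes are missing from the cohort")
  dropped <- genes[!present]
  if (length(dropped)) {
    warning(length(dropped), " model gene(s) missing at scoring time: ",
            paste(head(dropped, 5L), collapse = ", "))
  }
  genes <- genes[present]
  Z <- modelWeights(model)[genes]
  if (standardize == "training") {
    mu <- modelCenter(model)[genes]
    tau <- modelScale(model)[genes]
  } else {
    mu <- rowMeans(mat[genes, , drop = FALSE])
    tau <- apply(mat[genes, , drop = FALSE], 1L, sd)
    if (any(tau == 0)) stop("zero-variance gene under cohort standardization")
  }
  std <- (mat[genes, , drop = FALSE] - mu) / tau
  s <- colSums(std * Z)
  attr(s, "droppedGenes") <- dropped
  attr(s, "standardize") <- standardize
  s
}

#' Classify patients into risk groups
#'
#' Positive means score strictly greater than the threshold: the cohort
#' median under the "median" rule (computed within the cohort being
#' classified) or 0 under the "zero" rule.
#'
#' @param scores named numeric vector from \code{\link{scorePatients}}.
#' @param rule "median" or "zero".
#' @return a \linkS4class{RiskScores} object.
#' @export
classifyRisk <- function(scores, rule = c("median", "zero")) {
  rule <- match.arg(rule)
  if (rule == "median" && length(scores) < 2L) {
    stop("median rule needs at least 2 patients")
  }
  thr <- if (rule == "median") median(scores) else 0
  grp <- factor(ifelse(scores > thr, "positive", "negative"),
                levels = c("negative", "positive"))
  new("RiskScores", score = scores, group = grp, threshold = unname(thr),
      rule = rule,
      droppedGenes = attr(scores, "droppedGenes"))
}

#' Score and classify in one step
#'
#' @inheritParams scorePatients
#' @param rule overrides the model's stored threshold rule if given.
#' @return a \linkS4class{RiskScores}.
#' @export
riskStratify <- function(model, cohort, rule = NULL,
                         standardize = "training") {
  s <- scorePatients(model, cohort, standardize = standardize)
  classifyRisk(s, rule = if (is.null(rule)) model@thresholdRule else rule)
}

#' Serialize / load a scoring model as JSON
#'
#' @param model a \linkS4class{ScoringModel}.
#' @param path JSON file path.
#' @return invisibly the path; \code{readScoringModel} returns the model.
#' @export
writeScoringModel <- function(model, path) {
  jsonlite::write_json(list(
    genes = modelGenes(model),
    weights = unname(modelWeights(model)),
    center = unname(modelCenter(model)),
    scale = unname(modelScale(model)),
    thresholdRule = model@thresholdRule,
    dropped = model@dropped,
    provenance = provenance(model)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeScoringModel
#' @export
readScoringModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ScoringModel", genes = x$genes, weights = x$weights,
      center = x$center, scale = x$scale, thresholdRule = x$thresholdRule,
      dropped = if (length(x$dropped)) x$dropped else NULL,
      provenance = as.list(x$provenance))
}
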