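#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' SurvivalCohort: expression plus follow-up per patient
#'
#' A \linkS4class{SummarizedExperiment} whose \code{colData} carries
#' right-censored follow-up: \code{survTime} (months, strictly positive) and
#' \code{survEvent} (1 = recurrence/event, 0 = censored), plus any clinical
#' covariates. The first assay holds log2 expression (genes x patients).
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("SurvivalCohort", contains = "SummarizedExperiment")

setValidity("SurvivalCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("survTime", "survEvent") %in% colnames(cd))) {
    return("colData must contain 'survTime' and 'survEvent'")
  }
  tt <- cd$survTime
  ev <- cd$survEvent
  if (!is.numeric(tt) || any(!is.finite(tt)) || any(tt <= 0)) {
    return("survTime must be finite and > 0")
  }
  if (!all(ev %in% c(0, 1))) return("survEvent must be 0 or 1")
  TRUE
})

#' Construct a SurvivalCohort
#'
#' @param exprs numeric matrix of log2 expression, genes x patients, with
#'   dimnames.
#' @param time numeric vector of follow-up times (months), one per patient.
#' @param event 0/1 event indicators (1 = event observed).
#' @param covariates optional \code{data.frame} of clinical covariates, one
#'   row per patient.
#' @return A \linkS4class{SurvivalCohort}.
#' @export
SurvivalCohort <- function(exprs, time, event, covariates = NULL) {
  exprs <- as.matrix(exprs)
  if (is.null(rownames(exprs)) || is.null(colnames(exprs))) {
    stop("expression matrix needs row (gene) and column (patient) names")
  }
  cd <- S4Vectors::DataFrame(survTime = as.numeric(time),
                             survEvent = as.numeric(event),
                             row.names = colnames(exprs))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != ncol(exprs)) {
      stop("covariates must have one row per patient")
    }
    cd <- cbind(cd, S4Vectors::DataFrame(covariates))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd)
  new("SurvivalCohort", se)
}

#' Differential-expression result for one two-group or paired contrast
#'
#' @slot table per-gene data.frame: gene, statistic, log2FC, foldChange
#'   (symmetric, >= 1), direction (+1/-1/0), pvalue (paired mode),
#'   qvalue (permutation q or BH-adjusted p), significant.
#' @slot method "sam" or "pairedT".
#' @slot params list of thresholds and settings used.
#' @export
setClass("DEResult",
  representation(table = "data.frame", method = "character", params = "list"))

setValidity("DEResult", function(object) {
  tb <- object@table
  need <- c("gene", "statistic", "direction", "qvalue", "significant")
  if (!all(need %in% colnames(tb))) {
    return(paste("table must contain:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(tb$gene)) return("duplicate gene IDs")
  if (!all(tb$direction %in% c(-1, 0, 1))) return("direction must be -1/0/+1")
  q <- tb$qvalue[!is.na(tb$qvalue)]
  if (any(q < 0 | q > 1)) return("qvalue outside [0,1]")
  TRUE
})

#' An ordered, derived gene signature with provenance
#'
#' @slot genes character vector of gene symbols (unique).
#' @slot direction named integer (+1/-1), the knockdown-contrast direction.
#' @slot support named integer, number of supporting tumor contrasts.
#' @slot provenance list describing how the signature was derived.
#' @export
setClass("GeneSignature",
  representation(genes = "character", direction = "integer",
                 support = "integer", provenance = "list"))

setValidity("GeneSignature", function(object) {
  g <- object@genes
  if (anyDuplicated(g)) return("duplicate genes in signature")
  if (length(object@direction) &&
      !identical(names(object@direction), g)) {
    return("direction names must match genes")
  }
  if (length(object@support) && !identical(names(object@support), g)) {
    return("support names must match genes")
  }
  TRUE
})

#' Construct a GeneSignature
#'
#' @param genes character vector of gene symbols.
#' @param direction optional named (+1/-1) vector, recycled names from genes.
#' @param support optional named integer vector of support counts.
#' @param provenance list of derivation metadata.
#' @return A \linkS4class{GeneSignature}.
#' @export
GeneSignature <- function(genes, direction = NULL, support = NULL,
                          provenance = list()) {
  genes <- as.character(genes)
  if (is.null(direction)) direction <- integer(0) else {
    direction <- setNames(as.integer(direction), genes)
  }
  if (is.null(support)) support <- integer(0) else {
    support <- setNames(as.integer(support), genes)
  }
  new("GeneSignature", genes = genes, direction = direction,
      support = support, provenance = provenance)
}

#' Frozen Wald-weighted risk-scoring model
#'
#' Per-gene univariate Cox Wald statistics and the training-cohort
#' standardization constants; immutable once fitted.
#'
#' @slot genes gene symbols retained in the model.
#' @slot weights Wald statistics Z_i (beta/SE), one per gene.
#' @slot center training means mu_i (log2 units).
#' @slot scale training standard deviations tau_i (log2 units, > 0).
#' @slot thresholdRule "median" or "zero".
#' @slot dropped genes requested but unusable (missing or zero variance).
#' @slot provenance fit metadata (training cohort size, events, ties method).
#' @export
setClass("ScoringModel",
  representation(genes = "character", weights = "numeric", center = "numeric",
                 scale = "numeric", thresholdRule = "character",
                 dropped = "characterOrNULL", provenance = "list"))

setValidity("ScoringModel", function(object) {
  n <- length(object@genes)
  if (length(object@weights) != n || length(object@center) != n ||
      length(object@scale) != n) {
    return("genes, weights, center, scale must have equal length")
  }
  if (any(!is.finite(object@scale)) || any(object@scale <= 0)) {
    return("scale (tau) must be finite and > 0")
  }
  if (!object@thresholdRule %in% c("median", "zero")) {
    return("thresholdRule must be 'median' or 'zero'")
  }
  TRUE
})

#' Per-patient risk scores and risk-group labels
#'
#' @slot score named numeric, the Wald-weighted standardized score S.
#' @slot group factor with levels "negative", "positive".
#' @slot threshold numeric cutoff actually used.
#' @slot rule "median" or "zero".
#' @slot droppedGenes model genes absent from the scored cohort.
#' @export
setClass("RiskScores",
  representation(score = "numeric", group = "factor", threshold = "numeric",
                 rule = "character", droppedGenes = "characterOrNULL"))

setValidity("RiskScores", function(object) {
  if (length(object@group) &&
      !identical(levels(object@group), c("negative", "positive"))) {
    return("group levels must be negative, positive")
  }
  if (length(object@group) && length(object@group) != length(object@score)) {
    return("score and group lengths differ")
  }
  TRUE
})

#' Random-signature resampling null result
#'
#' @slot observedZ Wald statistic of the tested signature.
#' @slot nullZ Wald statistics of the size-matched random signatures.
#' @slot pValue right-tailed add-one empirical p.
#' @slot redraws count of degenerate resamples that were redrawn.
#' @slot config echo of the resampling configuration.
#' @export
setClass("ResamplingResult",
  representation(observedZ = "numeric", nullZ = "numeric", pValue = "numeric",
                 redraws = "integer", config = "list"))

setValidity("ResamplingResult", function(object) {
  B <- length(object@nullZ)
  if (B < 1L) return("need at least one resample")
  p <- object@pValue
  if (p < 1 / (B + 1) - 1e-12 || p > 1 + 1e-12) {
    return("pValue outside [1/(B+1), 1]")
  }
  TRUE
})

# -- show methods -------------------------------------------------------------

setMethod("show", "DEResult", function(object) {
  tb <- object@table
  cat(sprintf("DEResult (%s): %d genes, %d significant\n", object@method,
              nrow(tb), sum(tb$significant, na.rm = TRUE)))
})

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature with %d genes\n", length(object@genes)))
  if (length(object@genes)) {
    cat("  ", paste(head(object@genes, 8L), collapse = ", "),
        if (length(object@genes) > 8L) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "ScoringModel", function(object) {
  cat(sprintf(
    "ScoringModel: %d genes, threshold rule '%s'%s\n", length(object@genes),
    object@thresholdRule,
    if (length(object@dropped)) sprintf(" (%d dropped)", length(object@dropped))
    else ""))
})

setMethod("show", "RiskScores", function(object) {
  cat(sprintf("RiskScores for %d patients (%s cutoff %.4g): %d positive\n",
              length(object@score), object@rule, object@threshold,
              sum(object@group == "positive")))
})

setMethod("show", "ResamplingResult", function(object) {
  cat(sprintf(
    "ResamplingResult: observed Z = %.3f vs %d null draws, right-tail p = %.4g\n",
    object@observedZ, length(object@nullZ), object@pValue))
})
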