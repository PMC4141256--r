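# Accessor generics. Slots are never reached into directly by user code.

#' @rdname SurvivalCohort-class
#' @param x a SurvivalCohort
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))
#' @rdname SurvivalCohort-class
#' @export
setGeneric("survEvent", function(x) standardGeneric("survEvent"))

#' @rdname SurvivalCohort-class
#' @export
setMethod("survTime", "SurvivalCohort", function(x)
  SummarizedExperiment::colData(x)$survTime)
#' @rdname SurvivalCohort-class
#' @export
setMethod("survEvent", "SurvivalCohort", function(x)
  SummarizedExperiment::colData(x)$survEvent)

#' Per-gene result table of a DEResult
#' @param x a DEResult
#' @return data.frame with one row per gene.
#' @export
setGeneric("deTable", function(x) standardGeneric("deTable"))
#' @rdname deTable
#' @export
setMethod("deTable", "DEResult", function(x) x@table)

#' Genes significant in a DEResult
#' @param x a DEResult
#' @return character vector of flagged genes.
#' @export
setGeneric("significantGenes", function(x) standardGeneric("significantGenes"))
#' @rdname significantGenes
#' @export
setMethod("significantGenes", "DEResult", function(x)
  x@table$gene[which(x@table$significant)])

#' @rdname GeneSignature-class
#' @param x a GeneSignature
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))
#' @rdname GeneSignature-class
#' @export
setMethod("signatureGenes", "GeneSignature", function(x) x@genes)

#' @rdname GeneSignature-class
#' @export
setGeneric("geneDirection", function(x) standardGeneric("geneDirection"))
#' @rdname GeneSignature-class
#' @export
setMethod("geneDirection", "GeneSignature", function(x) x@direction)

#' @rdname GeneSignature-class
#' @export
setGeneric("geneSupport", function(x) standardGeneric("geneSupport"))
#' @rdname GeneSignature-class
#' @export
setMethod("geneSupport", "GeneSignature", function(x) x@support)

#' @rdname GeneSignature-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname GeneSignature-class
#' @export
setMethod("provenance", "GeneSignature", function(x) x@provenance)
#' @rdname ScoringModel-class
#' @export
setMethod("provenance", "ScoringModel", function(x) x@provenance)

#' @rdname ScoringModel-class
#' @param x a ScoringModel
#' @export
setGeneric("modelGenes", function(x) standardGeneric("modelGenes"))
#' @rdname ScoringModel-class
#' @export
setMethod("modelGenes", "ScoringModel", function(x) x@genes)

#' @rdname ScoringModel-class
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))
#' @rdname ScoringModel-class
#' @export
setMethod("modelWeights", "ScoringModel", function(x)
  setNames(x@weights, x@genes))

#' @rdname ScoringModel-class
#' @export
setGeneric("modelCenter", function(x) standardGeneric("modelCenter"))
#' @rdname ScoringModel-class
#' @export
setMethod("modelCenter", "ScoringModel", function(x)
  setNames(x@center, x@genes))

#' @rdname ScoringModel-class
#' @export
setGeneric("modelScale", function(x) standardGeneric("modelScale"))
#' @rdname ScoringModel-class
#' @export
setMethod("modelScale", "ScoringModel", function(x)
  setNames(x@scale, x@genes))

#' @rdname RiskScores-class
#' @param x a RiskScores
#' @export
setGeneric("riskScore", function(x) standardGeneric("riskScore"))
#' @rdname RiskScores-class
#' @export
setMethod("riskScore", "RiskScores", function(x) x@score)

#' @rdname RiskScores-class
#' @export
setGeneric("riskGroup", function(x) standardGeneric("riskGroup"))
#' @rdname RiskScores-class
#' @export
setMethod("riskGroup", "RiskScores", function(x)
  setNames(x@group, names(x@score)))

#' @rdname RiskScores-class
#' @export
setGeneric("riskThreshold", function(x) standardGeneric("riskThreshold"))
#' @rdname RiskScores-class
#' @export
setMethod("riskThreshold", "RiskScores", function(x) x@threshold)

#' @rdname ResamplingResult-class
#' @param x a ResamplingResult
#' @export
setGeneric("observedZ", function(x) standardGeneric("observedZ"))
#' @rdname ResamplingResult-class
#' @export
setMethod("observedZ", "ResamplingResult", function(x) x@observedZ)

#' @rdname ResamplingResult-class
#' @export
setGeneric("nullZ", function(x) standardGeneric("nullZ"))
#' @rdname ResamplingResult-class
#' @export
setMethod("nullZ", "ResamplingResult", function(x) x@nullZ)

#' @rdname ResamplingResult-class
#' @export
setGeneric("resamplingP", function(x) standardGeneric("resamplingP"))
#' @rdname ResamplingResult-class
#' @export
setMethod("resamplingP", "ResamplingResult", function(x) x@pValue)
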