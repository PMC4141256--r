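# Signature derivation: intersect the two knockdown contrasts requiring a
# concordant direction, then keep genes supported by enough tumor/normal
# contrasts under an explicit concordance convention.

#' Concordant intersection of two differential-expression results
#'
#' Genes significant in both contrasts with the same direction of change;
#' the recorded direction is taken from contrast A. Disjoint gene universes
#' are intersected with a warning.
#'
#' @param deA,deB \linkS4class{DEResult} objects from \code{\link{samDE}} or
#'   \code{\link{pairedDE}}.
#' @return data.frame: gene, direction.
#' @export
intersectConcordant <- function(deA, deB) {
  ta <- deTable(deA); tb <- deTable(deB)
  shared <- intersect(ta$gene, tb$gene)
  if (length(shared) < length(ta$gene) || length(shared) < length(tb$gene)) {
    warning("gene universes differ; intersecting on ", length(shared),
            " shared genes")
  }
  ta <- ta[match(shared, ta$gene), ]
  tb <- tb[match(shared, tb$gene), ]
  keep <- ta$significant & tb$significant & ta$direction == tb$direction &
    ta$direction != 0
  data.frame(gene = shared[keep], direction = ta$direction[keep],
             row.names = NULL)
}

#' Cross-cancer support filter
#'
#' For each candidate gene (with its knockdown direction), counts the tumor
#' contrasts where the gene is significant AND its tumor direction
#' satisfies the declared concordance convention relative to the knockdown
#' direction. Genes with support >= \code{minSupport} form the signature.
#' A significant-but-discordant contrast contributes zero support, never
#' negative.
#'
#' @param kdSet data.frame with columns gene, direction (the knockdown
#'   contrast consensus from \code{\link{intersectConcordant}}).
#' @param tumorDEs list of \linkS4class{DEResult} (one per cancer type).
#' @param minSupport required number of supporting contrasts (default 3).
#' @param tumorConcordance "same" (tumor change matches the knockdown
#'   change; default) or "opposite". The convention is an explicit,
#'   mandatory choice: results are never convention-silent.
#' @return a \linkS4class{GeneSignature} ordered by decreasing support then
#'   symbol.
#' @export
crossCancerFilter <- function(kdSet, tumorDEs,
                              minSupport = 3,
                              tumorConcordance = c("same", "opposite")) {
  tumorConcordance <- match.arg(tumorConcordance)
  if (!length(tumorDEs)) stop("need at least one tumor contrast")
  if (minSupport < 1 || minSupport > length(tumorDEs)) {
    stop("minSupport must be between 1 and the number of tumor contrasts")
  }
  if (nrow(kdSet) == 0L) {
    return(GeneSignature(character(0),
                         provenance = list(minSupport = minSupport,
                                           tumorConcordance = tumorConcordance)))
  }
  sgn <- if (tumorConcordance == "same") 1 else -1
  support <- integer(nrow(kdSet))
  for (de in tumorDEs) {
    tb <- deTable(de)
    i <- match(kdSet$gene, tb$gene)
    ok <- !is.na(i) & tb$significant[i] &
      tb$direction[i] == sgn * kdSet$direction
    support <- support + as.integer(ok & !is.na(ok))
  }
  keep <- support >= minSupport
  ord <- order(-support[keep], kdSet$gene[keep])
  genes <- kdSet$gene[keep][ord]
  GeneSignature(
    genes,
    direction = kdSet$direction[keep][ord],
    support = support[keep][ord],
    provenance = list(minSupport = minSupport,
                      tumorConcordance = tumorConcordance,
                      nTumorContrasts = length(tumorDEs),
                      nCandidates = nrow(kdSet)))
}

#' Derive a signature end-to-end from knockdown and tumor contrasts
#'
#' Convenience wrapper: concordant intersection of the two knockdown
#' contrasts followed by the cross-cancer support filter.
#'
#' @param kdA,kdB knockdown \linkS4class{DEResult} objects.
#' @param tumorDEs list of tumor/normal \linkS4class{DEResult} objects.
#' @inheritParams crossCancerFilter
#' @return a \linkS4class{GeneSignature}.
#' @export
deriveSignature <- function(kdA, kdB, tumorDEs, minSupport = 3,
                            tumorConcordance = "same") {
  crossCancerFilter(intersectConcordant(kdA, kdB), tumorDEs,
                    minSupport = minSupport,
                    tumorConcordance = tumorConcordance)
}

#' The published 39-gene signature
#'
#' Loads the packaged 39-symbol prognostic gene list (ADK ... ZMIZ2) as a
#' \linkS4class{GeneSignature} without directions or support counts, for
#' use against user data.
#'
#' @return a \linkS4class{GeneSignature} of 39 symbols.
#' @export
n39Signature <- function() {
  path <- system.file("extdata", "n39_genes.tsv", package = "survSig",
                      mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  GeneSignature(tab$symbol,
                provenance = list(source = "published 39-gene list"))
}

#' Write / read a signature as TSV with JSON provenance
#'
#' @param sig a \linkS4class{GeneSignature}.
#' @param path output TSV path; provenance goes to \code{<path>.json}.
#' @return invisibly, the path.
#' @export
writeSignature <- function(sig, path) {
  tb <- data.frame(symbol = signatureGenes(sig),
                   direction = if (length(geneDirection(sig)))
                     as.integer(geneDirection(sig)) else NA_integer_,
                   support = if (length(geneSupport(sig)))
                     as.integer(geneSupport(sig)) else NA_integer_)
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(provenance(sig), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  prov <- if (file.exists(paste0(path, ".json"))) {
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  } else list()
  GeneSignature(tb$symbol,
                direction = if (all(is.na(tb$direction))) NULL else tb$direction,
                support = if (all(is.na(tb$support))) NULL else tb$support,
                provenance = prov)
}
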