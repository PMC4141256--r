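# Matrix-level stand-ins for probe-level filtering: detection/presence
# filtering, unique-annotation deduplication, sex-chromosome removal.
# Gene annotation (symbol, chromosome) lives in rowData; each filter appends
# a row to the filter report kept in metadata().

.exprsAssay <- function(se) {
  if (is.matrix(se)) return(se)
  SummarizedExperiment::assay(se, 1L)
}

.appendReport <- function(se, step, removed) {
  rep0 <- S4Vectors::metadata(se)$filterReport
  if (is.null(rep0)) {
    rep0 <- data.frame(step = character(0), removed = integer(0),
                       remaining = integer(0))
  }
  S4Vectors::metadata(se)$filterReport <- rbind(
    rep0, data.frame(step = step, removed = as.integer(removed),
                     remaining = nrow(se)))
  se
}

#' Filter report accumulated by the preprocessing steps
#' @param se a SummarizedExperiment that has been through one or more filters.
#' @return data.frame with columns step, removed, remaining.
#' @export
filterReport <- function(se) {
  rp <- S4Vectors::metadata(se)$filterReport
  if (is.null(rp)) data.frame(step = character(0), removed = integer(0),
                              remaining = integer(0)) else rp
}

#' Presence filter
#'
#' Retains genes detected (log2 value >= \code{detectionThreshold}) in at
#' least \code{minFraction} of the samples; the boundary is inclusive. This
#' is the matrix-level analogue of a detection-call presence filter: without
#' raw probe data, presence is defined by a detection threshold on log2
#' intensities (default: the cohort-wide 10th percentile).
#'
#' @param se SummarizedExperiment (first assay = log2 expression).
#' @param detectionThreshold log2 detection cutoff; default the 10th
#'   percentile of all values.
#' @param minFraction minimum fraction of samples detected, in (0, 1];
#'   default 2/3.
#' @return filtered SummarizedExperiment; see \code{\link{filterReport}}.
#' @export
presenceFilter <- function(se, detectionThreshold = NULL, minFraction = 2 / 3) {
  if (nrow(se) == 0L || ncol(se) == 0L) stop("empty expression matrix")
  if (!(minFraction > 0 && minFraction <= 1)) {
    stop("minFraction must be in (0, 1]")
  }
  mat <- .exprsAssay(se)
  if (is.null(detectionThreshold)) {
    detectionThreshold <- quantile(mat, 0.1, names = FALSE)
  }
  frac <- rowMeans(mat >= detectionThreshold)
  keep <- frac >= minFraction - 1e-12          # inclusive boundary
  .appendReport(se[keep, ], "presence", sum(!keep))
}

#' Deduplicate by gene symbol
#'
#' Restricts the matrix to uniquely annotated rows. In \code{"strict"} mode
#' every row whose symbol maps to more than one row is removed (only
#' uniquely annotated rows survive); in \code{"collapse"} mode the row with
#' the highest mean expression is kept per symbol. Rows without a symbol are
#' always removed.
#'
#' @param se SummarizedExperiment with a \code{symbol} column in rowData.
#' @param mode "strict" (default) or "collapse".
#' @return filtered SummarizedExperiment, row names set to symbols.
#' @export
dedupBySymbol <- function(se, mode = c("strict", "collapse")) {
  mode <- match.arg(mode)
  rd <- SummarizedExperiment::rowData(se)
  if (!"symbol" %in% colnames(rd)) {
    stop("rowData(se)$symbol is required for deduplication")
  }
  sym <- as.character(rd$symbol)
  has <- !is.na(sym) & nzchar(sym)
  keep <- has
  if (mode == "strict") {
    multi <- sym %in% sym[has][duplicated(sym[has])]
    keep <- has & !multi
  } else {
    mat <- .exprsAssay(se)
    rm_ <- rowMeans(mat)
    keep <- rep(FALSE, nrow(se))
    for (s in unique(sym[has])) {
      idx <- which(has & sym == s)
      keep[idx[which.max(rm_[idx])]] <- TRUE
    }
  }
  out <- se[keep, ]
  rownames(out) <- as.character(SummarizedExperiment::rowData(out)$symbol)
  .appendReport(out, paste0("dedup_", mode), sum(!keep))
}

.normalizeChrom <- function(chr) {
  chr <- sub("^chr", "", as.character(chr), ignore.case = TRUE)
  chr[chr == "23"] <- "X"
  chr[chr == "24"] <- "Y"
  toupper(chr)
}

#' Remove genes on the sex chromosomes
#'
#' Drops every gene annotated to chromosome X or Y (confounded by patient
#' sex). Chromosome dialects "chrX", "X" and "23"/"24" are recognized; a
#' missing chromosome annotation is an error, never a silent pass-through.
#'
#' @param se SummarizedExperiment with a \code{chromosome} rowData column.
#' @return filtered SummarizedExperiment.
#' @export
dropSexChromosomes <- function(se) {
  rd <- SummarizedExperiment::rowData(se)
  if (!"chromosome" %in% colnames(rd)) {
    stop("rowData(se)$chromosome is required to remove sex-chromosome genes")
  }
  chr <- .normalizeChrom(rd$chromosome)
  keep <- !(chr %in% c("X", "Y"))
  .appendReport(se[keep, ], "sex_chromosomes", sum(!keep))
}

#' Run the standard filter chain
#'
#' Applies presence filtering, symbol deduplication and sex-chromosome
#' removal in that documented order; each step is skipped when its required
#' annotation is absent only if \code{strictAnnotation = FALSE}.
#'
#' @param se SummarizedExperiment.
#' @param detectionThreshold,minFraction see \code{\link{presenceFilter}}.
#' @param dedupMode see \code{\link{dedupBySymbol}}.
#' @param strictAnnotation error (default) or skip when symbol/chromosome
#'   annotation is missing.
#' @return filtered SummarizedExperiment with a three-row filter report.
#' @export
preprocessMatrix <- function(se, detectionThreshold = NULL,
                             minFraction = 2 / 3,
                             dedupMode = "strict",
                             strictAnnotation = TRUE) {
  se <- presenceFilter(se, detectionThreshold, minFraction)
  rd <- SummarizedExperiment::rowData(se)
  if ("symbol" %in% colnames(rd)) {
    se <- dedupBySymbol(se, dedupMode)
  } else if (strictAnnotation) {
    stop("no symbol annotation; set strictAnnotation = FALSE to skip dedup")
  }
  rd <- SummarizedExperiment::rowData(se)
  if ("chromosome" %in% colnames(rd)) {
    se <- dropSexChromosomes(se)
  } else if (strictAnnotation) {
    stop("no chromosome annotation; set strictAnnotation = FALSE to skip")
  }
  se
}
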