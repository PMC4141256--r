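# Tab-delimited readers/writers for expression matrices, gene annotation
# and phenotype (survival) tables, with line-level validation errors.

#' Read a log2 expression matrix from TSV
#'
#' Expects gene IDs in column 1 and sample IDs in the header. Duplicate
#' sample or gene IDs, ragged rows and non-numeric cells are rejected with
#' the offending line (and sample/gene) named.
#'
#' @param path TSV file.
#' @param annotation optional path to a 3-column TSV (gene, symbol,
#'   chromosome) joined into rowData.
#' @return SummarizedExperiment with assay \code{exprs}.
#' @export
readExpression <- function(path, annotation = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression file needs a header and >=1 gene")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ID(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  nf <- lengths(fields[-1L])
  bad <- which(nf != length(header))
  if (length(bad)) {
    stop("ragged row(s) at line(s): ", paste(bad + 1L, collapse = ", "))
  }
  genes <- vapply(fields[-1L], `[[`, "", 1L)
  if (anyDuplicated(genes)) {
    stop("duplicate gene ID(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  vals <- lapply(seq_along(fields[-1L]), function(i) {
    v <- suppressWarnings(as.numeric(fields[-1L][[i]][-1L]))
    if (any(is.na(v))) {
      stop("non-numeric cell(s) at line ", i + 1L, " (gene ", genes[i], ")")
    }
    v
  })
  mat <- do.call(rbind, vals)
  dimnames(mat) <- list(genes, samples)
  rd <- NULL
  if (!is.null(annotation)) {
    ann <- readAnnotation(annotation)
    i <- match(genes, ann$gene)
    rd <- S4Vectors::DataFrame(symbol = ann$symbol[i],
                               chromosome = ann$chromosome[i],
                               row.names = genes)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    rowData = if (is.null(rd)) NULL else rd)
}

#' @rdname readExpression
#' @param se SummarizedExperiment or matrix to write.
#' @export
writeExpression <- function(se, path) {
  mat <- .exprsAssay(se)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 3-column gene annotation TSV (gene, symbol, chromosome)
#' @param path TSV file with header.
#' @return data.frame with columns gene, symbol, chromosome.
#' @export
readAnnotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "symbol", "chromosome")
  if (!all(need %in% colnames(ann))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  ann
}

# Map "+"/"-" style binary codings to 1/0; leave other columns alone.
.typeCovariate <- function(x) {
  xs <- trimws(as.character(x))
  if (all(xs %in% c("+", "-"))) return(as.integer(xs == "+"))
  num <- suppressWarnings(as.numeric(xs))
  if (!any(is.na(num))) return(num)
  factor(xs)
}

#' Read a phenotype/survival table from TSV
#'
#' Expects columns \code{sample}, \code{time} (months, > 0) and
#' \code{event} (0/1), plus any covariates. Covariates coded "+"/"-" are
#' mapped to 1/0 ("+" = 1); fully numeric columns become numeric, others
#' factors. Validation failures report row numbers.
#'
#' @param path TSV file.
#' @param se optional expression SummarizedExperiment; samples absent from
#'   it are an error, and the returned cohort is aligned to it.
#' @return a data.frame (or, with \code{se}, a
#'   \linkS4class{SurvivalCohort}).
#' @export
readPhenotype <- function(path, se = NULL) {
  ph <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% colnames(ph))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(ph$time) | ph$time <= 0)
  if (length(bad)) {
    stop("non-positive or missing time at row(s): ",
         paste(bad, collapse = ", "))
  }
  bad <- which(!ph$event %in% c(0, 1))
  if (length(bad)) {
    stop("event outside {0,1} at row(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(ph$sample)) stop("duplicate sample IDs in phenotype")
  covCols <- setdiff(colnames(ph), need)
  for (cc in covCols) ph[[cc]] <- .typeCovariate(ph[[cc]])
  if (is.null(se)) return(ph)
  mat <- .exprsAssay(se)
  missing <- setdiff(ph$sample, colnames(mat))
  if (length(missing)) {
    stop("phenotype sample(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  }
  mat <- mat[, ph$sample, drop = FALSE]
  SurvivalCohort(mat, time = ph$time, event = ph$event,
                 covariates = ph[covCols])
}

#' Write a phenotype table for a SurvivalCohort
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param path output TSV.
#' @return invisibly the path.
#' @export
writePhenotype <- function(cohort, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  df <- data.frame(sample = colnames(cohort), time = cd$survTime,
                   event = cd$survEvent,
                   cd[setdiff(colnames(cd), c("survTime", "survEvent"))],
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a differential-expression result as TSV
#' @param de a \linkS4class{DEResult}.
#' @param path output TSV.
#' @return invisibly the path.
#' @export
writeDEResult <- function(de, path) {
  write.table(deTable(de), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
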