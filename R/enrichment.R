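# Gene-set over-representation by the one-sided Fisher exact test
# (hypergeometric upper tail) against a user-supplied background universe.

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member symbols,
#' tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("GMT line needs name, description, >=1 gene")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field (recycled).
#' @return invisibly the path.
#' @export
writeGMT <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Fisher's exact over-representation test
#'
#' For each gene set, builds the 2x2 table of query membership vs set
#' membership within the background universe and computes the one-sided
#' (over-representation) Fisher exact p, i.e. the hypergeometric upper
#' tail at the observed overlap; p-values are BH-adjusted across sets.
#' Query genes and set members outside the universe are dropped (with a
#' warning for the query).
#'
#' @param query character vector of genes of interest.
#' @param sets named list of gene sets (e.g. from \code{\link{readGMT}}).
#' @param universe background gene universe (e.g. all genes surviving
#'   preprocessing).
#' @return data.frame: set, setSize, overlap, expected, oddsRatio, p,
#'   adjP; ordered as given.
#' @export
fisherEnrichment <- function(query, sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  query <- unique(as.character(query))
  if (!length(query)) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    if (!length(query)) stop("no query genes inside the universe")
  }
  N <- length(universe); n <- length(query)
  res <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    # one-sided Fisher exact p == hypergeometric upper tail P(X >= k)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- n - k; c_ <- K - k; d <- N - K - n + k
    or <- if (b == 0 || c_ == 0) Inf else (a * d) / (b * c_)
    data.frame(set = nm, setSize = K, overlap = k,
               expected = n * K / N, oddsRatio = or, p = p)
  })
  out <- do.call(rbind, res)
  out$adjP <- bhAdjust(out$p)
  rownames(out) <- NULL
  out
}
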