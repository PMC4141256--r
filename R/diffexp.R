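# Differential expression: SAM-style moderated d statistic with
# permutation-based q-values for two-group contrasts, and the classical
# paired t-test with Benjamini-Hochberg adjustment for tumor/normal designs.

.groupMeansSE <- function(mat, idx) {
  n1 <- length(idx[[1L]]); n2 <- length(idx[[2L]])
  m1 <- rowMeans(mat[, idx[[1L]], drop = FALSE])
  m2 <- rowMeans(mat[, idx[[2L]], drop = FALSE])
  ss1 <- rowSums((mat[, idx[[1L]], drop = FALSE] - m1)^2)
  ss2 <- rowSums((mat[, idx[[2L]], drop = FALSE] - m2)^2)
  # Tusher pooled standard error of the mean difference
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(m1 = m1, m2 = m2, s = s)
}

#' SAM moderated difference statistic
#'
#' Computes d_i = (mean2 - mean1) / (s_i + s0), where s_i is the pooled
#' standard error of the group-mean difference and s0 a fudge factor that
#' keeps small-variance genes from dominating. The second group of
#' \code{groups} is the treatment (numerator is group2 minus group1), so
#' the statistic is antisymmetric under label swap.
#'
#' @param se SummarizedExperiment or log2 matrix.
#' @param labels two-group assignment, one per column.
#' @param s0 fudge factor (log2 units, >= 0).
#' @param groups optional character(2): reference, treatment. Default is
#'   order of first appearance in \code{labels}.
#' @return named numeric vector of d values.
#' @export
samStatistic <- function(se, labels, s0 = 0, groups = NULL) {
  .assertScalarNum(s0, "s0", nonneg = TRUE)
  mat <- .exprsAssay(se)
  idx <- .orientGroups(labels, groups, min_per_group = 2L)
  gm <- .groupMeansSE(mat, idx)
  denom <- gm$s + s0
  denom[denom == 0] <- sqrt(.Machine$double.eps)   # s0 floor, never /0
  (gm$m2 - gm$m1) / denom
}

.orientGroups <- function(labels, groups, min_per_group = 1L) {
  idx <- .splitGroups(labels, min_per_group)
  if (!is.null(groups)) {
    if (!setequal(groups, names(idx))) {
      stop("groups must name the two levels of labels")
    }
    idx <- idx[groups]
  }
  idx
}

#' Select the SAM fudge factor s0
#'
#' Tusher-style selection: candidate s0 values are percentiles of the s_i
#' distribution; for each candidate, genes are binned into windows of s_i
#' and the coefficient of variation of mad(d) across windows is computed.
#' The percentile minimizing that coefficient of variation wins.
#' Deterministic given the input; with fewer than 10 genes the median of
#' s_i is returned.
#'
#' @inheritParams samStatistic
#' @param alphas percentile grid searched (default 0, 0.05, ..., 1).
#' @param nBins number of s_i windows (capped by the gene count).
#' @return scalar s0.
#' @export
selectS0 <- function(se, labels, groups = NULL,
                     alphas = seq(0, 1, by = 0.05), nBins = 100L) {
  mat <- .exprsAssay(se)
  idx <- .orientGroups(labels, groups, min_per_group = 2L)
  gm <- .groupMeansSE(mat, idx)
  s <- gm$s
  if (length(s) < 10L) return(median(s))
  cand <- quantile(s, alphas, names = FALSE)
  bins <- cut(rank(s, ties.method = "first"),
              breaks = min(nBins, max(2L, floor(length(s) / 5))),
              labels = FALSE)
  cv <- vapply(cand, function(s0) {
    denom <- s + s0
    denom[denom == 0] <- sqrt(.Machine$double.eps)
    d <- (gm$m2 - gm$m1) / denom
    mads <- tapply(d, bins, mad)
    if (mean(mads) == 0) return(Inf)
    sd(mads) / mean(mads)
  }, numeric(1))
  cand[which.min(cv)]
}

.permLabels <- function(labels, nPermutations, seed) {
  n <- length(labels)
  lev <- unique(labels)
  n1 <- sum(labels == lev[1L])
  nDistinct <- choose(n, n1)
  if (nDistinct <= nPermutations) {
    warning(sprintf(
      "only %d distinct label assignments; enumerating all of them",
      nDistinct))
    combos <- combn(n, n1)
    lapply(seq_len(ncol(combos)), function(j) {
      lab <- rep(lev[2L], n)
      lab[combos[, j]] <- lev[1L]
      lab
    })
  } else {
    withSeed(substreamSeed(seed, "sam_perm"),
             replicate(nPermutations, sample(labels), simplify = FALSE))
  }
}

#' Per-gene linear fold change and direction
#'
#' FC = 2^(mean2 - mean1) on log2 data; the symmetric fold change
#' max(FC, 1/FC) is used against thresholds so down-regulation is treated
#' symmetrically.
#'
#' @inheritParams samStatistic
#' @return data.frame: gene, log2FC, foldChange (linear), symmetricFC,
#'   direction (+1/-1/0).
#' @export
foldChange <- function(se, labels, groups = NULL) {
  mat <- .exprsAssay(se)
  idx <- .orientGroups(labels, groups)
  m1 <- rowMeans(mat[, idx[[1L]], drop = FALSE])
  m2 <- rowMeans(mat[, idx[[2L]], drop = FALSE])
  l2 <- m2 - m1
  fc <- 2^l2
  data.frame(gene = rownames(mat), log2FC = l2, foldChange = fc,
             symmetricFC = pmax(fc, 1 / fc), direction = sign(l2),
             row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around \code{p.adjust(method = "BH")}; rejects
#' missing or out-of-range p-values and preserves input order.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1] with no missing values")
  }
  p.adjust(p, method = "BH")
}

#' Significance call from FDR and fold-change gates
#'
#' A gene is deemed differentially expressed when its q-value (or adjusted
#' p) is below \code{fdrThreshold} and its symmetric fold change exceeds
#' \code{fcThreshold}.
#'
#' @param qvalue per-gene q or adjusted p.
#' @param symmetricFC per-gene max(FC, 1/FC).
#' @param fdrThreshold FDR gate (default 0.05).
#' @param fcThreshold linear fold-change gate (default 1.1; set to 1 to
#'   disable).
#' @return logical vector.
#' @export
callDE <- function(qvalue, symmetricFC, fdrThreshold = 0.05,
                   fcThreshold = 1.1) {
  if (length(qvalue) != length(symmetricFC)) {
    stop("qvalue and symmetricFC computed on different gene universes")
  }
  if (fcThreshold < 1) stop("fcThreshold must be >= 1")
  (qvalue < fdrThreshold) & (symmetricFC > fcThreshold)
}

#' SAM differential expression with permutation q-values
#'
#' Computes the moderated d statistic, then a label-permutation null. For
#' each gene, the q-value is pi0 times the median permutation count of
#' null |d| at or above that gene's |d|, divided by the observed count,
#' monotonized so q never increases with |d|; pi0 is estimated from the
#' fraction of observed d falling between the central (25-75\%) quantiles
#' of the null. Significance combines q < \code{fdrThreshold} with the
#' symmetric fold-change gate.
#'
#' @inheritParams samStatistic
#' @param nPermutations requested balanced label permutations (all distinct
#'   assignments are enumerated, with a warning, when fewer exist).
#' @param fdrThreshold,fcThreshold significance gates (defaults 0.05, 1.1).
#' @param seed RNG seed for permutation sampling.
#' @return a \linkS4class{DEResult}.
#' @export
samDE <- function(se, labels, s0 = "auto", nPermutations = 1000,
                  fdrThreshold = 0.05, fcThreshold = 1.1, groups = NULL,
                  seed = 1) {
  mat <- .exprsAssay(se)
  if (identical(s0, "auto")) s0 <- selectS0(mat, labels, groups)
  d <- samStatistic(mat, labels, s0 = s0, groups = groups)
  perms <- .permLabels(labels, nPermutations, seed)
  absd <- abs(d)
  m <- length(d)
  sorted_counts <- function(v, thr) {
    v <- sort(v)
    length(v) - findInterval(thr, v, left.open = TRUE)  # count v >= thr
  }
  nullCounts <- matrix(0L, m, length(perms))
  nullQ <- matrix(NA_real_, 2, length(perms))
  for (b in seq_along(perms)) {
    db <- samStatistic(mat, perms[[b]], s0 = s0, groups = NULL)
    nullCounts[, b] <- sorted_counts(abs(db), absd)
    nullQ[, b] <- quantile(db, c(0.25, 0.75), names = FALSE)
  }
  # pi0 from the central null quantiles (averaged across permutations)
  lo <- mean(nullQ[1, ]); hi <- mean(nullQ[2, ])
  pi0 <- min(1, sum(d >= lo & d <= hi) / (0.5 * m))
  V <- apply(nullCounts, 1L, median)
  R <- sorted_counts(absd, absd)
  q <- pmin(1, pi0 * V / pmax(R, 1L))
  ord <- order(absd, decreasing = TRUE)
  q[ord] <- cummax(q[ord])                     # q non-increasing in |d|
  fc <- foldChange(mat, labels, groups)
  sig <- callDE(q, fc$symmetricFC, fdrThreshold, fcThreshold)
  tb <- data.frame(gene = rownames(mat), statistic = d, log2FC = fc$log2FC,
                   foldChange = fc$foldChange, symmetricFC = fc$symmetricFC,
                   direction = fc$direction, pvalue = NA_real_, qvalue = q,
                   significant = sig, row.names = NULL)
  new("DEResult", table = tb, method = "sam",
      params = list(s0 = s0, nPermutations = length(perms), pi0 = pi0,
                    fdrThreshold = fdrThreshold, fcThreshold = fcThreshold,
                    seed = seed))
}

#' Paired t-test per gene
#'
#' Classical paired t on per-patient tumor-minus-normal log2 differences
#' (df = n_pairs - 1, two-sided p). Zero-variance differences with a
#' non-zero mean yield an infinite t and p = 0; all-zero differences yield
#' t = 0, p = 1.
#'
#' @param se SummarizedExperiment or matrix.
#' @param pairing data.frame with columns \code{normal} and \code{tumor}
#'   holding sample IDs, one row per patient (complete pairs only).
#' @return data.frame: gene, statistic (t), meanDiff, pvalue.
#' @export
pairedT <- function(se, pairing) {
  mat <- .exprsAssay(se)
  if (!all(c("normal", "tumor") %in% colnames(pairing))) {
    stop("pairing needs 'normal' and 'tumor' columns")
  }
  ids <- c(pairing$normal, pairing$tumor)
  if (!all(ids %in% colnames(mat))) {
    stop("incomplete pairs: samples missing from the matrix: ",
         paste(setdiff(ids, colnames(mat)), collapse = ", "))
  }
  n <- nrow(pairing)
  if (n < 2L) stop("need at least 2 complete pairs")
  diffs <- mat[, pairing$tumor, drop = FALSE] -
    mat[, pairing$normal, drop = FALSE]
  md <- rowMeans(diffs)
  sdd <- sqrt(rowSums((diffs - md)^2) / (n - 1))
  tt <- ifelse(sdd > 0, md / (sdd / sqrt(n)),
               ifelse(md == 0, 0, sign(md) * Inf))
  pv <- ifelse(is.finite(tt), 2 * pt(-abs(tt), df = n - 1),
               0)
  pv[tt == 0 & sdd == 0] <- 1
  data.frame(gene = rownames(mat), statistic = tt, meanDiff = md,
             pvalue = pv, row.names = NULL)
}

#' Paired differential expression with BH adjustment
#'
#' Runs \code{\link{pairedT}}, adjusts p-values by Benjamini-Hochberg and
#' flags genes with adjusted p below \code{fdrThreshold} (no fold-change
#' gate by default, matching a paired-design significance call).
#'
#' @inheritParams pairedT
#' @param fdrThreshold adjusted-p gate (default 0.05).
#' @param fcThreshold optional symmetric fold-change gate (default 1 =
#'   disabled).
#' @return a \linkS4class{DEResult}.
#' @export
pairedDE <- function(se, pairing, fdrThreshold = 0.05, fcThreshold = 1) {
  tt <- pairedT(se, pairing)
  q <- bhAdjust(tt$pvalue)
  l2 <- tt$meanDiff
  fc <- 2^l2
  sfc <- pmax(fc, 1 / fc)
  sig <- (q < fdrThreshold) & (fcThreshold <= 1 | sfc > fcThreshold)
  tb <- data.frame(gene = tt$gene, statistic = tt$statistic, log2FC = l2,
                   foldChange = fc, symmetricFC = sfc,
                   direction = sign(l2), pvalue = tt$pvalue, qvalue = q,
                   significant = sig, row.names = NULL)
  new("DEResult", table = tb, method = "pairedT",
      params = list(fdrThreshold = fdrThreshold, fcThreshold = fcThreshold))
}
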