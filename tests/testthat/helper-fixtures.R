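# Shared fixture builders: everything is generated in code at test time.

# SummarizedExperiment from a plain matrix, with optional annotation.
makeSE <- function(mat, symbol = NULL, chromosome = NULL) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat))
  if (!is.null(symbol)) SummarizedExperiment::rowData(se)$symbol <- symbol
  if (!is.null(chromosome)) {
    SummarizedExperiment::rowData(se)$chromosome <- chromosome
  }
  se
}

matWithNames <- function(vals, nr, nc) {
  matrix(vals, nr, nc,
         dimnames = list(sprintf("g%02d", seq_len(nr)),
                         sprintf("s%02d", seq_len(nc))))
}

# Hand-built DEResult for signature-derivation tests.
makeDE <- function(genes, significant, direction,
                   qvalue = ifelse(significant, 0.01, 0.5)) {
  tb <- data.frame(gene = genes, statistic = direction * 2,
                   log2FC = direction * 1, foldChange = 2^(direction * 1),
                   symmetricFC = 2, direction = direction,
                   pvalue = qvalue, qvalue = qvalue,
                   significant = significant)
  new("DEResult", table = tb, method = "test", params = list())
}

# Small survival cohort with optional prognostic gene.
makeCohort <- function(n = 60, nGenes = 10, beta = 0, seed = 1) {
  sim <- simulateSurvivalCohort(
    nGenes = nGenes, nPatients = n,
    beta = if (beta != 0) stats::setNames(beta, "G0001") else numeric(0),
    seed = seed)
  sim$cohort
}

# Independent partial log-likelihood for a single covariate, Breslow ties
# (used only on tie-free toys, where Breslow == Efron).
partialLogLik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Independent log-rank chi-square by direct O-E/V accumulation.
bruteLogrank <- function(time, event, group) {
  group <- as.integer(as.factor(group))  # 1/2
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & group == 1L)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
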