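test_that("SAM d statistic matches hand arithmetic and the Tusher formula", {
  # 2v2 toy: (1,1 | 2,2), s0 = 0.5 -> d = (2-1)/(0+0.5) = 2
  se <- makeSE(matWithNames(c(1, 1, 2, 2), 1, 4))
  labels <- c("a", "a", "b", "b")
  expect_equal(unname(samStatistic(se, labels, s0 = 0.5)), 2)

  # equal group means: d = 0 whatever s0
  se0 <- makeSE(matWithNames(c(1, 2, 1, 2), 1, 4))
  expect_equal(unname(samStatistic(se0, labels, s0 = 0.1)), 0)

  # independent naive re-implementation of the pooled-SE formula, 3v3
  withr::with_seed(4, {
    mat <- matWithNames(rnorm(60), 10, 6)
  })
  lab <- rep(c("g1", "g2"), each = 3)
  d <- samStatistic(mat, lab, s0 = 0)
  naive <- apply(mat, 1, function(x) {
    x1 <- x[1:3]; x2 <- x[4:6]
    s <- sqrt((1 / 3 + 1 / 3) / 4 *
                (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)))
    (mean(x2) - mean(x1)) / s
  })
  expect_equal(unname(d), unname(naive), tolerance = 1e-12)

  # antisymmetric under label swap; invariant to a per-gene constant shift
  expect_equal(unname(samStatistic(mat, lab, 0.2, groups = c("g2", "g1"))),
               -unname(d2 <- samStatistic(mat, lab, 0.2)), tolerance = 1e-12)
  expect_equal(samStatistic(mat + 5, lab, 0.2), d2, tolerance = 1e-12)
})

test_that("s0 selection matches brute-force grid search", {
  withr::with_seed(9, {
    # bimodal spread: half the genes low-variance, half high-variance
    mat <- rbind(matWithNames(rnorm(200, sd = 0.1), 25, 8)[, ],
                 matrix(rnorm(200, sd = 3), 25, 8))
    rownames(mat) <- sprintf("g%02d", 1:50)
  })
  lab <- rep(c("a", "b"), each = 4)
  s0 <- selectS0(mat, lab)
  # oracle: exhaustive evaluation of the same percentile grid
  m1 <- rowMeans(mat[, 1:4]); m2 <- rowMeans(mat[, 5:8])
  s <- sqrt((1 / 4 + 1 / 4) / 6 *
              (rowSums((mat[, 1:4] - m1)^2) + rowSums((mat[, 5:8] - m2)^2)))
  bins <- cut(rank(s, ties.method = "first"),
              breaks = min(100L, max(2L, floor(length(s) / 5))),
              labels = FALSE)
  cvs <- sapply(quantile(s, seq(0, 1, 0.05)), function(cand) {
    d <- (m2 - m1) / (s + cand)
    v <- tapply(d, bins, mad)
    sd(v) / mean(v)
  })
  expect_equal(s0, unname(quantile(s, seq(0, 1, 0.05))[which.min(cvs)]))

  # degenerate: identical rows give identical s_i, so s0 equals that value
  matSame <- matWithNames(rep(c(1, 2, 1.5, 0.5, 3, 2, 1, 2.5), each = 12),
                          12, 8)
  sSame <- sqrt((1 / 4 + 1 / 4) / 6 *
                  (sum((c(1, 2, 1.5, 0.5) - 1.25)^2) +
                     sum((c(3, 2, 1, 2.5) - 2.125)^2)))
  expect_equal(selectS0(matSame, lab), sSame)

  # fewer than 10 genes: median fallback
  expect_equal(selectS0(mat[1:5, ], lab), median(s[1:5]))
})

test_that("permutation q-values behave at the extremes and recover effects", {
  # a gene exceeding every null value gets the minimum q in the result
  sim <- simulateKnockdownPair(nGenes = 120, nPerGroup = 5, deGenes = 1,
                               kdEffect = 6, noiseSd = 0.2, seed = 21)
  de <- suppressWarnings(
    samDE(sim$se, sim$labels, nPermutations = 300, seed = 3,
          groups = c("WT", "KD")))
  tb <- deTable(de)
  top <- which.max(abs(tb$statistic))
  expect_identical(tb$gene[top], "G0001")
  expect_equal(tb$qvalue[top], min(tb$qvalue))

  # q monotone non-increasing in |d|
  ord <- order(abs(tb$statistic), decreasing = TRUE)
  expect_true(all(diff(tb$qvalue[ord]) >= 0))

  # strong planted effects are all recovered at q < 0.05
  sim2 <- simulateKnockdownPair(nGenes = 400, nPerGroup = 5, deGenes = 20,
                                kdEffect = rep(c(2, -2), 10), noiseSd = 0.25,
                                seed = 22)
  de2 <- samDE(sim2$se, sim2$labels, nPermutations = 200, seed = 4,
               groups = c("WT", "KD"))
  expect_true(all(names(sim2$truth) %in% significantGenes(de2)))

  # requesting more permutations than exist enumerates all, with a warning
  simT <- simulateKnockdownPair(nGenes = 30, nPerGroup = 2, seed = 1)
  expect_warning(samDE(simT$se, simT$labels, nPermutations = 100, seed = 1),
                 "enumerating")
})

test_that("paired t matches the t distribution and its symmetries", {
  # tumor == normal: t = 0, p = 1
  mat <- matWithNames(rep(c(3, 3), each = 6), 3, 4)
  mat[, c(2, 4)] <- mat[, c(1, 3)]
  pairing <- data.frame(normal = c("s01", "s03"), tumor = c("s02", "s04"))
  tt <- pairedT(mat, pairing)
  expect_equal(tt$statistic, rep(0, 3))
  expect_equal(tt$pvalue, rep(1, 3))

  # differences (1,2,3): t = 2*sqrt(3), two-sided p at df=2 = 0.0741799
  m <- matWithNames(0, 1, 6)
  m[1, ] <- c(0, 1, 0, 2, 0, 3)
  pr <- data.frame(normal = c("s01", "s03", "s05"),
                   tumor = c("s02", "s04", "s06"))
  tt2 <- pairedT(m, pr)
  expect_equal(tt2$statistic, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(tt2$pvalue, 0.0741799, tolerance = 1e-6)

  # sign flip: t negates, p unchanged
  m2 <- m; m2[1, c(2, 4, 6)] <- -m[1, c(2, 4, 6)]
  tt3 <- pairedT(m2, pr)
  expect_equal(tt3$statistic, -tt2$statistic)
  expect_equal(tt3$pvalue, tt2$pvalue)

  # incomplete pairs are rejected
  expect_error(pairedT(m, data.frame(normal = "s01", tumor = "s99")),
               "missing")
})

test_that("BH adjustment is exact, monotone and order-preserving", {
  expect_equal(bhAdjust(0.3), 0.3)                  # m = 1
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))  # forced by step-up
  p <- c(0.01, 0.02, 0.03, 0.04)
  # oracle: direct min over k >= rank of (m/k) p_(k)
  brute <- function(p) {
    m <- length(p); o <- order(p); adj <- numeric(m)
    ps <- p[o]
    a <- vapply(seq_len(m), function(r)
      min(1, min(ps[r:m] * m / (r:m))), numeric(1))
    adj[o] <- a
    adj
  }
  expect_equal(bhAdjust(p), brute(p))
  expect_true(all(bhAdjust(p) >= p))
  expect_error(bhAdjust(c(0.5, NA)), "missing")
  expect_error(bhAdjust(c(0.5, 1.2)))
})

test_that("fold change is symmetric and feeds the significance gates", {
  m <- rbind(rep(5, 4),
             c(5, 5, 5 + log2(1.2), 5 + log2(1.2)))
  dimnames(m) <- list(c("g01", "g02"), sprintf("s%02d", 1:4))
  se <- makeSE(m)
  lab <- c("a", "a", "b", "b")
  fc <- foldChange(se, lab)
  expect_equal(fc$foldChange[1], 1)
  expect_equal(fc$foldChange[2], 1.2, tolerance = 1e-12)
  swapped <- foldChange(se, lab, groups = c("b", "a"))
  expect_equal(swapped$foldChange[2], 1 / 1.2, tolerance = 1e-12)
  expect_equal(swapped$direction[2], -fc$direction[2])
  # gate logic: FDR and FC must both pass
  expect_false(callDE(0.01, 1.05))
  expect_true(callDE(0.01, 1.2))
  expect_false(callDE(0.06, 2.0))
})
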