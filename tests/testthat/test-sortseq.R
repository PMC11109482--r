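test_that("size factors follow the median-of-ratios convention", {
  m <- matrix(rep(c(5, 8, 13, 21), each = 6), 6, 4)
  s <- computeSizeFactors(m)
  expect_equal(s, c(5, 8, 13, 21) / exp(mean(log(c(5, 8, 13, 21)))))
  # identical bins give unit factors
  expect_equal(computeSizeFactors(matrix(7, 5, 4)), rep(1, 4))
  # doubling one bin doubles its factor (up to the geometric-mean rescale)
  m2 <- cbind(m[, 1:3], 2 * m[, 1])
  s2 <- computeSizeFactors(m2)
  expect_equal(s2[4] / s2[1], 2)
  # brute-force oracle on a random table
  set.seed(42)
  r <- matrix(rnbinom(200, mu = 50, size = 5), 50, 4)
  expect_equal(computeSizeFactors(r), oracleSizeFactors(r))
  # all-zero-containing rows only: falls back to totals with a warning
  z <- rbind(c(0, 1, 2, 3), c(3, 0, 1, 2))
  expect_warning(sz <- computeSizeFactors(z), "falling back")
  expect_equal(sz, colSums(z) / exp(mean(log(colSums(z)))))
})

test_that("shift fit recovers the analytic Poisson-limit solution", {
  # stationarity of the Poisson likelihood at counts (10,20,20,40) gives
  # exp(beta0) = 20, exp(shift) = 2
  f <- fitShift(c(10, 20, 20, 40))
  expect_equal(f$shift, log(2), tolerance = 1e-7)
  expect_equal(f$beta0, log(20), tolerance = 1e-7)
  expect_true(f$converged && f$se > 0)
  # symmetry and mirror symmetry of the covariate
  expect_equal(fitShift(c(20, 20, 20, 20))$shift, 0, tolerance = 1e-9)
  expect_equal(fitShift(c(40, 20, 20, 10))$shift, -log(2), tolerance = 1e-7)
  # all-zero rows are flagged, not fitted
  f0 <- fitShift(c(0, 0, 0, 0))
  expect_false(f0$converged)
  expect_true(is.na(f0$shift))
})

test_that("fitted coefficients match the grid/golden-section oracle", {
  set.seed(7)
  for (i in 1:25) {
    cnt <- rnbinom(4, mu = exp(runif(1, 2, 5) + runif(1, -1, 1) *
                                 c(-1, 0, 0, 1)), size = 10)
    if (all(cnt == 0)) next
    alpha <- sample(c(0, 0.05, 0.2), 1)
    s <- exp(runif(4, -0.3, 0.3))
    fit <- fitShift(cnt, s, alpha = alpha)
    if (!fit$converged) next
    orc <- oracleShiftFit(cnt, s, alpha = alpha)
    expect_equal(fit$beta0, unname(orc["b0"]), tolerance = 1e-4)
    expect_equal(fit$shift, unname(orc["bs"]), tolerance = 1e-4)
  }
})

test_that("fit agrees with an independent NB GLM implementation", {
  skip_if_not_installed("DESeq2")
  sim <- tinyScreen(seed = 31L)
  cnt <- SummarizedExperiment::assay(sim$screen)
  keep <- rowSums(cnt) > 20
  cnt <- cnt[keep, ]
  sf <- computeSizeFactors(cnt)
  suppressMessages({
    cd <- S4Vectors::DataFrame(covariate = c(-1, 0, 0, 1))
    dds <- DESeq2::DESeqDataSetFromMatrix(cnt, cd, ~covariate)
    DESeq2::sizeFactors(dds) <- sf
    DESeq2::dispersions(dds) <- rep(0.05, nrow(cnt))
    dds <- DESeq2::nbinomWaldTest(dds)
    lfc <- DESeq2::results(dds)$log2FoldChange * log(2)
  })
  ours <- vapply(seq_len(nrow(cnt)), function(i)
    fitShift(cnt[i, ], sf, alpha = 0.05)$shift, numeric(1))
  expect_equal(ours, lfc, tolerance = 1e-3)
})

test_that("covariate shift and scale behave as a reparameterization", {
  cnt <- c(12, 25, 18, 44)
  base <- fitShift(cnt, covariate = c(-1, 0, 0, 1))
  shifted <- fitShift(cnt, covariate = c(-1, 0, 0, 1) + 2)
  scaled <- fitShift(cnt, covariate = 2 * c(-1, 0, 0, 1))
  expect_equal(shifted$shift, base$shift, tolerance = 1e-6)
  expect_equal(scaled$shift, base$shift / 2, tolerance = 1e-6)
  expect_equal(scaled$shift / scaled$se, base$shift / base$se,
               tolerance = 1e-6)
})

test_that("dispersion estimation shrinks toward a sensible trend", {
  set.seed(5)
  mu <- exp(runif(80, 3, 6))
  # Poisson-generated table: shrunk dispersions collapse toward zero
  pois <- t(vapply(mu, function(m) rpois(4, m), numeric(4)))
  dp <- ratioscreen::estimateDispersions(pois, rep(1, 4),
                                         X = cbind(1, c(-1, 0, 0, 1)))
  expect_gt(mean(dp$alpha < 1e-2), 0.9)
  # NB table with true alpha 0.1: trend value at the mean of means
  nb <- t(vapply(mu, function(m) rnbinom(4, mu = m, size = 10), numeric(4)))
  dn <- ratioscreen::estimateDispersions(nb, rep(1, 4),
                                         X = cbind(1, c(-1, 0, 0, 1)))
  mbar <- mean(dn$baseMean)
  trendAt <- dn$trendCoef[["a0"]] + dn$trendCoef[["a1"]] / mbar
  expect_gt(trendAt, 0.05)
  expect_lt(trendAt, 0.2)
  # constant row with a degenerate likelihood takes the trend value
  cst <- rbind(nb, rep(50, 4))
  dc <- ratioscreen::estimateDispersions(cst, rep(1, 4),
                                         X = cbind(1, c(-1, 0, 0, 1)))
  expect_equal(dc$alpha[nrow(cst)], dc$alphaTrend[nrow(cst)])
})

test_that("Wald tests and BH adjustment match hand computation", {
  fits <- data.frame(shift = -qnorm(c(0.01, 0.02, 0.03, 0.04) / 2) * 0.1,
                     se = 0.1)
  out <- testShifts(fits)
  expect_equal(out$pvalue, c(0.01, 0.02, 0.03, 0.04), tolerance = 1e-10)
  expect_equal(out$qvalue, rep(0.04, 4), tolerance = 1e-10)
  expect_equal(out$qvalue, oracleBH(out$pvalue), tolerance = 1e-12)
  # single test: q equals p
  one <- testShifts(data.frame(shift = 0.3, se = 0.1))
  expect_equal(one$qvalue, one$pvalue)
  # missing SE propagates missing p and q
  na <- testShifts(data.frame(shift = c(1, 1), se = c(0.1, NA)))
  expect_true(is.na(na$pvalue[2]) && is.na(na$qvalue[2]))
  # BH within sublibrary: families are adjusted independently
  two <- data.frame(shift = rep(0.3, 4), se = c(0.1, 0.2, 0.1, 0.2),
                    sublibrary = c("A", "A", "B", "B"))
  outg <- testShifts(two)
  for (g in c("A", "B")) {
    i <- two$sublibrary == g
    expect_equal(outg$qvalue[i], oracleBH(outg$pvalue[i]))
  }
})

test_that("null p-values are calibrated under BH", {
  set.seed(99)
  p <- runif(10000)
  q <- oracleBH(p)
  fits <- data.frame(shift = qnorm(1 - p / 2) * 0.1, se = 0.1)
  out <- testShifts(fits)
  expect_equal(out$qvalue, q, tolerance = 1e-9)
  expect_lte(mean(out$qvalue < 0.05), 0.01)
})

test_that("gene calling requires concordant significant sgRNAs", {
  mk <- function(gene, shift, q)
    data.frame(sgRNA = paste0(gene, "_", seq_along(shift)), gene = gene,
               shift = shift, qvalue = q, is_nontargeting = FALSE)
  fits <- rbind(
    mk("up2",   c(1, 1, 0.1, 0, 0),   c(0.01, 0.02, 0.5, 0.9, 0.9)),
    mk("one",   c(1, 0, 0, 0, 0),     c(0.01, 0.5, 0.6, 0.9, 0.9)),
    mk("mixed", c(1, -1, 0, 0, 0),    c(0.01, 0.02, 0.9, 0.9, 0.9)))
  ntc <- data.frame(sgRNA = paste0("NTC_", 1:2), gene = "non-targeting",
                    shift = c(2, 2), qvalue = c(0.001, 0.001),
                    is_nontargeting = TRUE)
  out <- callGenes(rbind(fits, ntc))
  expect_equal(out$hit[out$gene == "up2"], TRUE)
  expect_equal(out$direction[out$gene == "up2"], "up")
  expect_false(out$hit[out$gene == "one"])
  expect_false(out$hit[out$gene == "mixed"])   # concordance required
  expect_false("non-targeting" %in% out$gene)  # NTCs never produce calls
  # sgRNA missing from the design is an error naming the guide
  expect_error(callGenes(fits, design = data.frame(
    sgRNA = "other", gene = "g", is_nontargeting = FALSE)), "up2_1")
})

test_that("row order does not affect screen results", {
  sim <- tinyScreen(seed = 17L)
  res <- analyzeScreen(sim$screen)
  perm <- sample(nrow(sim$screen))
  resP <- analyzeScreen(sim$screen[perm, ])
  i <- match(res$sgRNA, resP$sgRNA)
  expect_equal(res$shift, resP$shift[i], tolerance = 1e-10)
  expect_equal(res$qvalue, resP$qvalue[i], tolerance = 1e-10)
})
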