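test_that("bin probabilities follow the normal-CDF construction", {
  thr <- qnorm(c(0.25, 0.5, 0.75))
  # neutral sgRNA in quantile bins occupies each bin equally
  expect_equal(binProbabilities(0, thr), rep(0.25, 4))
  # strong positive effect pushes all cells into the highest bin
  expect_equal(binProbabilities(50, thr), c(0, 0, 0, 1))
  # delta = sigma against standard-normal quartile gates: frozen values of
  # the independent Phi-difference evaluation diff(c(0, pnorm(z - 1), 1))
  expect_equal(binProbabilities(1, thr, mu0 = 0, sd = 1),
               c(0.0470171936, 0.1116380604, 0.2137422093, 0.6276025368),
               tolerance = 1e-9)
  expect_error(binProbabilities(0, c(1, 1, 2)))
})

test_that("pooled gates give equal expected occupancy and conserve cells", {
  sim <- tinyScreen(seed = 55L)
  cells <- attr(sim$truth, "cells")
  occ <- colSums(cells) / sum(cells)
  # binomial error bound on the pooled occupancy of each bin
  se <- sqrt(0.25 * 0.75 / sum(cells))
  expect_true(all(abs(occ - 0.25) < 5 * se))
  # every cell drawn for an sgRNA lands in exactly one bin
  expect_true(all(rowSums(cells) >= 1))
  # nontargeting sgRNAs carry effect 0 and hit genes nonzero sgRNA effects
  ntc <- grepl("^NTC", sim$truth$sgRNA)
  expect_true(all(sim$truth$delta[ntc] == 0))
  expect_true(all(diff(attr(sim$truth, "thresholds")) > 0))
})

test_that("empirical bin frequencies converge to Phi probabilities", {
  sim <- simulateScreen(ScreenSimConfig(nGenes = 4L, sgrnasPerGene = 2L,
                                        nNontargeting = 2L, hitFraction = 0.5,
                                        coverage = 1e5, seed = 77L))
  cells <- attr(sim$truth, "cells")
  thr <- attr(sim$truth, "thresholds")
  for (i in seq_len(nrow(cells))) {
    p <- binProbabilities(sim$truth$delta[i], thr)
    expect_true(max(abs(cells[i, ] / sum(cells[i, ]) - p)) < 0.01)
  }
})

test_that("screen generation is reproducible and validates its config", {
  a <- tinyScreen(seed = 9L)
  b <- tinyScreen(seed = 9L)
  expect_identical(SummarizedExperiment::assay(a$screen),
                   SummarizedExperiment::assay(b$screen))
  expect_identical(a$truth, b$truth)
  d <- tinyScreen(seed = 10L)
  expect_false(identical(SummarizedExperiment::assay(a$screen),
                         SummarizedExperiment::assay(d$screen)))
  expect_error(ScreenSimConfig(nBins = 1L), "nBins")
  expect_error(ScreenSimConfig(hitFraction = 1.5), "hitFraction")
  expect_error(ScreenSimConfig(cellSD = 0), "cellSD")
  expect_error(ScreenSimConfig(coverage = 1e6, nGenes = 1e5), "overflow")
})

test_that("flow simulation matches its noise-free limits and QC contract", {
  cfg <- FlowSimConfig(nEvents = 200L, noiseCV = 0, expressionSD = 0.3,
                       brightnessGreen = 2, brightnessRed = 1, seed = 3L)
  ev <- simulateFlow(cfg)
  expect_equal(ev$long_only$green / ev$long_only$red, rep(2, 200))
  expect_equal(ev$short_only$green, rep(0, 200))
  expect_true(attr(ev$long_only, "nFloored") >= 0)
  # Monte-Carlo: median green/red of a 50/50 mixture
  cfg2 <- FlowSimConfig(nEvents = 10000L, fractionLong = 0.5,
                        brightnessGreen = 2, brightnessRed = 1, seed = 21L)
  mix <- simulateFlow(cfg2)$mixed
  expect_equal(median(mix$green / mix$red), 0.5 * 2, tolerance = 0.02)
  expect_error(FlowSimConfig(fractionLong = 2), "fractionLong")
})

test_that("ribo simulation encodes the knockdown occupancy structure", {
  cfg <- RiboSimConfig(nGenes = 20L, nTop = 5L, seed = 13L)
  sim <- simulateRibo(cfg)
  expect_length(sim$profiles, 6L)
  expect_equal(dim(sim$rnaCounts), c(26L, 6L))
  # annotation geometry: uORF inside the 5' UTR, 7 nt spacer, CDS in frame
  rep1 <- sim$annotation[GenomicRanges::seqnames(sim$annotation) == "reporter"]
  get <- function(f) rep1[rep1$feature == f]
  expect_equal(GenomicRanges::start(get("cds")) -
                 GenomicRanges::end(get("uorf")) - 1L, 7L)
  expect_equal(GenomicRanges::width(get("cds")) %% 3L, 0L)
  expect_true(GenomicRanges::start(get("uorf")) >=
                GenomicRanges::start(get("utr5")) &&
              GenomicRanges::end(get("uorf")) <=
                GenomicRanges::end(get("utr5")))
  # all-neutral multipliers: knockdown and control totals agree closely
  cfg1 <- RiboSimConfig(nGenes = 20L, nTop = 5L, uorfMult = 1, startMult = 1,
                        utr3Mult = 1, topTeMult = 1, seed = 13L)
  sim1 <- simulateRibo(cfg1)
  tot <- vapply(sim1$profiles, function(p) sum(p$count), numeric(1))
  ctrl <- mean(tot[grepl("control", names(tot))])
  kd <- mean(tot[grepl("knockdown", names(tot))])
  expect_equal(kd / ctrl, 1, tolerance = 0.05)
  expect_error(RiboSimConfig(cdsLen = 0L))
  expect_error(RiboSimConfig(cdsLen = 301L), "divisible")
})
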