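# A tiny hand-built transcript: 30 nt 5' UTR containing a 9 nt uORF ending
# 7 nt before the CDS, 66 nt CDS (22 codons), 20 nt 3' UTR.
tinyRibo <- function(...) RiboSimConfig(utr5Len = 30L, uorfLen = 9L,
                                        spacerLen = 7L, cdsLen = 66L,
                                        utr3Len = 20L, ...)

tinyAnn <- function() transcriptAnnotation(tinyRibo(), "tx1")

test_that("region density is footprint count over feature length", {
  ann <- tinyAnn()
  # 10 footprints inside the CDS (66 nt): density 10/66
  prof <- data.frame(transcript = "tx1",
                     position = 30L + seq(0, 45, by = 5), count = 1L)
  d <- regionDensity(prof, ann)
  expect_equal(d$density[d$feature == "cds"], 10 / 66)
  expect_equal(d$density[d$feature == "utr3"], 0)  # empty feature
  # brute-force recomputation on a random profile
  set.seed(23)
  rnd <- data.frame(transcript = "tx1", position = sample(0:115, 40, TRUE),
                    count = rpois(40, 3) + 1L)
  rnd <- stats::aggregate(count ~ transcript + position, rnd, sum)
  d2 <- regionDensity(rnd, ann)
  for (f in unique(d2$feature)) {
    a <- ann[ann$feature == f]
    lo <- GenomicRanges::start(a) - 1L; hi <- GenomicRanges::end(a) - 1L
    brute <- sum(rnd$count[rnd$position >= lo & rnd$position <= hi])
    expect_equal(d2$count[d2$feature == f], brute)
  }
  # positions outside the transcript are an error
  bad <- data.frame(transcript = "tx1", position = 500L, count = 1L)
  expect_error(regionDensity(bad, ann), "bounds")
  expect_error(regionDensity(prof, ann, features = "nope"), "unknown")
})

test_that("stop-codon metagene is depth-normalized with median summary", {
  ann <- tinyAnn()
  txLen <- 116L
  # uniform counts: flat profile at 1/transcript_length
  unif <- data.frame(transcript = "tx1", position = 0:(txLen - 1L),
                     count = 4L)
  mg <- metageneStop(list(lib1 = unif), ann, window = 10)
  expect_equal(unique(mg$value), 1 / txLen)
  expect_equal(mg$offset, -10:10)
  # offset 0 is the first stop-codon nucleotide (CDS end - 3 in 0-based)
  spike <- data.frame(transcript = "tx1", position = 93L, count = 5L)
  mgs <- metageneStop(list(lib1 = spike), ann, window = 3)
  expect_equal(mgs$value[mgs$offset == 0], 1)
  # doubling every count leaves the normalized profile unchanged
  dbl <- unif; dbl$count <- 2L * dbl$count
  mg2 <- metageneStop(list(lib1 = dbl), ann, window = 10)
  expect_equal(mg2$value, mg$value)
  # median across three replicate libraries, against brute force
  libs <- list(a = unif, b = dbl, c = spike)
  sheet <- data.frame(library = c("a", "b", "c"), condition = "ctrl")
  mg3 <- metageneStop(libs, ann, window = 5, sheet = sheet)
  norm <- lapply(libs, function(p) {
    dense <- numeric(txLen)
    dense[p$position + 1L] <- p$count
    dense / sum(p$count)
  })
  stop0 <- 93L
  for (off in -5:5) {
    vals <- sapply(norm, function(v) v[stop0 + off + 1L])
    expect_equal(mg3$value[mg3$offset == off], median(vals))
  }
  # zero-total library is excluded with a warning
  empty <- data.frame(transcript = "tx1", position = 0L, count = 0L)
  expect_warning(metageneStop(list(a = unif, z = empty), ann, window = 3),
                 "zero total")
})

test_that("CDS normalization divides by interior CDS occupancy", {
  cfg <- RiboSimConfig(utr5Len = 30L, uorfLen = 9L, spacerLen = 7L,
                       cdsLen = 90L, utr3Len = 20L)
  ann <- transcriptAnnotation(cfg, "tx1")
  txLen <- 140L
  # uniform c everywhere normalizes to 1
  unif <- data.frame(transcript = "tx1", position = 0:(txLen - 1L),
                     count = 6L)
  np <- cdsNormalizedProfile(unif, ann, "tx1")
  expect_equal(np$value, rep(1, txLen))
  # 5' UTR at 2c reads as 2 (codon exclusion: first 15, last 5 codons)
  prof <- unif
  prof$count[prof$position < 30L] <- 12L
  np2 <- cdsNormalizedProfile(prof, ann, "tx1")
  expect_equal(np2$value[np2$position < 30L], rep(2, 30L))
  expect_equal(np2$value[np2$position >= 30L], rep(1, txLen - 30L))
  # the divisor excludes the first 15 codons: inflating them changes nothing
  infl <- unif
  infl$count[infl$position >= 30L & infl$position < 30L + 45L] <- 60L
  np3 <- cdsNormalizedProfile(infl, ann, "tx1")
  expect_equal(np3$value[np3$position >= 100L], rep(1, 40L))
  # zero interior CDS occupancy is an error naming the transcript
  zero <- data.frame(transcript = "tx1", position = 0L, count = 3L)
  expect_error(cdsNormalizedProfile(zero, ann, "tx1"), "tx1")
})

test_that("TE interaction test behaves on noise-free constructions", {
  genes <- paste0("g", 1:25)
  sheet <- data.frame(
    library = c(paste0("ribo_c_", 1:2), paste0("ribo_k_", 1:2),
                paste0("rna_c_", 1:2), paste0("rna_k_", 1:2)),
    condition = rep(rep(c("control", "knockdown"), each = 2), 2),
    assay = rep(c("ribo", "rna"), each = 4),
    replicate = rep(1:2, 4))
  base <- matrix(rep(c(100L, 200L, 400L, 150L, 120L), 5), 25, 1)
  mk <- function(mult) matrix(rep(base * mult, 2), 25, 2)
  # footprints and RNA change by the same factor: log2dTE = 0
  fp <- cbind(mk(1), mk(3)); rna <- cbind(mk(1), mk(3))
  dimnames(fp) <- list(genes, sheet$library[1:4])
  dimnames(rna) <- list(genes, sheet$library[5:8])
  te0 <- teTest(fp, rna, sheet)
  expect_true(all(abs(te0$log2dTE) < 1e-6))
  # footprints double, RNA unchanged: log2dTE = 1 (unit size factors so
  # the global doubling is not absorbed by depth normalization)
  fp2 <- cbind(mk(1), mk(2)); rna2 <- cbind(mk(1), mk(1))
  dimnames(fp2) <- dimnames(fp); dimnames(rna2) <- dimnames(rna)
  usf <- setNames(rep(1, 8), sheet$library)
  te1 <- teTest(fp2, rna2, sheet, sizeFactors = usf)
  expect_equal(te1$log2dTE, rep(1, 25), tolerance = 1e-6)
  # count filter: a gene below the mean threshold is not tested
  fp3 <- fp2; fp3[1, ] <- c(1L, 1L, 1L, 1L)
  te2 <- teTest(fp3, rna2, sheet)
  expect_false(te2$tested[1])
  expect_true(is.na(te2$log2dTE[1]))
  expect_error(teTest(fp2[, 1:3], rna2, sheet), "replicates")
})

test_that("TE interaction coefficient matches DESeq2 on shared inputs", {
  skip_if_not_installed("DESeq2")
  set.seed(61)
  sim <- simulateRibo(RiboSimConfig(nGenes = 40L, nTop = 10L, seed = 62L))
  fp <- quantifyCdsCounts(sim$profiles, sim$annotation)
  te <- teTest(fp, sim$rnaCounts, sim$librarySheet)
  cnt <- cbind(fp, sim$rnaCounts)
  sh <- sim$librarySheet[match(colnames(cnt), sim$librarySheet$library), ]
  cd <- S4Vectors::DataFrame(
    condition = factor(sh$condition),
    assay = factor(sh$assay, levels = c("rna", "ribo")))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(cnt, cd, ~ condition * assay)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, name = "conditionknockdown.assayribo")
  })
  ok <- te$tested & !is.na(te$log2dTE)
  # same model, independently estimated dispersions: close agreement
  expect_gt(cor(te$log2dTE[ok], res$log2FoldChange[ok]), 0.98)
  expect_lt(median(abs(te$log2dTE[ok] - res$log2FoldChange[ok])), 0.1)
})

test_that("gene-set ECDF reports the median TE shift", {
  te <- data.frame(gene = paste0("g", 1:40),
                   log2dTE = c(rep(1, 10), rep(0, 30)),
                   tested = TRUE)
  e <- genesetEcdf(te, paste0("g", 1:10))
  expect_equal(e$medianShift, 1)
  expect_equal(e$nSet, 10)
  # a set drawn from the same distribution shifts by ~0
  eNull <- genesetEcdf(te[11:40, ], paste0("g", 11:20))
  expect_equal(eNull$medianShift, 0)
  expect_error(genesetEcdf(te, "absent"), "intersect")
})

test_that("feature sums tile the transcript total", {
  sim <- simulateRibo(RiboSimConfig(nGenes = 5L, nTop = 2L, seed = 71L))
  p <- sim$profiles[[1]]
  d <- regionDensity(p, sim$annotation,
                     features = c("utr5", "cds", "utr3"),
                     transcripts = "reporter")
  expect_equal(sum(d$count),
               sum(p$count[p$transcript == "reporter"]))
})
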