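# Ribosome footprint quantification: region densities, stop-codon metagene
# profiles, CDS-normalized occupancy, gene-level CDS counts, and the
# translation-efficiency interaction test.

# Dense per-position count vector for one transcript from a sparse profile.
denseFromRows <- function(rows, transcript, txLen) {
  out <- numeric(txLen)
  if (!is.null(rows) && nrow(rows)) {
    if (any(rows$position < 0L | rows$position >= txLen))
      stop("positions outside transcript bounds for ", transcript)
    out[rows$position + 1L] <- rows$count
  }
  out
}

denseCounts <- function(profile, transcript, txLen) {
  denseFromRows(profile[profile$transcript == transcript, , drop = FALSE],
                transcript, txLen)
}

annotationFor <- function(annotation, transcript) {
  a <- annotation[as.character(GenomicRanges::seqnames(annotation)) ==
                    transcript]
  if (length(a) == 0L) stop("transcript not in annotation: ", transcript)
  a
}

transcriptLength <- function(annotation, transcript) {
  sl <- GenomeInfoDb::seqlengths(annotation)[transcript]
  if (is.na(sl))
    sl <- max(GenomicRanges::end(annotationFor(annotation, transcript)))
  as.integer(sl)
}

#' Footprint density per annotated region
#'
#' Sums footprint 5'-end counts over each feature interval and divides by
#' the feature length: density = footprint count / length (footprints per
#' nt). An empty feature has density 0.
#'
#' @param profile `data.frame(transcript, position, count)`, 0-based
#'   footprint 5'-end positions (zero-count positions may be omitted).
#' @param annotation feature `GRanges` (see [transcriptAnnotation()]).
#' @param features feature names to quantify (default: all in the
#'   annotation).
#' @param transcripts transcripts to quantify (default: all with counts).
#' @return `data.frame`: `transcript`, `feature`, `count`, `length`,
#'   `density`.
#' @export
regionDensity <- function(profile, annotation, features = NULL,
                          transcripts = NULL) {
  if (is.null(transcripts)) transcripts <- unique(profile$transcript)
  allFeat <- unique(annotation$feature)
  if (is.null(features)) features <- allFeat
  if (!all(features %in% allFeat))
    stop("unknown features: ",
         paste(setdiff(features, allFeat), collapse = ", "))
  out <- list()
  for (tx in transcripts) {
    a <- annotationFor(annotation, tx)
    txLen <- transcriptLength(annotation, tx)
    if (any(GenomicRanges::end(a) > txLen | GenomicRanges::start(a) < 1L))
      stop("feature outside transcript bounds for ", tx)
    cnt <- denseCounts(profile, tx, txLen)
    for (f in features) {
      ai <- a[a$feature == f]
      if (length(ai) == 0L) next
      s <- GenomicRanges::start(ai)[1L]; e <- GenomicRanges::end(ai)[1L]
      n <- sum(cnt[s:e])
      out[[length(out) + 1L]] <- data.frame(
        transcript = tx, feature = f, count = n, length = e - s + 1L,
        density = n / (e - s + 1L))
    }
  }
  do.call(rbind, out)
}

#' Region densities across replicate libraries with medians
#'
#' Applies [regionDensity()] per library and adds the across-replicate
#' median density per condition when a library sheet is supplied.
#'
#' @param profiles named list of profiles.
#' @param annotation feature `GRanges`.
#' @param sheet optional `data.frame(library, condition)`.
#' @inheritParams regionDensity
#' @return list with `perLibrary` (long `data.frame` with a `library`
#'   column) and, with a sheet, `medians` (`condition`, `transcript`,
#'   `feature`, `density`).
#' @export
regionDensityAcross <- function(profiles, annotation, sheet = NULL,
                                features = NULL, transcripts = NULL) {
  per <- do.call(rbind, lapply(names(profiles), function(lib) {
    d <- regionDensity(profiles[[lib]], annotation, features, transcripts)
    d$library <- lib
    d
  }))
  res <- list(perLibrary = per)
  if (!is.null(sheet)) {
    per$condition <- sheet$condition[match(per$library, sheet$library)]
    agg <- stats::aggregate(density ~ condition + transcript + feature,
                            data = per, FUN = median)
    res$medians <- agg
  }
  res
}

#' Stop-codon metagene profile
#'
#' Re-indexes footprint 5'-end counts to the offset from the first
#' nucleotide of the stop codon (offset 0 = first stop-codon nt, i.e. the
#' position immediately after the last sense codon), normalizes each
#' library by its total footprint count, and takes the per-position median
#' across the replicate libraries of each condition. Transcript positions
#' falling outside the transcript are skipped for that transcript.
#'
#' @param profiles named list of profiles (footprint libraries).
#' @param annotation feature `GRanges` with a `cds` feature per transcript.
#' @param window nt on each side of the stop codon; either a single number
#'   or `c(upstream, downstream)`.
#' @param sheet optional `data.frame(library, condition)`; without it all
#'   libraries form one condition `"all"`.
#' @return `data.frame`: `condition`, `offset`, `value` (median across
#'   replicates of the depth-normalized per-position count summed over
#'   transcripts).
#' @export
metageneStop <- function(profiles, annotation, window = 50,
                         sheet = NULL) {
  if (length(window) == 1L) window <- c(window, window)
  offsets <- seq(-window[1L], window[2L])
  txs <- unique(as.character(GenomicRanges::seqnames(annotation)))
  stopPos0 <- vapply(txs, function(tx) {
    a <- annotationFor(annotation, tx)
    cds <- a[a$feature == "cds"]
    if (length(cds) == 0L) stop("transcript without CDS: ", tx)
    GenomicRanges::end(cds)[1L] - 3L  # 0-based first nt of the stop codon
  }, numeric(1))
  txLens <- vapply(txs, transcriptLength, integer(1),
                   annotation = annotation)
  perLib <- lapply(names(profiles), function(lib) {
    p <- profiles[[lib]]
    total <- sum(p$count)
    if (total == 0) {
      warning("library with zero total footprints excluded: ", lib)
      return(NULL)
    }
    acc <- numeric(length(offsets))
    byTx <- split(p, p$transcript)
    for (ti in seq_along(txs)) {
      cnt <- denseFromRows(byTx[[txs[ti]]], txs[ti], txLens[ti])
      pos0 <- stopPos0[ti] + offsets
      ok <- pos0 >= 0L & pos0 < txLens[ti]
      acc[ok] <- acc[ok] + cnt[pos0[ok] + 1L]
    }
    acc / total
  })
  names(perLib) <- names(profiles)
  perLib <- perLib[!vapply(perLib, is.null, logical(1))]
  if (is.null(sheet))
    sheet <- data.frame(library = names(perLib), condition = "all")
  out <- list()
  for (cond in unique(sheet$condition)) {
    libs <- intersect(sheet$library[sheet$condition == cond],
                      names(perLib))
    if (length(libs) == 0L) next
    m <- do.call(rbind, perLib[libs])
    out[[cond]] <- data.frame(condition = cond, offset = offsets,
                              value = apply(m, 2L, median))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' CDS-normalized occupancy profile
#'
#' Divides every position's footprint count by the mean per-position count
#' over the CDS excluding the first 15 and last 5 codons (initiating and
#' terminating ribosomes accumulate there), so a uniformly translated CDS
#' sits at 1 and UTR features read as fold of CDS occupancy.
#'
#' @param profile one library's profile.
#' @param annotation feature `GRanges`.
#' @param transcript transcript id.
#' @param excludeCodons codons excluded at the CDS start and end
#'   (default `c(15, 5)`).
#' @return `data.frame`: `position` (0-based), `value`.
#' @export
cdsNormalizedProfile <- function(profile, annotation, transcript,
                                 excludeCodons = c(15L, 5L)) {
  a <- annotationFor(annotation, transcript)
  cds <- a[a$feature == "cds"]
  if (length(cds) == 0L) stop("transcript without CDS: ", transcript)
  txLen <- transcriptLength(annotation, transcript)
  cnt <- denseCounts(profile, transcript, txLen)
  s <- GenomicRanges::start(cds)[1L] + 3L * excludeCodons[1L]
  e <- GenomicRanges::end(cds)[1L] - 3L * excludeCodons[2L]
  if (e < s) stop("CDS too short for the codon exclusion: ", transcript)
  divisor <- mean(cnt[s:e])
  if (divisor == 0)
    stop("zero CDS occupancy after codon exclusion: ", transcript)
  data.frame(position = seq_len(txLen) - 1L, value = cnt / divisor)
}

#' Gene-level CDS footprint counts
#'
#' Sums footprint 5'-end counts over the CDS of each transcript, excluding
#' the first 15 and last 5 codons, per library — the footprint counterpart
#' of an RNA-seq gene count table, used by [teTest()].
#'
#' @param profiles named list of profiles.
#' @param annotation feature `GRanges`.
#' @param excludeCodons codons excluded at the CDS start and end.
#' @return integer matrix, genes x libraries.
#' @export
quantifyCdsCounts <- function(profiles, annotation,
                              excludeCodons = c(15L, 5L)) {
  txs <- unique(as.character(GenomicRanges::seqnames(annotation)))
  m <- matrix(0L, length(txs), length(profiles),
              dimnames = list(txs, names(profiles)))
  cdsAll <- annotation[annotation$feature == "cds"]
  cdsTx <- as.character(GenomicRanges::seqnames(cdsAll))
  for (lib in names(profiles)) {
    p <- profiles[[lib]]
    byTx <- split(p, p$transcript)
    for (tx in txs) {
      i <- match(tx, cdsTx)
      if (is.na(i)) stop("transcript without CDS: ", tx)
      s <- GenomicRanges::start(cdsAll)[i] + 3L * excludeCodons[1L]
      e <- GenomicRanges::end(cdsAll)[i] - 3L * excludeCodons[2L]
      cnt <- denseFromRows(byTx[[tx]], tx, transcriptLength(annotation, tx))
      m[tx, lib] <- sum(cnt[s:e])
    }
  }
  m
}

#' Translation-efficiency interaction test
#'
#' Fits, per gene, a negative binomial GLM with log link over the combined
#' footprint and RNA libraries with coefficients for condition, assay, and
#' their interaction, using per-library median-of-ratios size factors
#' computed on the combined count matrix and trend-shrunk dispersions. The
#' condition-by-assay interaction is the log fold change of TE (footprint
#' abundance relative to mRNA abundance) between conditions; it is reported
#' as `log2dTE` with a Wald p-value and BH q-value over tested genes.
#' Genes with mean count below `minMean` in either assay are excluded
#' (reported with `tested = FALSE`).
#'
#' @param fpCounts footprint gene count matrix (genes x footprint
#'   libraries), e.g. from [quantifyCdsCounts()].
#' @param rnaCounts RNA gene count matrix (same genes x RNA libraries).
#' @param sheet `data.frame(library, condition, assay, replicate)`
#'   covering all columns of both matrices; `condition` must have two
#'   levels and `assay` the values `ribo` and `rna`.
#' @param minMean count filter threshold (default 10).
#' @param sizeFactors optional named per-library size factors; computed by
#'   median-of-ratios on the combined matrix when missing.
#' @return `data.frame`: `gene`, `baseMean`, `log2dTE`, `se` (log2
#'   scale), `pvalue`, `qvalue`, `tested`.
#' @export
teTest <- function(fpCounts, rnaCounts, sheet, minMean = 10,
                   sizeFactors = NULL) {
  stopifnot(identical(rownames(fpCounts), rownames(rnaCounts)))
  counts <- cbind(fpCounts, rnaCounts)
  sheet <- sheet[match(colnames(counts), sheet$library), , drop = FALSE]
  if (anyNA(sheet$library)) stop("library sheet does not cover all columns")
  stopifnot(length(unique(sheet$condition)) == 2L,
            all(c("ribo", "rna") %in% sheet$assay))
  if (any(table(sheet$condition, sheet$assay) < 2L))
    stop("at least 2 replicates per condition x assay are required")
  condition <- factor(sheet$condition)
  assay <- factor(sheet$assay, levels = c("rna", "ribo"))
  X <- stats::model.matrix(~ condition * assay)
  sf <- if (is.null(sizeFactors)) computeSizeFactors(counts)
        else sizeFactors[colnames(counts)]
  meanFp <- rowMeans(sweep(fpCounts, 2L, sf[colnames(fpCounts)], "/"))
  meanRna <- rowMeans(sweep(rnaCounts, 2L, sf[colnames(rnaCounts)], "/"))
  tested <- meanFp >= minMean & meanRna >= minMean
  res <- data.frame(gene = rownames(counts),
                    baseMean = rowMeans(sweep(counts, 2L, sf, "/")),
                    log2dTE = NA_real_, se = NA_real_,
                    pvalue = NA_real_, qvalue = NA_real_,
                    tested = tested, stringsAsFactors = FALSE)
  sub <- counts[tested, , drop = FALSE]
  if (nrow(sub) == 0L) return(res)
  disp <- estimateDispersions(sub, sf, X = X)
  iCoef <- ncol(X)  # interaction column of ~ condition * assay
  for (k in seq_len(nrow(sub))) {
    fit <- fitNbGlm(sub[k, ], X, offset = log(sf), alpha = disp$alpha[k])
    i <- which(tested)[k]
    if (fit$converged && is.finite(fit$se[iCoef])) {
      res$log2dTE[i] <- fit$beta[iCoef] / log(2)
      res$se[i] <- fit$se[iCoef] / log(2)
      res$pvalue[i] <- 2 * pnorm(abs(fit$beta[iCoef] / fit$se[iCoef]),
                                 lower.tail = FALSE)
    }
  }
  ok <- !is.na(res$pvalue)
  res$qvalue[ok] <- p.adjust(res$pvalue[ok], method = "BH")
  res
}

#' Gene-set ECDF of TE changes
#'
#' Empirical cumulative distributions of `log2dTE` for a gene set (e.g.
#' TOP mRNAs) and the complement of tested genes, with the difference of
#' medians.
#'
#' @param teResults output of [teTest()].
#' @param geneSet character vector of gene ids.
#' @return list: `set` and `background` (each `list(x, ecdf)` with sorted
#'   values and an `ecdf` function), `medianShift` (set median minus
#'   background median), `nSet`, `nBackground`.
#' @export
genesetEcdf <- function(teResults, geneSet) {
  ok <- teResults$tested & !is.na(teResults$log2dTE)
  inSet <- ok & teResults$gene %in% geneSet
  inBg <- ok & !(teResults$gene %in% geneSet)
  if (!any(inSet)) stop("gene set does not intersect the tested genes")
  xs <- sort(teResults$log2dTE[inSet])
  xb <- sort(teResults$log2dTE[inBg])
  list(set = list(x = xs, ecdf = ecdf(xs)),
       background = list(x = xb, ecdf = ecdf(xb)),
       medianShift = median(xs) - median(xb),
       nSet = length(xs), nBackground = length(xb))
}
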