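# Sort-seq enrichment model: per-sgRNA isoform shift scores from counts in
# ordered fluorescence bins, modeled as NB(mean = s_b * exp(b0 + shift * x_b)).

#' Median-of-ratios size factors across bins
#'
#' Each sorted bin is a separate sequencing library; size factors equalize
#' depth and composition using the median-of-ratios convention: for rows
#' with all-positive counts, each bin's ratio to the row geometric mean is
#' taken, and the per-bin median of those ratios is the size factor. Factors
#' are rescaled to geometric mean 1. When no all-positive row exists, the
#' total-count ratio is used instead (with a warning).
#'
#' @param counts integer matrix (rows = sgRNAs, columns = bins) or a
#'   [BinCountScreen-class].
#' @return positive numeric vector, one size factor per bin, geometric
#'   mean 1.
#' @examples
#' m <- rbind(c(10, 10, 10, 20), c(30, 30, 30, 60))
#' computeSizeFactors(m)  # ~ (1,1,1,2) / 2^(1/4)
#' @export
computeSizeFactors <- function(counts) {
  if (methods::is(counts, "BinCountScreen"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no sgRNA with positive counts in every bin; ",
            "falling back to total-count size factors")
    s <- colSums(counts)
    s <- s / exp(mean(log(s)))
    return(s)
  }
  geo <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  s <- apply(counts[pos, , drop = FALSE] / geo, 2L, median)
  s / exp(mean(log(s)))
}

#' Fit the isoform shift model for one sgRNA
#'
#' Counts in the ordered bins are modeled as
#' \deqn{count_b \sim NB(\mu_b = s_b e^{\beta_0 + \beta_{shift} x_b},\ \alpha)}
#' with the default covariate \eqn{x = (-1, 0, 0, 1)}: counts in the two
#' extreme bins have a constant multiplicative change relative to the middle
#' bins, and \eqn{\beta_{shift}} is the isoform shift score (log fold change
#' per unit covariate; positive = shift toward the high green/red bins, i.e.
#' toward the long isoform).
#'
#' @param counts counts for one sgRNA, one per bin.
#' @param sizeFactors per-bin size factors.
#' @param covariate per-bin numeric covariate.
#' @param alpha NB dispersion for this sgRNA (0 = Poisson).
#' @return list with `beta0`, `shift`, `se` (of the shift), `loglik`,
#'   `converged`.
#' @examples
#' fitShift(c(10, 20, 20, 40))$shift  # = log(2)
#' @export
fitShift <- function(counts, sizeFactors = rep(1, length(counts)),
                     covariate = defaultBinCovariate(length(counts)),
                     alpha = 0) {
  stopifnot(length(counts) == length(sizeFactors),
            length(counts) == length(covariate))
  if (all(counts == 0))
    return(list(beta0 = NA_real_, shift = NA_real_, se = NA_real_,
                loglik = NA_real_, converged = FALSE))
  X <- cbind(intercept = 1, shift = covariate)
  fit <- fitNbGlm(counts, X, offset = log(sizeFactors), alpha = alpha)
  list(beta0 = unname(fit$beta[1L]), shift = unname(fit$beta[2L]),
       se = unname(fit$se[2L]), loglik = fit$loglik,
       converged = fit$converged)
}

#' Wald tests and BH correction for shift fits
#'
#' Two-sided Wald p-values `2 * (1 - pnorm(|shift| / se))` with
#' Benjamini-Hochberg adjustment. When a `sublibrary` column is present, the
#' BH family is each sublibrary (targeting plus nontargeting sgRNAs fitted
#' within it), matching per-sublibrary screening.
#'
#' @param fits `data.frame` with at least `shift` and `se` columns, and
#'   optionally `sublibrary`.
#' @return the input with `pvalue` and `qvalue` columns added; rows with
#'   missing `se` get missing p and q.
#' @export
testShifts <- function(fits) {
  stopifnot(all(c("shift", "se") %in% names(fits)))
  p <- 2 * pnorm(abs(fits$shift) / fits$se, lower.tail = FALSE)
  p[!is.finite(fits$se) | fits$se <= 0] <- NA_real_
  q <- rep(NA_real_, length(p))
  grp <- if ("sublibrary" %in% names(fits)) as.character(fits$sublibrary)
         else rep("all", length(p))
  for (g in unique(grp)) {
    i <- which(grp == g & !is.na(p))
    q[i] <- p.adjust(p[i], method = "BH")
  }
  fits$pvalue <- p
  fits$qvalue <- q
  fits
}

#' Analyze a sort-seq screen end to end
#'
#' Computes per-bin size factors, estimates per-sgRNA NB dispersions
#' (trend-shrunk by default, or a single pooled moment estimate), fits the
#' shift model for every sgRNA, and attaches Wald p-values and BH q-values.
#' Rows with total count below `minTotal` are fitted and reported but
#' flagged `low_coverage` and excluded from dispersion trend fitting;
#' all-zero rows are flagged and excluded from testing.
#'
#' @param screen a [BinCountScreen-class].
#' @param dispersion `"shrunk"` (per-sgRNA Cox-Reid ML with parametric
#'   trend and log-normal shrinkage) or `"pooled"` (single moment-based
#'   dispersion).
#' @param minTotal low-coverage flag threshold on the row total.
#' @param sizeFactors optional per-bin size factors (computed if missing).
#' @return `data.frame` with one row per sgRNA: `sgRNA`, `gene`,
#'   `beta0`, `shift`, `se`, `dispersion`, `pvalue`, `qvalue`, `flags`
#'   (and `sublibrary` when present in the design).
#' @export
analyzeScreen <- function(screen, dispersion = c("shrunk", "pooled"),
                          minTotal = 10L, sizeFactors = NULL) {
  stopifnot(methods::is(screen, "BinCountScreen"))
  dispersion <- match.arg(dispersion)
  cnt <- SummarizedExperiment::assay(screen, "counts")
  x <- binCovariate(screen)
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(cnt)
  totals <- rowSums(cnt)
  lowCov <- totals < minTotal
  X <- cbind(1, x)
  if (dispersion == "shrunk") {
    disp <- estimateDispersions(cnt, sizeFactors, X = X,
                                trendRows = !lowCov)
    alpha <- disp$alpha
  } else {
    alpha <- rep(pooledDispersion(cnt, sizeFactors), nrow(cnt))
  }
  fits <- lapply(seq_len(nrow(cnt)), function(i)
    fitShift(cnt[i, ], sizeFactors, x, alpha[i]))
  res <- data.frame(
    sgRNA = rownames(cnt),
    gene = SummarizedExperiment::rowData(screen)$gene,
    beta0 = vapply(fits, `[[`, numeric(1), "beta0"),
    shift = vapply(fits, `[[`, numeric(1), "shift"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    dispersion = alpha,
    stringsAsFactors = FALSE)
  rd <- SummarizedExperiment::rowData(screen)
  if ("sublibrary" %in% colnames(rd)) res$sublibrary <- rd$sublibrary
  res$is_nontargeting <- rd$is_nontargeting
  conv <- vapply(fits, `[[`, logical(1), "converged")
  res$flags <- ifelse(totals == 0, "all_zero",
               ifelse(!conv, "not_converged",
               ifelse(lowCov, "low_coverage", "")))
  res$se[!conv] <- NA_real_
  res <- testShifts(res)
  attr(res, "sizeFactors") <- sizeFactors
  res
}

#' Gene-level hit calls from sgRNA shift fits
#'
#' A gene is called a hit in a direction when at least `minSgrnas` of its
#' sgRNAs are significant (`qvalue < fdrThreshold`) with a shift of that
#' sign; significant sgRNAs of opposite signs do not combine (concordance
#' required). Nontargeting sgRNAs never produce gene calls.
#'
#' @param fits result of [analyzeScreen()] / [testShifts()] with `gene`,
#'   `shift`, `qvalue` columns.
#' @param design library design `data.frame` (`sgRNA`, `gene`,
#'   `is_nontargeting`); defaults to the columns carried in `fits`.
#' @param fdrThreshold FDR cutoff on the sgRNA q-value (default 0.05).
#' @param minSgrnas minimum concordant significant sgRNAs (default 2).
#' @return `data.frame` per gene: `gene`, `n_sgrnas`, `n_sig_up`,
#'   `n_sig_down`, `direction` (`"up"` toward long isoform / high
#'   green-red, `"down"`, or `"none"`), `hit`.
#' @export
callGenes <- function(fits, design = NULL, fdrThreshold = 0.05,
                      minSgrnas = 2L) {
  if (is.null(design)) {
    stopifnot(all(c("gene", "is_nontargeting") %in% names(fits)))
    design <- data.frame(sgRNA = fits$sgRNA, gene = fits$gene,
                         is_nontargeting = fits$is_nontargeting)
  }
  idx <- match(fits$sgRNA, design$sgRNA)
  if (anyNA(idx))
    stop("sgRNA absent from design: ",
         paste(utils::head(fits$sgRNA[is.na(idx)], 5), collapse = ", "))
  fits$gene <- design$gene[idx]
  fits$is_nontargeting <- design$is_nontargeting[idx]
  tf <- fits[!fits$is_nontargeting, , drop = FALSE]
  sig <- !is.na(tf$qvalue) & tf$qvalue < fdrThreshold
  genes <- unique(tf$gene)
  up <- tapply(sig & tf$shift > 0, tf$gene, sum)[genes]
  dn <- tapply(sig & tf$shift < 0, tf$gene, sum)[genes]
  n <- tapply(rep(1L, nrow(tf)), tf$gene, sum)[genes]
  hitUp <- up >= minSgrnas
  hitDn <- dn >= minSgrnas
  direction <- ifelse(hitUp & !hitDn, "up",
               ifelse(hitDn & !hitUp, "down",
               ifelse(hitUp & hitDn, "both", "none")))
  data.frame(gene = genes, n_sgrnas = as.integer(n),
             n_sig_up = as.integer(up), n_sig_down = as.integer(dn),
             direction = direction,
             hit = direction %in% c("up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}
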