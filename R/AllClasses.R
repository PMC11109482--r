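#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom stats median quantile rnorm rpois rnbinom rlnorm rmultinom
#'   runif pnorm qnorm p.adjust t.test uniroot optimize dnbinom dpois
#'   setNames complete.cases ks.test ecdf cor
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Screen container: sgRNA-by-bin counts with an ordered bin covariate
#'
#' `BinCountScreen` extends
#' \link[SummarizedExperiment]{RangedSummarizedExperiment}'s parent class
#' \linkS4class{SummarizedExperiment} with a `"counts"` assay holding one row
#' per sgRNA and one column per sorted fluorescence bin. Columns are ordered
#' by increasing green/red ratio (default labels `FR`, `NR`, `NG`, `FG`) and
#' carry the numeric covariate used by the enrichment GLM in
#' `colData()$covariate` (default `c(-1, 0, 0, 1)`). `rowData()` holds the
#' library design: `gene` and `is_nontargeting`, plus optional `sublibrary`.
#'
#' No additional slots; all state lives in the
#' \linkS4class{SummarizedExperiment} representation.
#'
#' @seealso [BinCountScreen()] for the constructor, [binCovariate()],
#'   [computeSizeFactors()], [analyzeScreen()]
#' @export
setClass("BinCountScreen", contains = "SummarizedExperiment")

setValidity("BinCountScreen", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be nonnegative")
    if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integers")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"covariate" %in% colnames(cd))
    msg <- c(msg, "colData must contain a numeric 'covariate' per bin")
  else {
    x <- cd$covariate
    if (!is.numeric(x) || anyNA(x))
      msg <- c(msg, "'covariate' must be numeric and non-missing")
    else if (length(unique(x)) < 2L)
      msg <- c(msg, "'covariate' must not be constant across bins")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "sgRNA ids (rownames) must be present and unique")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("gene", "is_nontargeting") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'gene' and 'is_nontargeting'")
  if (length(msg)) msg else TRUE
})

#' Construct a BinCountScreen
#'
#' @param counts integer matrix, one row per sgRNA (rownames = sgRNA ids),
#'   one column per bin in increasing green/red order.
#' @param design `data.frame` with columns `sgRNA`, `gene`,
#'   `is_nontargeting`, optionally `sublibrary`; matched to `counts` rows by
#'   `sgRNA`.
#' @param covariate numeric covariate per bin, default `c(-1, 0, 0, 1)` for
#'   the four-bin design (extremes carry a constant multiplicative change
#'   relative to the two middle bins).
#' @param binLabels bin (column) labels, default `FR`, `NR`, `NG`, `FG`.
#' @return A [BinCountScreen-class] object.
#' @examples
#' cnt <- matrix(rpois(8, 50), 2, 4,
#'               dimnames = list(c("sg1", "sg2"), NULL))
#' des <- data.frame(sgRNA = c("sg1", "sg2"), gene = c("A", "A"),
#'                   is_nontargeting = FALSE)
#' scr <- BinCountScreen(cnt, des)
#' binCovariate(scr)
#' @export
BinCountScreen <- function(counts,
                           design,
                           covariate = defaultBinCovariate(ncol(counts)),
                           binLabels = defaultBinLabels(ncol(counts))) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (length(covariate) != ncol(counts))
    stop("covariate length (", length(covariate),
         ") must equal the number of bin columns (", ncol(counts), ")")
  if (is.null(rownames(counts)) && !missing(design))
    rownames(counts) <- design$sgRNA
  stopifnot(is.data.frame(design), all(c("sgRNA", "gene") %in% names(design)))
  if (!"is_nontargeting" %in% names(design))
    design$is_nontargeting <- FALSE
  idx <- match(rownames(counts), design$sgRNA)
  if (anyNA(idx))
    stop("sgRNAs missing from design: ",
         paste(utils::head(rownames(counts)[is.na(idx)], 5), collapse = ", "))
  design <- design[idx, , drop = FALSE]
  colnames(counts) <- binLabels
  rd <- S4Vectors::DataFrame(design[setdiff(names(design), "sgRNA")],
                             row.names = design$sgRNA)
  cd <- S4Vectors::DataFrame(bin = binLabels, covariate = as.numeric(covariate),
                             row.names = binLabels)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
  methods::new("BinCountScreen", se)
}

#' Default bin labels and covariate
#'
#' Four bins are labeled `FR`, `NR`, `NG`, `FG` in increasing green/red
#' order; other bin numbers get `bin1..binK`. The default covariate for four
#' bins is `c(-1, 0, 0, 1)`: the far bins are modeled as a constant
#' multiplicative change relative to the middle bins. For other bin numbers
#' a centered, unit-spaced score is used.
#'
#' @param nBins number of bins.
#' @return character / numeric vector of length `nBins`.
#' @export
defaultBinLabels <- function(nBins) {
  if (nBins == 4L) c("FR", "NR", "NG", "FG") else paste0("bin", seq_len(nBins))
}

#' @rdname defaultBinLabels
#' @export
defaultBinCovariate <- function(nBins) {
  if (nBins == 4L) c(-1, 0, 0, 1)
  else seq_len(nBins) - (nBins + 1) / 2
}

#' Three-color reporter calibration model
#'
#' Holds the green-per-red brightness factor of the pure long isoform
#' (`kappa`), the residual green/red leak measured on the short-only
#' calibrator line, the per-channel background offsets that were subtracted,
#' and event QC counts.
#'
#' @slot kappa green-per-red brightness ratio of the long-only calibrator
#'   (dimensionless, > 0).
#' @slot leak median green/red of the short-only calibrator (>= 0); must be
#'   small relative to `kappa` for the two-state model to hold.
#' @slot background numeric, background offsets for the green and red
#'   channels (fluorescence units).
#' @slot nEvents integer, events retained in each calibrator after QC.
#' @export
setClass("CalibrationModel",
         representation(kappa = "numeric", leak = "numeric",
                        background = "numeric", nEvents = "integer"),
         prototype(background = c(green = 0, red = 0), nEvents = c(0L, 0L)))

setValidity("CalibrationModel", function(object) {
  msg <- character()
  if (length(object@kappa) != 1L || !is.finite(object@kappa) ||
      object@kappa <= 0)
    msg <- c(msg, "kappa must be a single positive number")
  if (length(object@leak) != 1L || object@leak < 0)
    msg <- c(msg, "leak must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CalibrationModel", function(object) {
  cat("CalibrationModel\n")
  cat(sprintf("  kappa (green per red, long-only): %.4g\n", object@kappa))
  cat(sprintf("  leak  (green/red, short-only):    %.4g (%.2f%% of kappa)\n",
              object@leak, 100 * object@leak / object@kappa))
  cat(sprintf("  events after QC: long-only %d, short-only %d\n",
              object@nEvents[1L], object@nEvents[2L]))
  invisible(NULL)
})

setMethod("show", "BinCountScreen", function(object) {
  cat(sprintf("BinCountScreen: %d sgRNAs x %d bins (%s)\n",
              nrow(object), ncol(object),
              paste(colnames(object), collapse = ", ")))
  cat("  covariate:", paste(binCovariate(object), collapse = ", "), "\n")
  rd <- SummarizedExperiment::rowData(object)
  cat(sprintf("  %d genes, %d nontargeting sgRNAs\n",
              length(unique(rd$gene[!rd$is_nontargeting])),
              sum(rd$is_nontargeting)))
  invisible(NULL)
})
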