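#' Bin covariate of a screen
#'
#' Accessors for the per-bin numeric covariate and the library design stored
#' in a [BinCountScreen-class].
#'
#' @param object a [BinCountScreen-class].
#' @return `binCovariate`: numeric vector, one value per bin.
#'   `libraryDesign`: `data.frame` with `sgRNA`, `gene`, `is_nontargeting`
#'   (and `sublibrary` if present).
#' @export
setGeneric("binCovariate", function(object) standardGeneric("binCovariate"))

#' @rdname binCovariate
#' @export
setMethod("binCovariate", "BinCountScreen", function(object)
  SummarizedExperiment::colData(object)$covariate)

#' @rdname binCovariate
#' @export
setGeneric("libraryDesign", function(object) standardGeneric("libraryDesign"))

#' @rdname binCovariate
#' @export
setMethod("libraryDesign", "BinCountScreen", function(object) {
  rd <- as.data.frame(SummarizedExperiment::rowData(object))
  data.frame(sgRNA = rownames(object), rd, row.names = NULL,
             check.names = FALSE)
})

#' @rdname binCovariate
#' @param value replacement covariate (length = number of bins).
#' @export
setGeneric("binCovariate<-",
           function(object, value) standardGeneric("binCovariate<-"))

#' @rdname binCovariate
#' @export
setMethod("binCovariate<-", "BinCountScreen", function(object, value) {
  stopifnot(length(value) == ncol(object))
  SummarizedExperiment::colData(object)$covariate <- as.numeric(value)
  methods::validObject(object)
  object
})

#' Calibration model accessors
#'
#' @param object a [CalibrationModel-class].
#' @return `calKappa`: the green-per-red brightness factor of the pure long
#'   isoform; `calLeak`: the short-only line's residual green/red ratio.
#' @export
setGeneric("calKappa", function(object) standardGeneric("calKappa"))

#' @rdname calKappa
#' @export
setMethod("calKappa", "CalibrationModel", function(object) object@kappa)

#' @rdname calKappa
#' @export
setGeneric("calLeak", function(object) standardGeneric("calLeak"))

#' @rdname calKappa
#' @export
setMethod("calLeak", "CalibrationModel", function(object) object@leak)
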