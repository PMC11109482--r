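# Shared readers/writers (TSV tables, BED-like annotation, JSON results),
# seeded substream management, and the end-to-end pipeline driver.

#' Derive a named RNG substream seed from a global seed
#'
#' Each pipeline stage draws from its own deterministic substream so that
#' changing one stage's randomness does not perturb the others. The
#' substream seed is a 31-bit hash of the global seed and the stream name.
#'
#' @param seed global integer seed.
#' @param stream stream name (e.g. `"screen"`, `"flow"`, `"ribo"`).
#' @return integer seed below 2^31.
#' @export
substreamSeed <- function(seed, stream) {
  h <- as.integer(seed) %% 2147483647L
  for (ch in utf8ToInt(stream))
    h <- as.integer((as.numeric(h) * 31 + ch) %% 2147483647)
  h
}

fmtNum <- function(x) {
  if (is.numeric(x) && !is.integer(x))
    format(x, digits = 15, scientific = FALSE, trim = TRUE)
  else x
}

#' Write a table as TSV with deterministic formatting
#'
#' Tab separation, a header line, no quoting, no row names, full-precision
#' fixed-notation numbers — so identical inputs produce byte-identical
#' files.
#'
#' @param x `data.frame`; @param path output file.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(x, path) {
  y <- as.data.frame(x)
  for (cn in names(y)) y[[cn]] <- fmtNum(y[[cn]])
  write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bin count table with its library design
#'
#' Expects a TSV with columns `sgRNA`, `gene`, then one count column per
#' bin in covariate order (default `FR`, `NR`, `NG`, `FG`). Optional
#' columns `sublibrary` and `is_nontargeting` join the design; without
#' `is_nontargeting`, sgRNAs whose gene matches `ntcLabel` are flagged.
#'
#' @param path count TSV.
#' @param binLabels expected bin columns, in increasing green/red order.
#' @param covariate per-bin covariate (default `c(-1, 0, 0, 1)` for 4
#'   bins).
#' @param ntcLabel reserved gene label for nontargeting controls.
#' @return a [BinCountScreen-class].
#' @export
readCountTable <- function(path, binLabels = c("FR", "NR", "NG", "FG"),
                           covariate = defaultBinCovariate(length(binLabels)),
                           ntcLabel = "non-targeting") {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sgRNA", "gene", binLabels)
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  if (anyDuplicated(d$sgRNA))
    stop("duplicated sgRNA ids: ",
         paste(utils::head(unique(d$sgRNA[duplicated(d$sgRNA)]), 3),
               collapse = ", "))
  cnt <- as.matrix(d[binLabels])
  bad <- which(!is.finite(cnt) | cnt < 0 | cnt != round(cnt),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("invalid count at row ", bad[1L, 1L], ", column ",
         binLabels[bad[1L, 2L]])
  rownames(cnt) <- d$sgRNA
  design <- data.frame(sgRNA = d$sgRNA, gene = d$gene,
                       stringsAsFactors = FALSE)
  if ("sublibrary" %in% names(d)) design$sublibrary <- d$sublibrary
  design$is_nontargeting <- if ("is_nontargeting" %in% names(d))
    as.logical(d$is_nontargeting) else d$gene == ntcLabel
  BinCountScreen(cnt, design, covariate = covariate, binLabels = binLabels)
}

#' @rdname readCountTable
#' @param screen a [BinCountScreen-class] to serialize.
#' @param path output TSV path.
#' @export
writeCountTable <- function(screen, path) {
  cnt <- SummarizedExperiment::assay(screen, "counts")
  d <- cbind(libraryDesign(screen)[c("sgRNA", "gene")],
             as.data.frame(cnt, check.names = FALSE))
  rd <- SummarizedExperiment::rowData(screen)
  if ("sublibrary" %in% colnames(rd)) d$sublibrary <- rd$sublibrary
  d$is_nontargeting <- rd$is_nontargeting
  writeTsv(d, path)
}

#' Read/write footprint profiles and BED-like annotation
#'
#' Profile TSVs have columns `transcript`, `position` (0-based footprint
#' 5'-end), `count`. Annotation TSVs are BED-like: `transcript`, `start`,
#' `end` (0-based half-open), `feature`; they are converted to/from the
#' 1-based `GRanges` representation used internally.
#'
#' @param path file path.
#' @return `readFootprintProfile`: `data.frame(transcript, position,
#'   count)`; `readAnnotation`: a `GRanges` with `feature` column.
#' @export
readFootprintProfile <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript", "position", "count")
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  if (any(d$count < 0) || any(d$position < 0))
    stop("negative position or count in ", path)
  d
}

#' @rdname readFootprintProfile
#' @param profile `data.frame(transcript, position, count)`.
#' @export
writeFootprintProfile <- function(profile, path)
  writeTsv(profile[c("transcript", "position", "count")], path)

#' @rdname readFootprintProfile
#' @export
readAnnotation <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript", "start", "end", "feature")
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  gr <- GenomicRanges::GRanges(
    seqnames = d$transcript,
    ranges = IRanges::IRanges(start = d$start + 1L, end = d$end),
    feature = d$feature)
  lens <- tapply(d$end, d$transcript, max)
  GenomeInfoDb::seqlengths(gr) <-
    setNames(as.integer(lens[GenomeInfoDb::seqlevels(gr)]),
             GenomeInfoDb::seqlevels(gr))
  gr
}

#' @rdname readFootprintProfile
#' @param annotation feature `GRanges`.
#' @export
writeAnnotation <- function(annotation, path) {
  writeTsv(data.frame(
    transcript = as.character(GenomicRanges::seqnames(annotation)),
    start = GenomicRanges::start(annotation) - 1L,
    end = GenomicRanges::end(annotation),
    feature = annotation$feature), path)
}

#' Read a flow cytometry event CSV
#'
#' @param path CSV with header; @param columnMap named character mapping
#'   the required channels `green`, `red`, `infrared` to file column
#'   names (default: identical names).
#' @return `data.frame` with columns `green`, `red`, `infrared` (plus any
#'   extras).
#' @export
readFlowEvents <- function(path,
                           columnMap = c(green = "green", red = "red",
                                         infrared = "infrared")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(columnMap), names(d))
  if (length(miss))
    stop("missing channel columns: ", paste(miss, collapse = ", "))
  for (ch in names(columnMap)) d[[ch]] <- d[[columnMap[[ch]]]]
  d
}

#' Serialize a calibration model to JSON
#'
#' @param calibration a [CalibrationModel-class]; @param path JSON path.
#' @export
writeCalibration <- function(calibration, path) {
  jsonlite::write_json(list(kappa = calibration@kappa,
                            leak = calibration@leak,
                            background = as.list(calibration@background),
                            n_events = calibration@nEvents),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibration
#' @return `readCalibration`: a [CalibrationModel-class].
#' @export
readCalibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("CalibrationModel", kappa = x$kappa, leak = x$leak,
               background = unlist(x$background),
               nEvents = as.integer(x$n_events))
}

#' Run the simulate-analyze-call pipeline
#'
#' Simulates a screen (or reads a real count table), runs the enrichment
#' model, calls genes, and writes per-sgRNA and per-gene TSVs plus a JSON
#' provenance/QC record. Re-running with an identical config and seed
#' reproduces byte-identical tables.
#'
#' @param config named list; recognized keys: `seed` (global seed),
#'   `outDir`, `countTable` (path to a real count TSV; omit to simulate),
#'   `screen` (list of [ScreenSimConfig()] arguments), `fdrThreshold`,
#'   `minSgrnas`, `dispersion` (`"shrunk"`/`"pooled"`), `covariate`.
#'   Unknown keys are rejected.
#' @return invisible list: `results` (per-sgRNA), `genes` (per-gene),
#'   `paths` of written files, and the QC record.
#' @export
runPipeline <- function(config) {
  known <- c("seed", "outDir", "countTable", "screen", "fdrThreshold",
             "minSgrnas", "dispersion", "covariate")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outDir <- if (is.null(config$outDir)) "." else config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  qc <- list(seed = seed, version = as.character(packageVersion("ratioscreen")),
             config_hash = sum(utf8ToInt(paste(
               names(config)[order(names(config))], collapse = "|"))))
  t0 <- Sys.time()
  if (!is.null(config$countTable)) {
    screen <- readCountTable(config$countTable)
    truth <- NULL
  } else {
    args <- if (is.null(config$screen)) list() else config$screen
    if (!is.null(config$covariate) && !is.null(args$nBins) &&
        length(config$covariate) != args$nBins)
      stop("covariate length does not match nBins")
    args$seed <- substreamSeed(seed, "screen")
    sim <- do.call(ScreenSimConfig, args)
    out <- simulateScreen(sim)
    screen <- out$screen
    truth <- out$truth
  }
  if (!is.null(config$covariate)) {
    if (length(config$covariate) != ncol(screen))
      stop("covariate length does not match the number of bins")
    binCovariate(screen) <- config$covariate
  }
  disp <- if (is.null(config$dispersion)) "shrunk" else config$dispersion
  res <- analyzeScreen(screen, dispersion = disp)
  fdr <- if (is.null(config$fdrThreshold)) 0.05 else config$fdrThreshold
  minSg <- if (is.null(config$minSgrnas)) 2L else config$minSgrnas
  genes <- callGenes(res, libraryDesign(screen), fdrThreshold = fdr,
                     minSgrnas = minSg)
  paths <- list(
    counts = file.path(outDir, "counts.tsv"),
    sgrna = file.path(outDir, "sgrna_results.tsv"),
    gene = file.path(outDir, "gene_calls.tsv"),
    qc = file.path(outDir, "run_qc.json"))
  writeCountTable(screen, paths$counts)
  writeTsv(res[c("sgRNA", "gene", "beta0", "shift", "se", "dispersion",
                 "pvalue", "qvalue", "flags")], paths$sgrna)
  writeTsv(genes, paths$gene)
  if (!is.null(truth)) {
    paths$truth <- file.path(outDir, "truth.tsv")
    writeTsv(truth, paths$truth)
  }
  qc$n_sgrnas <- nrow(res)
  qc$n_flagged <- sum(res$flags != "")
  qc$n_hit_genes <- sum(genes$hit)
  qc$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(qc, paths$qc, auto_unbox = TRUE, digits = NA)
  invisible(list(results = res, genes = genes, paths = paths, qc = qc))
}
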