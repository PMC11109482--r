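# Three-color reporter deconvolution: infrared-normalized green/red
# channels, calibration against single-isoform lines, absolute long/short
# isoform abundances, and replicate-level ratio contrasts.

#' Normalize flow events by the infrared channel
#'
#' Subtracts per-channel background and divides green and red by the
#' constitutive infrared signal per cell: `g = (G - bgG) / I`,
#' `r = (R - bgR) / I`. Events with nonpositive infrared or nonpositive
#' background-subtracted red are dropped and counted; more than 20% drops
#' triggers a warning.
#'
#' @param events `data.frame` with columns `green`, `red`, `infrared`.
#' @param background named numeric, background offsets `green` and `red`
#'   (fluorescence units, default 0; estimate from an unstained control
#'   with [estimateBackground()]).
#' @return `data.frame` with columns `g`, `r` (plus any extra input
#'   columns), attribute `nDropped`.
#' @export
normalizeEvents <- function(events, background = c(green = 0, red = 0)) {
  stopifnot(all(c("green", "red", "infrared") %in% names(events)))
  bgG <- if ("green" %in% names(background)) background[["green"]] else 0
  bgR <- if ("red" %in% names(background)) background[["red"]] else 0
  g <- (events$green - bgG) / events$infrared
  r <- (events$red - bgR) / events$infrared
  keep <- events$infrared > 0 & r > 0
  nDropped <- sum(!keep)
  if (nDropped > 0.2 * nrow(events))
    warning(sprintf("%d of %d events (%.1f%%) dropped during normalization",
                    nDropped, nrow(events), 100 * nDropped / nrow(events)))
  out <- data.frame(g = g[keep], r = r[keep])
  extra <- setdiff(names(events), c("green", "red", "infrared"))
  for (cn in extra) out[[cn]] <- events[[cn]][keep]
  attr(out, "nDropped") <- nDropped
  out
}

#' Background offsets from an unstained control
#'
#' @param events unstained-control event table (`green`, `red` columns).
#' @return named numeric with the channel medians.
#' @export
estimateBackground <- function(events) {
  c(green = median(events$green), red = median(events$red))
}

#' Calibrate the reporter against single-isoform lines
#'
#' The green-per-red brightness factor kappa is the ratio of channel
#' medians `median(g) / median(r)` on the long-only calibrator; the same
#' ratio on the short-only calibrator is the residual leak, which must stay
#' below 5% of kappa for the two-state model (green reports only the long
#' isoform) to hold.
#'
#' @param longOnly,shortOnly raw event tables for the two calibrator lines.
#' @param background per-channel background offsets (see
#'   [normalizeEvents()]).
#' @return a [CalibrationModel-class].
#' @export
calibrateIsoforms <- function(longOnly, shortOnly,
                              background = c(green = 0, red = 0)) {
  nl <- normalizeEvents(longOnly, background)
  ns <- normalizeEvents(shortOnly, background)
  if (nrow(nl) == 0L || nrow(ns) == 0L)
    stop("calibrator table empty after QC")
  kappa <- median(nl$g) / median(nl$r)
  leak <- median(ns$g) / median(ns$r)
  if (leak > 0.05 * kappa)
    stop(sprintf(paste("short-only green/red leak (%.4g) exceeds 5%% of",
                       "kappa (%.4g); two-state calibration invalid"),
                 leak, kappa))
  methods::new("CalibrationModel", kappa = kappa, leak = max(leak, 0),
               background = c(green = unname(background[["green"]]),
                              red = unname(background[["red"]])),
               nEvents = c(nrow(nl), nrow(ns)))
}

#' Deconvolve absolute isoform abundances from a mixed reporter sample
#'
#' With red reporting total protein and green only the long isoform,
#' long = `median(g) / kappa`, short = `median(r) - long` (so
#' long + short equals the normalized red median exactly, pre-clamping),
#' and the long-isoform fraction is `f = long / median(r)`, clamped to
#' [0, 1] with a flag.
#'
#' @param events raw sample event table (`green`, `red`, `infrared`).
#' @param calibration a [CalibrationModel-class].
#' @return one-row `data.frame`: `long`, `short`, `fraction_long`,
#'   `ratio_green_red` (median g/r), `clamped`, `n_events`.
#' @export
deconvolveIsoforms <- function(events, calibration) {
  stopifnot(methods::is(calibration, "CalibrationModel"))
  ne <- normalizeEvents(events, calibration@background)
  medR <- median(ne$r)
  if (!is.finite(medR) || medR <= 0)
    stop("median normalized red is nonpositive; cannot deconvolve")
  long <- median(ne$g) / calibration@kappa
  short <- medR - long
  f <- long / medR
  clamped <- f < 0 || f > 1
  f <- min(max(f, 0), 1)
  data.frame(long = long, short = short, fraction_long = f,
             ratio_green_red = median(ne$g / ne$r),
             clamped = clamped, n_events = nrow(ne))
}

#' Replicate-level green/red ratio contrast with Welch t-test
#'
#' Summarizes each replicate by its median normalized green/red ratio and
#' reports the mean difference between a knockdown sample and a reference
#' (nontargeting) sample, with a two-sided Welch t-test across replicate
#' medians when both sides have at least two replicates.
#'
#' @param sample,reference either numeric vectors of per-replicate median
#'   g/r ratios, or lists of raw event tables (one per replicate).
#' @param background channel backgrounds applied when event tables are
#'   given.
#' @return `data.frame`: `delta` (sample minus reference), `p_value`
#'   (`NA` with fewer than 2 replicates per side), `n_sample`,
#'   `n_reference`.
#' @export
ratioContrast <- function(sample, reference,
                          background = c(green = 0, red = 0)) {
  asMedians <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    vapply(x, function(ev) {
      ne <- normalizeEvents(ev, background)
      median(ne$g / ne$r)
    }, numeric(1))
  }
  ms <- asMedians(sample)
  mr <- asMedians(reference)
  delta <- mean(ms) - mean(mr)
  p <- if (length(ms) >= 2L && length(mr) >= 2L)
    t.test(ms, mr, var.equal = FALSE)$p.value else NA_real_
  data.frame(delta = delta, p_value = p,
             n_sample = length(ms), n_reference = length(mr))
}

#' Convenience percentile-box gate on two scatter columns
#'
#' Keeps events inside the central `keep` quantile box of two columns
#' (e.g. FSC/SSC surrogates). Inputs to the main functions are expected
#' pre-gated; this is offered for convenience only.
#'
#' @param events event table; @param columns two column names;
#' @param keep central fraction kept per axis (default 0.9).
#' @return gated event table.
#' @export
percentileGate <- function(events, columns, keep = 0.9) {
  stopifnot(length(columns) == 2L, all(columns %in% names(events)))
  lo <- (1 - keep) / 2
  inBox <- rep(TRUE, nrow(events))
  for (cn in columns) {
    q <- quantile(events[[cn]], c(lo, 1 - lo), names = FALSE)
    inBox <- inBox & events[[cn]] >= q[1L] & events[[cn]] <= q[2L]
  }
  events[inBox, , drop = FALSE]
}
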