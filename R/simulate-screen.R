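# Synthetic sort-seq screen generator. Cells carry a log green/red ratio
# Normal(mu0 + delta, sigma^2); the pool is gated into n_bins equal-occupancy
# bins; each sgRNA's cells distribute multinomially with Phi-difference
# probabilities; sequencing counts are NB around depth-scaled cell counts.

#' Configuration for the synthetic sort-seq screen
#'
#' Defaults emulate the screen design at desk scale: five sgRNAs per gene,
#' coverage of at least 500 cells per sgRNA, four equal-occupancy sort bins,
#' and a small fraction of hit genes whose sgRNAs shift the log green/red
#' ratio. Nontargeting controls carry effect 0.
#'
#' @slot nGenes number of targeted genes.
#' @slot sgrnasPerGene sgRNAs per gene (library design: 5).
#' @slot nNontargeting number of nontargeting control sgRNAs.
#' @slot hitFraction fraction of genes that are true regulators.
#' @slot effectSD SD of the gene-level true effect delta (log-ratio units).
#' @slot baselineMu baseline log green/red ratio mu0.
#' @slot cellSD cell-to-cell SD sigma of the log ratio.
#' @slot coverage mean cells per sgRNA entering the sort (>= 500 by design).
#' @slot nBins number of sort bins.
#' @slot depthPerBin sequencing reads per bin library; `NA` means matched to
#'   the expected number of cells per bin.
#' @slot countDispersion NB dispersion of sequencing counts around the
#'   depth-scaled cell counts (PCR/sequencing overdispersion).
#' @slot pooledThresholds gate on the pooled population (`TRUE`, mirroring
#'   sorting of the whole transduced pool) or recompute per sublibrary.
#' @slot seed integer RNG seed; `NA` uses the current RNG state.
#' @export
setClass("ScreenSimConfig", representation(
  nGenes = "integer", sgrnasPerGene = "integer", nNontargeting = "integer",
  hitFraction = "numeric", effectSD = "numeric", baselineMu = "numeric",
  cellSD = "numeric", coverage = "numeric", nBins = "integer",
  depthPerBin = "numeric", countDispersion = "numeric",
  pooledThresholds = "logical", seed = "integer"))

setValidity("ScreenSimConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L || object@sgrnasPerGene < 1L)
    msg <- c(msg, "nGenes and sgrnasPerGene must be positive")
  if (object@nNontargeting < 0L) msg <- c(msg, "nNontargeting must be >= 0")
  if (object@hitFraction < 0 || object@hitFraction > 1)
    msg <- c(msg, "hitFraction must be in [0, 1]")
  if (object@cellSD <= 0) msg <- c(msg, "cellSD must be > 0")
  if (object@coverage <= 0) msg <- c(msg, "coverage must be > 0")
  if (object@nBins < 2L) msg <- c(msg, "nBins must be >= 2")
  if (object@countDispersion < 0)
    msg <- c(msg, "countDispersion must be >= 0")
  nsg <- object@nGenes * object@sgrnasPerGene + object@nNontargeting
  if (is.finite(object@depthPerBin) &&
      object@depthPerBin * object@nBins > 2^31 - 1)
    msg <- c(msg, "depthPerBin too large (integer overflow)")
  if (nsg * object@coverage > 2^31 - 1)
    msg <- c(msg, "coverage * library size overflows integer range")
  if (length(msg)) msg else TRUE
})

#' @rdname ScreenSimConfig-class
#' @param nGenes,sgrnasPerGene,nNontargeting,hitFraction,effectSD see slots.
#' @param baselineMu,cellSD,coverage,nBins,depthPerBin,countDispersion
#'   see slots.
#' @param pooledThresholds,seed see slots.
#' @return a validated `ScreenSimConfig`.
#' @examples
#' cfg <- ScreenSimConfig(nGenes = 50, seed = 1L)
#' sim <- simulateScreen(cfg)
#' sim$screen
#' @export
ScreenSimConfig <- function(nGenes = 400L, sgrnasPerGene = 5L,
                            nNontargeting = 100L, hitFraction = 0.05,
                            effectSD = 1, baselineMu = 0, cellSD = 1,
                            coverage = 500, nBins = 4L, depthPerBin = NA,
                            countDispersion = 0.05,
                            pooledThresholds = TRUE, seed = NA_integer_) {
  methods::new("ScreenSimConfig", nGenes = as.integer(nGenes),
               sgrnasPerGene = as.integer(sgrnasPerGene),
               nNontargeting = as.integer(nNontargeting),
               hitFraction = hitFraction, effectSD = effectSD,
               baselineMu = baselineMu, cellSD = cellSD,
               coverage = coverage, nBins = as.integer(nBins),
               depthPerBin = as.numeric(depthPerBin),
               countDispersion = countDispersion,
               pooledThresholds = pooledThresholds,
               seed = as.integer(seed))
}

# Equal-occupancy bin thresholds for a mixture of Normal(mu0+delta_i, sd^2):
# t_k solves mean_i Phi((t - mu0 - delta_i)/sd) = k/nBins.
binThresholds <- function(delta, mu0, sd, nBins) {
  mixCdf <- function(t) mean(pnorm((t - mu0 - delta) / sd))
  lo <- mu0 + min(delta) - 10 * sd
  hi <- mu0 + max(delta) + 10 * sd
  vapply(seq_len(nBins - 1L), function(k)
    uniroot(function(t) mixCdf(t) - k / nBins, c(lo, hi),
            tol = 1e-10)$root, numeric(1))
}

#' Bin occupancy probabilities for one sgRNA
#'
#' Probability that a cell with log-ratio Normal(`mu0 + delta`, `sd^2`)
#' falls in each bin delimited by `thresholds`:
#' \eqn{\Phi((t_{k+1}-\mu_0-\delta)/\sigma) - \Phi((t_k-\mu_0-\delta)/\sigma)}.
#'
#' @param delta sgRNA true effect (log-ratio units).
#' @param thresholds increasing bin boundaries (length nBins - 1).
#' @param mu0 baseline log ratio; @param sd cell-to-cell SD.
#' @return probability vector of length `length(thresholds) + 1`.
#' @export
binProbabilities <- function(delta, thresholds, mu0 = 0, sd = 1) {
  stopifnot(!is.unsorted(thresholds, strictly = TRUE))
  edges <- c(-Inf, thresholds, Inf)
  diff(pnorm((edges - mu0 - delta) / sd))
}

#' Simulate a sort-seq CRISPRi screen
#'
#' Draws gene-level effects for a `hitFraction` of genes from
#' Normal(0, `effectSD`^2), multiplies each by a per-sgRNA efficacy drawn
#' Uniform(0.3, 1) (CRISPRi guides vary in potency), places
#' equal-occupancy bin thresholds at the quantiles of the pooled log-ratio
#' population, allocates each sgRNA's cells to bins multinomially with
#' normal-CDF probabilities, and draws sequencing counts NB around the
#' depth-scaled cell counts. Deterministic given `seed`.
#'
#' @param config a [ScreenSimConfig-class].
#' @return list with `screen` (a [BinCountScreen-class]), `design`
#'   (`sgRNA`, `gene`, `sublibrary`, `is_nontargeting`), and `truth`
#'   (`sgRNA`, `delta`, `is_hit`, plus cell counts per bin as attribute
#'   `cells` and gate positions as attribute `thresholds`).
#' @export
simulateScreen <- function(config = ScreenSimConfig()) {
  stopifnot(methods::is(config, "ScreenSimConfig"))
  methods::validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  nT <- config@nGenes * config@sgrnasPerGene
  nsg <- nT + config@nNontargeting
  genes <- paste0("gene", seq_len(config@nGenes))
  design <- data.frame(
    sgRNA = c(paste0(rep(genes, each = config@sgrnasPerGene), "_sg",
                     seq_len(config@sgrnasPerGene)),
              if (config@nNontargeting > 0)
                paste0("NTC_sg", seq_len(config@nNontargeting))),
    gene = c(rep(genes, each = config@sgrnasPerGene),
             rep("non-targeting", config@nNontargeting)),
    sublibrary = "simlib",
    is_nontargeting = rep(c(FALSE, TRUE), c(nT, config@nNontargeting)),
    stringsAsFactors = FALSE)
  isHitGene <- runif(config@nGenes) < config@hitFraction
  geneEffect <- ifelse(isHitGene, rnorm(config@nGenes, 0, config@effectSD), 0)
  efficacy <- runif(nT, 0.3, 1)
  delta <- c(rep(geneEffect, each = config@sgrnasPerGene) * efficacy,
             rep(0, config@nNontargeting))
  thr <- binThresholds(delta, config@baselineMu, config@cellSD, config@nBins)
  probs <- t(vapply(delta, binProbabilities, numeric(config@nBins),
                    thresholds = thr, mu0 = config@baselineMu,
                    sd = config@cellSD))
  cellsPerSg <- pmax(rpois(nsg, config@coverage), 1L)
  cells <- matrix(0L, nsg, config@nBins)
  for (i in seq_len(nsg))
    cells[i, ] <- drop(rmultinom(1L, cellsPerSg[i], probs[i, ]))
  depth <- config@depthPerBin
  if (is.na(depth)) depth <- config@coverage * nsg / config@nBins
  binCells <- colSums(cells)
  counts <- matrix(0L, nsg, config@nBins)
  for (b in seq_len(config@nBins)) {
    mu <- cells[, b] * depth / max(binCells[b], 1)
    counts[, b] <- if (config@countDispersion > 0)
      rnbinom(nsg, size = 1 / config@countDispersion, mu = mu)
    else rpois(nsg, mu)
  }
  rownames(counts) <- design$sgRNA
  rownames(cells) <- design$sgRNA
  truth <- data.frame(sgRNA = design$sgRNA, delta = delta,
                      is_hit = c(rep(isHitGene, each = config@sgrnasPerGene),
                                 rep(FALSE, config@nNontargeting)),
                      stringsAsFactors = FALSE)
  attr(truth, "thresholds") <- thr
  attr(truth, "cells") <- cells
  list(screen = BinCountScreen(counts, design,
                               covariate = defaultBinCovariate(config@nBins),
                               binLabels = defaultBinLabels(config@nBins)),
       design = design, truth = truth)
}
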