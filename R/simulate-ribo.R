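# Synthetic ribosome profiling data over a uORF/spacer/CDS/3'UTR transcript
# architecture, with condition-specific occupancy multipliers emulating a
# ribosome-rescue-factor knockdown: uORF and start-codon-vicinity occupancy
# on a reporter transcript, transcriptome-wide 3'UTR accumulation, and a
# TE increase of a TOP gene set. Matched RNA-seq counts carry no TE shift.

#' Configuration for synthetic ribosome profiling data
#'
#' All transcripts share one architecture: a 5' UTR containing a short uORF
#' that ends `spacerLen` nucleotides before the CDS start (the reporter's
#' wild-type spacer is 7 nt and the uORF is six codons plus its stop), then
#' the CDS and a 3' UTR. Per-position footprint 5'-end counts are drawn
#' NB (Poisson at dispersion 0) around feature-specific rates times a
#' per-gene expression factor; knockdown libraries additionally apply the
#' occupancy multipliers.
#'
#' @slot utr5Len,uorfLen,spacerLen,cdsLen,utr3Len feature lengths (nt). The
#'   uORF is placed so it ends `spacerLen` nt before the CDS start.
#' @slot rates named numeric, baseline footprint 5'-end rate per nt for
#'   `utr5`, `uorf`, `spacer`, `cds`, `utr3` (footprints/nt per library at
#'   expression factor 1).
#' @slot uorfMult,startMult,utr3Mult knockdown occupancy multipliers for
#'   the reporter uORF, the start-codon vicinity (the `startWindow` nt of
#'   5' UTR/spacer immediately upstream of the CDS start), and all 3' UTRs.
#' @slot topTeMult knockdown TE fold change of the TOP gene set (applied to
#'   footprints only).
#' @slot startWindow width (nt) of the start-codon vicinity.
#' @slot nGenes background genes; @slot nTop TOP-set genes.
#' @slot replicates libraries per condition and assay (study design: 3).
#' @slot countDispersion NB dispersion of counts (0 = Poisson).
#' @slot exprSD log-normal SD of the per-gene expression factor.
#' @slot rnaBase mean RNA-seq count per gene at expression factor 1.
#' @slot seed integer seed; `NA` uses current RNG state.
#' @export
setClass("RiboSimConfig", representation(
  utr5Len = "integer", uorfLen = "integer", spacerLen = "integer",
  cdsLen = "integer", utr3Len = "integer", rates = "numeric",
  uorfMult = "numeric", startMult = "numeric", utr3Mult = "numeric",
  topTeMult = "numeric", startWindow = "integer",
  nGenes = "integer", nTop = "integer", replicates = "integer",
  countDispersion = "numeric", exprSD = "numeric", rnaBase = "numeric",
  seed = "integer"))

setValidity("RiboSimConfig", function(object) {
  msg <- character()
  lens <- c(object@utr5Len, object@uorfLen, object@spacerLen,
            object@cdsLen, object@utr3Len)
  if (any(lens[-3L] <= 0L)) msg <- c(msg, "feature lengths must be > 0")
  if (object@spacerLen < 0L) msg <- c(msg, "spacerLen must be >= 0")
  if (object@cdsLen %% 3L != 0L)
    msg <- c(msg, "cdsLen must be divisible by 3")
  if (object@cdsLen < 63L)
    msg <- c(msg, "cdsLen must leave codons after the 15/5-codon exclusion")
  if (object@uorfLen + object@spacerLen > object@utr5Len)
    msg <- c(msg, "uORF plus spacer must fit inside the 5' UTR")
  if (!all(c("utr5", "uorf", "spacer", "cds", "utr3") %in%
           names(object@rates)))
    msg <- c(msg, "rates must name utr5, uorf, spacer, cds, utr3")
  if (any(c(object@uorfMult, object@startMult, object@utr3Mult,
            object@topTeMult) <= 0))
    msg <- c(msg, "multipliers must be > 0")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname RiboSimConfig-class
#' @param utr5Len,uorfLen,spacerLen,cdsLen,utr3Len,rates see slots.
#' @param uorfMult,startMult,utr3Mult,topTeMult,startWindow see slots.
#' @param nGenes,nTop,replicates,countDispersion,exprSD,rnaBase,seed
#'   see slots.
#' @return a validated `RiboSimConfig`.
#' @export
RiboSimConfig <- function(utr5Len = 100L, uorfLen = 21L, spacerLen = 7L,
                          cdsLen = 300L, utr3Len = 150L,
                          rates = c(utr5 = 0.05, uorf = 0.5, spacer = 0.1,
                                    cds = 0.5, utr3 = 0.02),
                          uorfMult = 3, startMult = 4, utr3Mult = 5,
                          topTeMult = 2, startWindow = 15L,
                          nGenes = 300L, nTop = 50L, replicates = 3L,
                          countDispersion = 0.02, exprSD = 0.5,
                          rnaBase = 200, seed = NA_integer_) {
  methods::new("RiboSimConfig", utr5Len = as.integer(utr5Len),
               uorfLen = as.integer(uorfLen),
               spacerLen = as.integer(spacerLen),
               cdsLen = as.integer(cdsLen), utr3Len = as.integer(utr3Len),
               rates = rates, uorfMult = uorfMult, startMult = startMult,
               utr3Mult = utr3Mult, topTeMult = topTeMult,
               startWindow = as.integer(startWindow),
               nGenes = as.integer(nGenes), nTop = as.integer(nTop),
               replicates = as.integer(replicates),
               countDispersion = countDispersion, exprSD = exprSD,
               rnaBase = rnaBase, seed = as.integer(seed))
}

#' Build the shared transcript annotation
#'
#' Feature intervals in transcript coordinates as a
#' \link[GenomicRanges]{GRanges} (1-based internally; the TSV interchange
#' format is 0-based half-open, see [writeAnnotation()]). Features:
#' `utr5`, `uorf` (inside the 5' UTR, ending `spacerLen` nt before the
#' CDS), `spacer`, `cds`, `utr3`.
#'
#' @param config a [RiboSimConfig-class].
#' @param transcripts transcript ids.
#' @return `GRanges` with a `feature` metadata column and `seqlengths` set
#'   to the transcript length.
#' @export
transcriptAnnotation <- function(config, transcripts) {
  u5 <- config@utr5Len; uo <- config@uorfLen; sp <- config@spacerLen
  cds <- config@cdsLen; u3 <- config@utr3Len
  txLen <- u5 + cds + u3
  # 0-based half-open feature starts/ends within one transcript
  start0 <- c(utr5 = 0L, uorf = u5 - sp - uo, spacer = u5 - sp,
              cds = u5, utr3 = u5 + cds)
  end0 <- c(utr5 = u5, uorf = u5 - sp, spacer = u5, cds = u5 + cds,
            utr3 = txLen)
  feat <- names(start0)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(transcripts, each = length(feat)),
    ranges = IRanges::IRanges(start = rep(start0 + 1L, length(transcripts)),
                              end = rep(end0, length(transcripts))),
    feature = rep(feat, length(transcripts)))
  GenomeInfoDb::seqlengths(gr) <- setNames(rep(txLen, length(transcripts)),
                                           transcripts)
  gr
}

#' Simulate footprint profiles, RNA counts, and annotation
#'
#' Generates `2 * replicates` footprint libraries (conditions `control`
#' and `knockdown`) and matched RNA-seq count libraries over `nGenes`
#' background genes, `nTop` TOP-set genes, and one `reporter` transcript.
#' Knockdown multipliers: reporter uORF occupancy `uorfMult`; reporter
#' start-codon vicinity `startMult`; every transcript's 3' UTR `utr3Mult`;
#' TOP-gene footprints (all positions) `topTeMult` — RNA counts are
#' unchanged, so `topTeMult` is a pure TE shift. Deterministic given
#' `seed`.
#'
#' @param config a [RiboSimConfig-class].
#' @return list: `profiles` (named list of `data.frame(transcript,
#'   position, count)`, 0-based footprint 5'-end positions, zero rows
#'   omitted), `rnaCounts` (gene x RNA-library integer matrix),
#'   `annotation` (`GRanges`), `topGenes`, `librarySheet`
#'   (`library`, `condition`, `assay`, `replicate`), `config`.
#' @export
simulateRibo <- function(config = RiboSimConfig()) {
  stopifnot(methods::is(config, "RiboSimConfig"))
  methods::validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  genes <- c("reporter",
             paste0("top", seq_len(config@nTop)),
             paste0("bg", seq_len(config@nGenes)))
  topGenes <- genes[seq_len(config@nTop) + 1L]
  ann <- transcriptAnnotation(config, genes)
  txLen <- config@utr5Len + config@cdsLen + config@utr3Len
  exprFactor <- setNames(rlnorm(length(genes), 0, config@exprSD), genes)

  # per-position baseline rate vector shared by all transcripts
  featAt <- rep("utr5", txLen)
  g1 <- ann[GenomicRanges::seqnames(ann) == genes[1L]]
  for (i in seq_along(g1)) {
    f <- g1$feature[i]
    if (f == "utr5") next
    featAt[GenomicRanges::start(g1)[i]:GenomicRanges::end(g1)[i]] <- f
  }
  baseRate <- config@rates[featAt]
  cdsStart0 <- config@utr5Len            # 0-based CDS start
  startVic <- (cdsStart0 - config@startWindow):(cdsStart0 - 1L) + 1L # 1-based
  utr3Idx <- which(featAt == "utr3")
  uorfIdx <- which(featAt == "uorf")

  conds <- c("control", "knockdown")
  profiles <- list()
  sheet <- NULL
  drawCounts <- function(mu) {
    if (config@countDispersion > 0)
      rnbinom(length(mu), size = 1 / config@countDispersion, mu = mu)
    else rpois(length(mu), mu)
  }
  for (cond in conds) for (rep_ in seq_len(config@replicates)) {
    lib <- sprintf("ribo_%s_%d", cond, rep_)
    rows <- vector("list", length(genes))
    for (gi in seq_along(genes)) {
      rate <- baseRate * exprFactor[gi]
      if (cond == "knockdown") {
        rate[utr3Idx] <- rate[utr3Idx] * config@utr3Mult
        if (genes[gi] == "reporter") {
          rate[uorfIdx] <- rate[uorfIdx] * config@uorfMult
          rate[startVic] <- rate[startVic] * config@startMult
        }
        if (genes[gi] %in% topGenes) rate <- rate * config@topTeMult
      }
      cnt <- drawCounts(rate)
      nz <- which(cnt > 0)
      if (length(nz))
        rows[[gi]] <- data.frame(transcript = genes[gi],
                                 position = nz - 1L,
                                 count = cnt[nz])
    }
    profiles[[lib]] <- do.call(rbind, rows[!vapply(rows, is.null,
                                                   logical(1))])
    rownames(profiles[[lib]]) <- NULL
    sheet <- rbind(sheet, data.frame(library = lib, condition = cond,
                                     assay = "ribo", replicate = rep_))
  }
  rnaLibs <- as.vector(outer(seq_len(config@replicates), conds,
                             function(r, cn) sprintf("rna_%s_%d", cn, r)))
  rnaCounts <- matrix(0L, length(genes), length(rnaLibs),
                      dimnames = list(genes, rnaLibs))
  for (cond in conds) for (rep_ in seq_len(config@replicates)) {
    lib <- sprintf("rna_%s_%d", cond, rep_)
    mu <- config@rnaBase * exprFactor
    rnaCounts[, lib] <- drawCounts(mu)
    sheet <- rbind(sheet, data.frame(library = lib, condition = cond,
                                     assay = "rna", replicate = rep_))
  }
  list(profiles = profiles, rnaCounts = rnaCounts, annotation = ann,
       topGenes = topGenes, librarySheet = sheet, config = config)
}
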