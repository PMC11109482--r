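---
title: "Models and methods in ratioscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ratioscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratioscreen)
```

## Overview

`ratioscreen` analyzes pooled CRISPRi sort-seq screens built on a
ratiometric fluorescent reporter of translation start-site choice, plus
the two orthogonal readouts that typically accompany such a screen:
three-color flow cytometry of reporter lines and ribosome profiling. This
vignette explains the models, the tunable parameters, the synthetic-data
generator used for validation, and the numerical and design choices.

## The sort-seq enrichment model

Cells carrying a guide are sorted into `n` bins of increasing green/red
fluorescence ratio (default four, labeled FR, NR, NG, FG, each holding
about a quarter of the pool). The count of guide $i$ in bin $b$ is modeled

$$K_{ib} \sim \mathrm{NB}\!\left(\mu_{ib} = s_b\,
e^{\beta_{0i} + \beta_i x_b},\ \alpha_i\right),
\qquad x = (-1, 0, 0, 1),$$

so a guide that shifts the isoform ratio has a constant multiplicative
enrichment in the far bins relative to the two middle bins. $\beta_i$ is
the **isoform shift score**: positive values mean enrichment toward the
high green/red (long-isoform) bins. The covariate is a parameterization,
not a measurement: adding a constant to $x$ moves only $\beta_0$, and
scaling $x$ by $c$ scales $\beta$ by $1/c$ with identical p-values (both
properties are tested).

Components:

* **Size factors** ($s_b$): each bin is its own sequencing library, so
  depth/composition is equalized by median-of-ratios over guides with
  positive counts in every bin, rescaled to geometric mean 1. The four
  bins hold near-identical guide compositions, which is exactly the
  regime in which median-of-ratios is well behaved. With no all-positive
  row the total-count ratio is used, with a warning.
* **Dispersion** ($\alpha_i$): four observations and two coefficients
  leave almost no per-guide information, so per-guide Cox–Reid adjusted
  ML estimates are shrunk toward a parametric trend
  $\alpha(\mu) = a_0 + a_1/\mu$ via the posterior mode under a log-normal
  prior (variance 0.25 on the log scale — deliberately strong given the
  four-observation design). When the gamma-family trend fit fails, a
  nonnegative least-squares fit is tried; when most per-guide estimates
  sit at the $10^{-8}$ floor (effectively Poisson data) the prior centers
  on the floor-dominated median. `dispersion = "pooled"` instead uses a
  single moment-based estimate, as a transparent alternative.
* **Testing**: Wald $p = 2(1 - \Phi(|\beta|/\mathrm{SE}))$ with SE from
  the observed Fisher information; BH adjustment within each sublibrary,
  matching per-sublibrary screening. Guides with total count below 10 are
  reported but flagged `low_coverage` and excluded from trend fitting;
  all-zero rows are excluded from testing.
* **Gene calls**: a gene is a hit when at least two guides reach
  `qvalue < 0.05` with the *same* sign. Sign concordance is our reading
  of "two or more independent sgRNAs": discordant significant guides more
  likely reflect off-target behavior than a coherent gene effect.
  Nontargeting guides never generate calls.

The estimator is validated three ways: an analytic Poisson-limit row
(counts `(10, 20, 20, 40)` give $\beta = \ln 2$ exactly), a dense
grid-plus-golden-section search of the same likelihood (agreement to
$10^{-4}$ on random rows), and a fixed-dispersion comparison against an
independent NB GLM implementation.

Two open choices we resolved and record here: the shift scores are
reported as unshrunk MLEs (no LFC shrinkage — effect-size shrinkage would
entangle the ranking with the dispersion prior), and nontargeting guides
participate in size-factor and dispersion estimation (they are the bulk
of the null and carry the same technical noise).

## The screen simulator

`simulateScreen()` draws, per cell, a log green/red ratio
$\mathrm{Normal}(\mu_0 + \delta_i, \sigma^2)$; guide effects $\delta$ act
additively on the log ratio, the minimal model consistent with a
multiplicative change in the ratio itself. Bin gates are the
equal-occupancy quantiles of the pooled population, computed exactly by
root-finding on the mixture CDF (the pool is gated once, as in sorting a
whole transduced pool; per-sublibrary gates are a config option). Each
guide's cells are then allocated multinomially with
$\Phi((t_{k+1}-\mu_0-\delta)/\sigma) - \Phi((t_k-\mu_0-\delta)/\sigma)$
probabilities, and sequencing counts are drawn NB around depth-scaled
cell counts (dispersion 0.05, standing in for PCR/sequencing
overdispersion the GLM must absorb).

Defaults are the study design where stated and desk-scale otherwise:
5 sgRNAs/gene, coverage 500 cells per guide, 4 bins, baseline
$\mu_0 = 0$, cell spread $\sigma = 1$ (log-ratio units), 400 genes plus
100 nontargeting guides (~2,100 guides — the same nontargeting proportion
as the 57,900/1,070 full library, at 1/30 scale), hit fraction 5%, gene
effects $\mathrm{Normal}(0, 1)$ with per-guide efficacy
$\mathrm{Uniform}(0.3, 1)$ so that guides against one gene differ in
potency — the partial-concordance structure gene calling must handle.

What the simulator does *not* model: sequence-level reads, PCR
duplicates, barcode swapping, guide-specific off-target effects, or
fitness dropout during culture. Passing tests therefore demonstrate
correctness of the estimator under the stated sampling model, not
robustness to those real-data pathologies.

A note on rank recovery: the Spearman correlation between estimated and
true effects is evaluated on a dense effect grid (every gene perturbed).
On a 5%-hit screen the statistic is mathematically bounded near 0.38
regardless of estimator quality, because 95% of true effects are exactly
tied at zero while their estimates are continuous noise; the grid design
is the meaningful rank test, and sign accuracy plus gene-level FDR cover
the sparse-hit regime.

## Three-color deconvolution

Events carry green $G$ (long isoform via split-fluorophore
complementation), red $R$ (both isoforms, same C-terminal fusion), and
infrared $I$ (constitutive normalizer). After optional background
subtraction, $g = (G-\mathrm{bg}_G)/I$ and $r = (R-\mathrm{bg}_R)/I$
remove per-cell expression variation. Calibration on a long-only line
gives the brightness factor $\kappa = \tilde g/\tilde r$ (medians);
the same ratio on a short-only line is the leak, and calibration is
rejected when leak $> 0.05\,\kappa$ because residual green from the
short isoform violates the two-state model. For a mixed sample,

$$\mathrm{long} = \tilde g/\kappa, \quad
\mathrm{short} = \tilde r - \mathrm{long}, \quad
f = \mathrm{long}/\tilde r \in [0, 1].$$

Medians, not means, summarize every channel (robust to flow outliers and
consistent throughout the package); $f$ comes from per-sample channel
medians rather than per-event ratios to avoid ratio-of-noisy-numbers
instability. Conservation (long + short equals the normalized red median,
pre-clamping) and exact scale invariance under a global channel rescale
are tested. Equal per-molecule red brightness of both isoforms is
assumed; differential red-fluorophore maturation between isoforms would
bias $f$ and is not corrected. The simulator draws a log-normal latent
expression level per event, splits it $f:(1-f)$ between isoforms, applies
5% CV multiplicative channel noise by default, and floors negative
outcomes at zero with a QC counter; recovery is within 0.02 of truth
across $f \in \{0, 0.1, \ldots, 1\}$ at 10,000 events.

Replicate-level comparisons use the difference of median $g/r$ with a
two-sided Welch t-test across replicate medians (the only inferential
comparison provided; multi-group ANOVA machinery is out of scope).

## Ribosome footprint quantification

Footprints are indexed by their 5′-end position, 0-based, in transcript
coordinates; feature intervals are half-open `[start, end)` in the TSV
interchange format and 1-based closed inside `GRanges`. An optional fixed
P-site offset (+12 nt) exists but is off by default, since the analyses
here are defined on 5′ ends.

* `regionDensity()` — footprint count / feature length.
* `metageneStop()` — counts re-indexed to the offset from the stop
  codon's first nucleotide (offset 0), each library normalized by its
  total footprint count, then the per-position median across a
  condition's replicate libraries. Depth invariance is exact by
  construction and tested.
* `cdsNormalizedProfile()` — per-position counts divided by the mean CDS
  occupancy excluding the first 15 and last 5 codons. The exclusion is
  stated for transcriptome quantification; we apply it to the divisor as
  well so that initiation/termination peaks cannot inflate their own
  denominator.
* `teTest()` — per gene, an NB GLM over the combined footprint + RNA
  libraries with condition, assay, and interaction coefficients;
  `log2dTE` is the interaction divided by $\ln 2$. This is the standard
  interaction operationalization of a TE contrast and reuses the same
  NB machinery as the screen model (one implementation, doubly tested).
  Size factors are median-of-ratios over the combined matrix; genes with
  normalized mean count below 10 in either assay are excluded; BH across
  tested genes.
* `genesetEcdf()` — ECDFs of `log2dTE` for a supplied gene set (e.g. TOP
  mRNAs) versus the complement, with the median shift. No formal set
  test is attached, only the descriptive curves and shift.

The ribo simulator shares one architecture across transcripts — 100 nt
5′ UTR containing a 21 nt uORF (six codons plus stop) ending 7 nt before
a 300 nt CDS, then a 150 nt 3′ UTR — with per-feature footprint rates
(CDS 0.5/nt baseline, uORF elevated, UTRs low) scaled by a log-normal
per-gene expression factor. Knockdown multiplies: the reporter's uORF
occupancy (×3) and start-codon vicinity (15 nt upstream of the CDS, ×4),
every transcript's 3′ UTR (×5, the unrecycled-ribosome signature), and
all footprint positions of a 50-gene TOP set (×2, a pure TE shift since
RNA is untouched). Three replicate libraries per condition and assay,
301 background + TOP genes plus the reporter — sizes chosen so the full
simulation-and-analysis cycle runs in seconds while leaving per-gene
3′ UTR counts realistically sparse.

## Determinism and numerics

Every generator is bit-reproducible given its seed; pipeline stages draw
from named substreams derived from one global seed so perturbing one
stage leaves the others untouched. Writers emit tab-separated tables with
full-precision deterministic number formatting, making re-runs
byte-identical. GLM convergence is declared at a score-vector maximum
below $10^{-8}$ with step-halving against divergence; dispersions are
floored at $10^{-8}$; degenerate rows (all-zero, constant) follow
explicit contracts (flagged, or assigned the trend dispersion) rather
than numerical accident.

## Known limitations

The NB GLM treats bins as independent libraries, ignoring the
multinomial coupling induced by sorting a fixed pool of cells; with four
bins and moderate effects this costs little, but extremely skewed guides
(all reads in one bin) rely on the NB tail rather than the exact
multinomial. The dispersion prior variance is fixed rather than
estimated from the data (four observations per row give no usable
estimate of it). The flow model assumes linear detectors and no spectral
spillover between the three channels. TE inference assumes the RNA and
footprint libraries share size-factor geometry; strongly
composition-biased libraries would need assay-specific normalization.
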