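---
title: "Detecting and assigning extrachromosomal DNA from scATAC-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and assigning extrachromosomal DNA from scATAC-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccell)
```

## The problem

Extrachromosomal DNA (ecDNA) circles carry amplified oncogenes in many
tumours, glioblastoma prominently among them. Because ecDNA is present at
tens of copies per cell and is unusually accessible chromatin, a
single-cell ATAC-seq library contains a strong, continuous accessibility
signal over the circle's genomic footprint, plus discordant and clipped
read pairs at the ligation junctions that betray its circular structure.
`eccell` exploits both signals in two stages:

1. **Pseudo-bulk detection.** All cells are pooled into one bulk-like
   library. Amplified segments are called from binned coverage, discordant
   read pairs are clustered into breakpoint junctions, junctions are
   sharpened to base resolution with soft-clip positions, and circular
   candidates are assembled as alternating cycles in the breakpoint graph.
2. **Per-cell assignment.** For each candidate, the per-cell normalised
   signal `log2(ecCPM)` is tested for multimodality with Hartigan's dip
   test; bimodal signals are split with a two-component Gaussian mixture
   (cells in the higher-mean component are called ecDNA-positive),
   unimodal signals fall back to k-means on a gene-score matrix. Cells
   with their own discordant reads at the junctions form a gold standard,
   and a one-sided Fisher's exact test checks that predicted positives are
   enriched for that direct evidence.

The package also provides the two simulation protocols used to benchmark
the method and a sliding-window per-cell copy-number estimator, so the
whole pipeline can be validated without any external data.

## Model and assumptions

Detection rests on three assumptions about ecDNA in scATAC-seq data: the
circle is present at many copies (so its footprint is strongly enriched
over the genome-wide background), its accessibility signal is continuous
over the footprint, and in samples that carry ecDNA it is the dominant
source of copy gain in its region. Violations -- for example, a linear
homogeneously-staining-region amplification -- produce the coverage
enrichment without circular junction evidence; such regions are not
assembled into cycles and are not reported.

Per-cell assignment models the normalised signal of cell $i$,

$$\log_2 \mathrm{ecCPM}_i = \log_2\!\left(
  \frac{\text{reads in ecDNA}_i + 1}{\text{total reads}_i}\times 10^6
\right),$$

as a two-component normal mixture
$w\,\mathcal{N}(\mu_1,\sigma_1^2) + (1-w)\,\mathcal{N}(\mu_2,\sigma_2^2)$,
fitted by EM. The `+1` pseudocount is this package's choice (documented,
configurable): zero-signal cells otherwise map to $-\infty$ and cannot
enter the fit. The mixture is fitted only when the dip test rejects
unimodality at $\alpha = 0.05$; its p-value is Monte-Carlo, computed
against sorted uniform samples (the asymptotically least favourable
unimodal null), with $B = 2000$ replicates by default -- table-free and
exactly reproducible under a seed.

## Parameters that matter

Detector (`detector_config()`), with units and defaults:

* `bin_size` (1 kb) -- coverage resolution; segment boundaries are
  quantised to it until clip refinement sharpens them.
* `depth_floor` (5) and `enrich_factor` (2) -- a bin is amplified when its
  depth reaches `max(depth_floor, enrich_factor x global median)`. The
  absolute floor ties segment calling to the published `depth_mean > 5`
  retention filter; the relative guard keeps the rule meaningful in deep
  libraries.
* `insert_cutoff` (1 kb) -- a pair is discordant when its mates sit on
  different chromosomes, share a strand or face outward, or exceed this
  template length (standard structural-variant practice).
* `cluster_window` (500 bp) / `min_discordant_support` (3) -- breakend
  clustering granularity and the minimum read-pair support per junction.
* `snap_window` (2 kb) -- junction breakends snap to the nearest amplified
  segment end of matching side within this window. It is deliberately
  wider than `cluster_window`: coverage-derived segment ends carry up to
  one `bin_size` of quantisation error, so snapping at 500 bp would
  discard true junctions. Junctions near no segment end are dropped
  rather than seeding segments, per the continuity assumption.
* Retention filter -- size within [10 kb, 20 Mb], `depth_mean > 5`,
  `high_coverage > 0.1`. `high_coverage` is defined here as the fraction
  of candidate bases at or above the segment-calling threshold, which
  makes the published `> 0.1` rule self-consistent with segmentation.

Assignment: dip $\alpha$ (0.05), mixture `sigma_floor` ($10^{-3}$),
posterior threshold (0.5, strict, on the higher-mean component), gene
score = per-gene standardised `log2(1 + CPM)` over the gene body plus a
2 kb upstream promoter. The gene score is a simplified stand-in for
distance-weighted accessibility models used by large scATAC frameworks;
it is swappable and only reached when the signal is unimodal.

## What the simulators emulate

**Read-level simulator.** Circles are random compositions of 1--4
oriented genomic segments ligated into one circular sequence; paired-end
50 bp reads are drawn uniformly from the circle at a configurable local
depth over a uniform ~4x background. Pairs straddling a ligation junction
become discordant records and reads crossing one are soft-clipped at the
exact breakpoint, which is precisely the evidence the detector consumes.
Reads are emitted as already-aligned records by coordinate projection
(`write_sam()` exports them for an external aligner when wanted); they are
error-free, the background is uniform rather than peaked, and barcodes
carry no doublet or quality structure. Passing detection benchmarks on
this background therefore demonstrates the geometry of the method --
segmentation, clustering, assembly -- not robustness to mapping artefacts
of repetitive regions.

**Count-matrix simulator.** Bin-by-cell counts follow
$X_{ij} \sim \mathrm{Poisson}(0.5\,C_{ij}\lambda_{ij})$ with a sparse
baseline $\lambda$ (10% accessible bins, log-normal magnitudes and
per-cell depth factors; a template count matrix can be supplied instead,
reproduced by rank-one moment matching). Cells are split into 5 equal
groups; in the first $m$ groups the entries of $C$ overlapping the
simulated ecDNA are $2 \times$ the copy ratio, diploid $C = 2$ elsewhere,
so the amplified expectation is exactly copy-ratio times baseline.
Simulated ecDNA regions span 50 kb--10 Mb and must overlap accessible
bins by at least 3%, mirroring the protocol's retention rule. The mixture
sweep samples 1000-cell mixtures (10%..90% positives, without
replacement) from amplified/diploid pools of 2500 simulated cells.

## Problem sizes

Desk-scale runs use a synthetic mini-genome instead of hg38; the protocol
is size-parameterised, so everything scales proportionally. The package's
own benchmarks use: detection, 8 x 10 Mb chromosomes, 24 planted circles
of 150--900 kb (1--3 segments, placed without overlap -- on a small genome
random placement would otherwise entangle the truth), local depths
10--30x or 5x over a 4x background; classification, 5000 x 10 kb bins,
1000 cells, the full $m \in \{1..4\} \times$ copy-ratio
$\{3,5,10,20\}$ grid with 3 repeats and 4 regions per repeat. These sizes
were fixed once when the benchmarks were designed.

## Numerical choices

* Dip statistic: the greatest-convex-minorant / least-concave-majorant
  construction over a shrinking modal interval, in C++; equally spaced
  samples attain the exact lower bound $1/(2n)$ and two equal point
  masses the 0.25 maximum, which the tests pin down. A slow chord-based
  reference implementation cross-checks it on random samples.
* EM: initialised from 1-D k-means centroids; convergence at relative
  log-likelihood change $< 10^{-8}$; component SDs floored at
  `sigma_floor` to avoid the degenerate spike solution; components
  reordered so $\mu_1 \le \mu_2$ after fitting. The log-likelihood is
  asserted non-decreasing at every iteration.
* Fisher's exact test: exact hypergeometric tail via `phyper`, one-sided
  "greater" because the hypothesis is directional (enrichment of
  discordant evidence in predicted positives). The reported odds ratio is
  the sample ratio $ad/bc$ ($\infty$ when $bc = 0 < ad$), not the
  conditional MLE.
* Clip-mode ties break towards the smaller coordinate; k-means label
  semantics always follow the higher-mean cluster; greedy detection-truth
  matching (reciprocal overlap $\ge$ 0.5, best first, one-to-one) is
  deterministic and order-invariant.
* Chunked processing: coverage chunks are aligned to the bin grid and
  each record contributes its full span to the global track, while
  discordant pairs are clustered globally; the tests assert the result is
  identical for any chunk size.
* Degenerate inputs error out early: intervals with `start >= end`,
  mixture fits on constant data, dip on fewer than 4 points or
  zero-spread samples, assignments with fewer than 10 qualified cells.

## Open design points, as resolved here

Where the upstream literature leaves choices open, this package fixes
them as follows. Detection-truth matching uses reciprocal overlap of the
segment footprints at 0.5 (per-ecDNA, not per-breakpoint). The copy
estimate reported by `cnv_zscore()` is `2 x (window CPM / per-cell median
window CPM)` with 10%-trimmed moments for the z-score background -- a
robust diploid-scaled surrogate, not a claim of numeric equivalence with
any particular published per-cell copy number. "Reads within ecDNA"
counts fragment records; weighting by the fragments file's support column
is configurable upstream of the signal computation. The count-matrix
simulator's size range defaults to the 50 kb lower bound, the stricter of
the two bounds stated for that protocol.

## Limitations

The simulators do not model mapping ambiguity, GC or Tn5 insertion bias,
doublets, or peak-structured background; detection numbers on them are
upper bounds for real libraries. The gene-score k-means branch is a
deliberately simple surrogate and its absolute accuracy on real mixtures
of near-identical populations (the regime where the dip test fails to
reject) should be validated against direct junction evidence, which is
what the Fisher step is for. The copy-number module performs no
GC/mappability correction and no segmentation; it is a per-cell signal
summary over fixed windows, intentionally anchored to detected ecDNA
boundaries rather than replacing them.

## A worked run

```{r example, eval = FALSE}
library(eccell)

genome <- synthetic_genome(6, 10e6)
set.seed(1)
truth <- simulate_ecdna_structures(genome, n_circles = 10,
                                   size_range = c(150e3, 900e3))
bcs <- sprintf("BC%04d", 1:200)
lib <- simulate_library(truth, genome,
  sim_read_config(background_depth = 4, circle_depth = 20,
                  barcodes = bcs,
                  circle_cells = setNames(rep(list(bcs[1:80]), 10),
                                          vapply(truth, `[[`, "", "id"))))

det <- detect_ecdna(lib, genome)
match_detections(det, truth)$prf

frags <- fragments_from_alignments(lib)
res <- assign_ecdna(frags, lib, det[[1]], whitelist = bcs, seed = 1)
res
```

The same pipeline is exposed on the command line through
`inst/cli/eccell.R` (subcommands `detect`, `assign`, `cnv`,
`simulate-reads`, `simulate-matrix`, `benchmark`).
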