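# eccell

Detection and single-cell assignment of extrachromosomal DNA (ecDNA) from
scATAC-seq.

ecDNA circles carry amplified oncogenes in many cancers (EGFR, PDGFRA,
MDM2/4 and MYC amplifications in glioblastoma are classic examples) and
drive tumour heterogeneity because their copy number varies wildly between
cells. A single-cell ATAC-seq library sees ecDNA twice: as a strongly
enriched, continuous accessibility signal over the circle's genomic
footprint, and as discordant / soft-clipped read pairs at the ligation
junctions that reveal the circular structure. `eccell` turns both signals
into calls, for bioinformaticians analysing barcoded scATAC libraries of
tumour samples:

1. **Pseudo-bulk detection** — pool all cells; call amplified segments
   from binned coverage (threshold `max(5, 2 × median depth)`); cluster
   discordant pairs into breakpoint junctions and sharpen them with clip
   positions; assemble circular candidates as alternating cycles in the
   breakpoint graph; retain candidates with size 10 kb–20 Mb,
   `depth_mean > 5` and `high_coverage > 0.1`.
2. **Per-cell assignment** — for each candidate compute, per cell,

   `log2(ecCPM_i) = log2((reads in ecDNA_i + 1) / total reads_i × 1e6)`,

   test the distribution for multimodality (Hartigan's dip, Monte-Carlo
   p-value), fit `w·N(μ₁,σ₁²) + (1−w)·N(μ₂,σ₂²)` by EM when bimodal and
   call cells in the higher-mean component ecDNA⁺ (k-means on a gene-score
   matrix when unimodal), then validate against cells carrying their own
   discordant junction reads with a one-sided Fisher's exact test.

The package ships the two simulation protocols used to benchmark the
method — read-level circular-amplicon libraries over a ~4× background, and
bin-by-cell Poisson count matrices `X ~ Poisson(0.5·C·λ)` with group-wise
copy-ratio amplification — plus a 5 Mb / 1 Mb sliding-window per-cell
copy-number estimator, so everything is testable offline.

## Worked example

Plant ten circles on a synthetic mini-genome, simulate the barcoded
library (80 of 200 cells carry the circles), detect, and assign:

```r
library(eccell)

genome <- synthetic_genome(6, 10e6)
set.seed(1)
truth <- simulate_ecdna_structures(genome, n_circles = 10,
                                   size_range = c(150e3, 900e3))
bcs <- sprintf("BC%04d", 1:200)
lib <- simulate_library(truth, genome,
  sim_read_config(background_depth = 4, circle_depth = 20, barcodes = bcs,
                  circle_cells = setNames(rep(list(bcs[1:80]), 10),
                                          vapply(truth, `[[`, "", "id"))))

det <- detect_ecdna(lib, genome)
det[[1]]
#> <ecdna_candidate ecdna_1> 2 segment(s), 387,204 bp
#>   chr1:2874465-3084165:+ | chr4:3264945-3442449:+
#>   depth_mean=23.95 high_coverage=0.999 junctions=2

match_detections(det, truth)$prf
#>   tp fp fn precision recall f1
#> 1 10  0  0         1      1  1

frags <- fragments_from_alignments(lib)
assign_ecdna(frags, lib, det[[1]], whitelist = bcs, seed = 1)
#> ecDNA assignment over 200 cells: 80 ecDNA+ / 120 ecDNA- (gmm)
#>   dip p = 0; Fisher p = 5.021e-34, OR = Inf; 60 gold cells
```

All ten planted circles are recovered with exact junction breakpoints
(clip refinement is base-precise on clean reads), and the mixture model
labels exactly the 80 carrier cells; the 60 gold-standard cells are the
subset with junction-spanning reads of their own, and the Fisher test
confirms the enrichment.

A thin command-line wrapper over the same functions lives in
`inst/cli/eccell.R` (subcommands `detect`, `assign`, `cnv`,
`simulate-reads`, `simulate-matrix`, `benchmark`).

The methods vignette (`vignettes/ecdna-single-cell.Rmd`) documents the
model, the tunable parameters, what the simulators do and do not emulate,
and the numerical choices.

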