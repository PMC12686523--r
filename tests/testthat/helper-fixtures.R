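# Shared fixtures, built in code at test time.

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

tiny_genome <- function(n = 3, len = 4e6) synthetic_genome(n, len)

# a small planted-circle library plus its truth
tiny_library <- function(seed = 3, n_circles = 2, circle_depth = 15,
                         genome = tiny_genome(), barcodes = NULL,
                         circle_cells = NULL, size_range = c(150e3, 300e3),
                         max_segments = 2) {
  set.seed(seed)
  truth <- simulate_ecdna_structures(genome, n_circles = n_circles,
                                     size_range = size_range,
                                     max_segments = max_segments)
  cfg <- sim_read_config(background_depth = 4, circle_depth = circle_depth,
                         barcodes = if (is.null(barcodes))
                           sprintf("BC%04d", 1:200) else barcodes,
                         circle_cells = circle_cells)
  lib <- simulate_library(truth, genome, cfg)
  list(genome = genome, truth = truth, lib = lib, cfg = cfg)
}

# hand-built alignment record rows (0-based half-open)
aln_row <- function(qname, chrom, pos, end, strand = "+", mchrom = NA,
                    mpos = NA, mstrand = "+", tlen = 0L, clip_left = 0L,
                    clip_right = 0L, barcode = NA_character_,
                    first = TRUE) {
  data.table::data.table(
    qname = as.integer(qname), first = first, chrom = chrom,
    pos = as.integer(pos), end = as.integer(end), strand = strand,
    clip_left = as.integer(clip_left), clip_right = as.integer(clip_right),
    mchrom = mchrom, mpos = as.integer(mpos), mstrand = mstrand,
    tlen = as.integer(tlen), barcode = barcode, secondary = FALSE)
}

# a discordant read pair spanning a head-to-tail junction at (c1,p1)->(c2,p2)
disc_pair <- function(qname, c1, p1, c2, p2, rl = 50,
                      barcode = NA_character_) {
  rbind(
    aln_row(qname, c1, p1 - rl, p1, "+", mchrom = c2, mpos = p2,
            mstrand = "-", tlen = 0L, barcode = barcode, first = TRUE),
    aln_row(qname, c2, p2, p2 + rl, "-", mchrom = c1, mpos = p1 - rl,
            mstrand = "+", tlen = 0L, barcode = barcode, first = FALSE)
  )
}
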