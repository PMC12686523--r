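#' Synthetic mini-genome specification
#'
#' A genome is a named numeric vector of chromosome lengths (bp). The
#' simulators run against a small multi-chromosome synthetic genome so that
#' whole pipeline benchmarks need no external reference; every size in the
#' simulation protocol scales with the genome.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome in bp (recycled).
#' @return named numeric vector of chromosome lengths.
#' @examples
#' synthetic_genome(4, 30e6)
#' @export
synthetic_genome <- function(n_chroms = 4, chrom_length = 30e6) {
  stopifnot(n_chroms >= 1, all(chrom_length > 0))
  len <- rep_len(chrom_length, n_chroms)
  stats::setNames(as.numeric(len), paste0("chr", seq_len(n_chroms)))
}

#' Read / write a chrom.sizes file
#' @param genome named numeric vector of chromosome lengths.
#' @param path file path (two tab-separated columns: name, length).
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(data.frame(names(genome), as.integer(genome)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_chrom_sizes
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), tab[[1]])
}

#' Write a random-sequence FASTA for a synthetic genome
#'
#' Generates i.i.d. uniform A/C/G/T sequence per chromosome (seeded by the
#' caller via [set.seed()]). Only needed for optional end-to-end runs
#' through a real aligner; the pipeline itself never requires sequence.
#'
#' @param genome named numeric vector of chromosome lengths.
#' @param path output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required to write FASTA")
  seqs <- Biostrings::DNAStringSet(vapply(genome, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1)))
  names(seqs) <- names(genome)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
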