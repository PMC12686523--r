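#' Alignment record tables
#'
#' The detector and the simulators exchange alignments as a `data.table`
#' with one row per read and 0-based half-open coordinates:
#'
#' * `qname` read-pair name; `first` logical, TRUE for read 1
#' * `chrom`, `pos`, `end`, `strand` aligned reference span
#' * `clip_left`, `clip_right` soft-clipped bases at either end of the
#'   alignment (clip position = `pos` resp. `end`)
#' * `mchrom`, `mpos`, `mstrand` mate position, `tlen` template length
#' * `barcode` cell barcode (`CB` tag), NA when absent
#' * `secondary` TRUE for secondary/supplementary records
#'
#' `read_alignments()` fills this table from a BAM (or SAM, converted via
#' [Rsamtools::asBam()]) file; the read-level simulator emits it directly.
#'
#' @param path BAM or SAM file.
#' @return a `data.table` of alignment records, coordinate-sorted.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path)) {
    bam <- Rsamtools::asBam(path, sub("\\.sam$", "", path),
                            overwrite = TRUE, indexDestination = TRUE)
    path <- bam
  }
  what <- c("qname", "flag", "rname", "strand", "pos", "cigar",
            "mrnm", "mpos", "isize", "mapq")
  p <- Rsamtools::ScanBamParam(what = what, tag = "CB")
  res <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(res$pos)
  cig <- res$cigar[keep]
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  clips <- cigar_soft_clips(cig)
  flag <- res$flag[keep]
  qn <- res$qname[keep]
  aln <- data.table::data.table(
    qname = match(qn, unique(qn)),  # compact integer pair ids
    first = bitwAnd(flag, 64L) > 0L,
    chrom = as.character(res$rname[keep]),
    pos = res$pos[keep] - 1,
    end = res$pos[keep] - 1 + width,
    strand = as.character(res$strand[keep]),
    cigar = cig,
    clip_left = clips$left,
    clip_right = clips$right,
    mchrom = as.character(res$mrnm[keep]),
    mpos = res$mpos[keep] - 1,
    mstrand = ifelse(bitwAnd(flag, 32L) > 0L, "-", "+"),
    tlen = res$isize[keep],
    barcode = if (is.null(res$tag$CB)) NA_character_ else res$tag$CB[keep],
    secondary = bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  )
  data.table::setorder(aln, chrom, pos)
  aln[]
}

cigar_soft_clips <- function(cigar) {
  left <- integer(length(cigar))
  right <- integer(length(cigar))
  ml <- regmatches(cigar, regexpr("^[0-9]+S", cigar))
  hasl <- grepl("^[0-9]+S", cigar)
  left[hasl] <- as.integer(sub("S", "", ml))
  mr <- regmatches(cigar, regexpr("[0-9]+S$", cigar))
  hasr <- grepl("[0-9]+S$", cigar)
  right[hasr] <- as.integer(sub("S", "", mr))
  list(left = left, right = right)
}

#' Write alignment records to a SAM file
#'
#' Emits a minimal coordinate-sorted SAM (no sequence/quality strings) with
#' `CB` barcode tags, suitable for conversion to BAM with
#' [Rsamtools::asBam()] or samtools.
#'
#' @param aln alignment record table (see [read_alignments()]).
#' @param genome named numeric vector of chromosome lengths for the header.
#' @param path output `.sam` path.
#' @export
write_sam <- function(aln, genome, path) {
  aln <- data.table::as.data.table(aln)
  data.table::setorder(aln, chrom, pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                       as.integer(genome))), con)
  if (nrow(aln) == 0L) return(invisible(path))
  paired <- !is.na(aln$mchrom)
  flag <- 0L +
    ifelse(paired, 1L, 0L) +
    ifelse(aln$strand == "-", 16L, 0L) +
    ifelse(paired & aln$mstrand == "-", 32L, 0L) +
    ifelse(paired & aln$first, 64L, 0L) +
    ifelse(paired & !aln$first, 128L, 0L) +
    ifelse(aln$secondary, 256L, 0L)
  cigar <- if ("cigar" %in% names(aln)) aln$cigar else {
    m <- as.integer(aln$end - aln$pos)
    paste0(ifelse(aln$clip_left > 0, paste0(aln$clip_left, "S"), ""),
           m, "M",
           ifelse(aln$clip_right > 0, paste0(aln$clip_right, "S"), ""))
  }
  rnext <- ifelse(!paired, "*",
                  ifelse(aln$mchrom == aln$chrom, "=", aln$mchrom))
  qn <- if (is.numeric(aln$qname)) paste0("r", aln$qname) else aln$qname
  lines <- paste(qn, flag, aln$chrom, format(aln$pos + 1,
                                                    scientific = FALSE,
                                                    trim = TRUE),
                 60L, cigar, rnext,
                 ifelse(paired, format(aln$mpos + 1, scientific = FALSE,
                                       trim = TRUE), "0"),
                 ifelse(paired & !is.na(aln$tlen),
                        format(aln$tlen, scientific = FALSE, trim = TRUE),
                        "0"),
                 "*", "*",
                 sep = "\t")
  hasbc <- !is.na(aln$barcode)
  lines[hasbc] <- paste0(lines[hasbc], "\tCB:Z:", aln$barcode[hasbc])
  writeLines(lines, con)
  invisible(path)
}

#' Derive a fragments table from paired alignment records
#'
#' Concordant pairs yield one fragment spanning the outer ends of the two
#' reads; discordant pairs (which span a structural junction) contribute one
#' record per read covering just its aligned span.
#'
#' @param aln alignment record table.
#' @return `data.table` with columns `chrom`, `start`, `end`, `barcode`,
#'   `support` (all 1), BED-like 0-based half-open.
#' @export
fragments_from_alignments <- function(aln) {
  aln <- data.table::as.data.table(aln)[secondary == FALSE]
  disc <- classify_discordant(aln, insert_cutoff = 1000)
  conc <- aln[!disc & !is.na(mchrom)]
  frag_c <- if (nrow(conc)) conc[, .(chrom = chrom[1], start = min(pos),
                                     end = max(end), barcode = barcode[1]),
                                 by = qname]
            else data.table::data.table(qname = integer(),
                                        chrom = character(),
                                        start = integer(), end = integer(),
                                        barcode = character())
  frag_d <- aln[disc | is.na(mchrom),
                .(chrom, start = pos, end = end, barcode)]
  frags <- rbind(frag_c[, .(chrom, start, end, barcode)], frag_d)
  frags[, support := 1L]
  data.table::setorder(frags, chrom, start)
  frags[]
}

#' Read / write 10x-style fragments files
#'
#' Five tab-separated columns without header: chrom, start, end, barcode,
#' support; 0-based half-open. Plain or gzip-compressed TSV.
#'
#' @param path fragments file path (`.tsv` or `.tsv.gz`).
#' @export
read_fragments <- function(path) {
  if (grepl("\\.gz$", path)) {
    tab <- utils::read.table(gzfile(path), sep = "\t",
                             col.names = c("chrom", "start", "end",
                                           "barcode", "support"),
                             colClasses = c("character", "integer",
                                            "integer", "character",
                                            "integer"))
    frags <- data.table::as.data.table(tab)
  } else {
    frags <- data.table::fread(path, header = FALSE,
                               col.names = c("chrom", "start", "end",
                                             "barcode", "support"))
  }
  frags[]
}

#' @rdname read_fragments
#' @param fragments fragments `data.table`.
#' @export
write_fragments <- function(fragments, path) {
  out <- data.table::as.data.table(fragments)[
    , .(chrom, start = as.integer(start), end = as.integer(end), barcode,
        support = as.integer(support))]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
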