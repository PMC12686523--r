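#' Genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`.
#' Coordinates are 0-based half-open throughout the package (the convention
#' of BED and 10x fragments files); SAM records (1-based) and printed
#' 1-based-inclusive intervals are converted at I/O boundaries.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open; `0 <= start < end`.
#' @return A data frame with class `gintervals`.
#' @examples
#' gintervals("chr1", 0, 1000)
#' @export
gintervals <- function(chrom, start, end) {
  x <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    stringsAsFactors = FALSE
  )
  validate_gintervals(x)
  class(x) <- c("gintervals", "data.frame")
  x
}

validate_gintervals <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(!is.finite(x$start)) || any(!is.finite(x$end)))
    stop("interval coordinates must be finite")
  if (any(x$start < 0)) stop("interval start must be >= 0")
  if (any(x$end <= x$start)) stop("intervals must satisfy start < end")
  invisible(x)
}

#' Total size of a set of intervals in bp
#' @param x interval data frame (`chrom`, `start`, `end`).
#' @return numeric scalar, sum of `end - start`.
#' @export
gi_size <- function(x) {
  if (nrow(x) == 0L) return(0)
  sum(x$end - x$start)
}

## 0-based half-open <-> GRanges (1-based closed)
gi_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

gr_to_gi <- function(gr) {
  x <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  class(x) <- c("gintervals", "data.frame")
  x
}

#' Merge intervals closer than a maximum gap
#'
#' Intervals on the same chromosome whose gap is at most `max_gap` bp are
#' merged (overlapping or book-ended intervals always merge). The output is
#' sorted by chromosome then start and the union of the output covers the
#' union of the input.
#'
#' @param x interval data frame.
#' @param max_gap non-negative gap in bp below or at which to merge.
#' @return merged, sorted interval data frame.
#' @export
merge_intervals <- function(x, max_gap = 0) {
  stopifnot(max_gap >= 0)
  if (nrow(x) == 0L) return(gintervals(character(), numeric(), numeric()))
  validate_gintervals(x)
  gr <- GenomicRanges::reduce(gi_to_gr(x), min.gapwidth = max_gap + 1)
  out <- gr_to_gi(GenomicRanges::sort(gr))
  out
}

#' Reciprocal overlap between two interval sets
#'
#' Computes `min(|a n b| / |a|, |a n b| / |b|)` where `|.|` is total bp after
#' normalising each set (merging internal overlaps). Symmetric in its
#' arguments; used to match detected ecDNA candidates against planted truth.
#'
#' @param a,b non-empty interval data frames.
#' @return fraction in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("reciprocal_overlap requires non-empty interval sets")
  ga <- GenomicRanges::reduce(gi_to_gr(a))
  gb <- GenomicRanges::reduce(gi_to_gr(b))
  ## suppress seqlevel-mismatch warnings for disjoint chromosome sets
  ov <- sum(GenomicRanges::width(suppressWarnings(
    GenomicRanges::intersect(ga, gb, ignore.strand = TRUE))))
  min(ov / sum(GenomicRanges::width(ga)), ov / sum(GenomicRanges::width(gb)))
}

## GRanges overlap helpers that tolerate disjoint seqlevel sets quietly
quiet_count_overlaps <- function(query, subject) {
  suppressWarnings(GenomicRanges::countOverlaps(query, subject))
}

quiet_find_overlaps <- function(query, subject) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject))
}
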