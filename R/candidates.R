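#' Breakpoint junctions
#'
#' A junction joins two breakends. Each breakend is a (chrom, pos, side)
#' triple; `side = "right"` means the amplified segment continues to the
#' left of `pos` (the breakpoint sits at a segment's 3' end on the forward
#' strand), `side = "left"` the mirror case. Breakends are stored in
#' canonical order (lexicographic by chrom, then position, then side) so
#' that equality between junctions is well defined.
#'
#' @param chrom_a,pos_a,side_a first breakend (`side` in `left`/`right`).
#' @param chrom_b,pos_b,side_b second breakend.
#' @param discordant_support number of supporting discordant read pairs.
#' @param clip_support number of supporting clipped reads.
#' @return data frame with class `bp_junctions`, breakends canonicalised.
#' @export
bp_junctions <- function(chrom_a, pos_a, side_a, chrom_b, pos_b, side_b,
                         discordant_support = 0L, clip_support = 0L) {
  x <- data.frame(
    chrom_a = as.character(chrom_a), pos_a = as.numeric(pos_a),
    side_a = as.character(side_a),
    chrom_b = as.character(chrom_b), pos_b = as.numeric(pos_b),
    side_b = as.character(side_b),
    discordant_support = as.integer(discordant_support),
    clip_support = as.integer(clip_support),
    stringsAsFactors = FALSE
  )
  canonicalize_junctions(x)
}

empty_junctions <- function() {
  bp_junctions(character(), numeric(), character(),
               character(), numeric(), character(), integer(), integer())
}

canonicalize_junctions <- function(x) {
  stopifnot(all(x$side_a %in% c("left", "right")),
            all(x$side_b %in% c("left", "right")),
            all(x$discordant_support >= 0), all(x$clip_support >= 0))
  flip <- (x$chrom_a > x$chrom_b) |
    (x$chrom_a == x$chrom_b & x$pos_a > x$pos_b) |
    (x$chrom_a == x$chrom_b & x$pos_a == x$pos_b & x$side_a > x$side_b)
  if (any(flip)) {
    tmp <- x[flip, c("chrom_a", "pos_a", "side_a")]
    x[flip, c("chrom_a", "pos_a", "side_a")] <-
      x[flip, c("chrom_b", "pos_b", "side_b")]
    x[flip, c("chrom_b", "pos_b", "side_b")] <- tmp
  }
  rownames(x) <- NULL
  class(x) <- c("bp_junctions", "data.frame")
  x
}

#' ecDNA candidate
#'
#' An ordered cyclic list of oriented genomic segments plus the breakpoint
#' junctions closing the cycle, with the pseudo-bulk QC statistics used by
#' the published retention filter (size within bounds, `depth_mean > 5`,
#' `high_coverage > 0.1`).
#'
#' @param id candidate label.
#' @param segments data frame `chrom`, `start`, `end`, `strand`
#'   (`+` forward / `-` reverse), in cycle order.
#' @param junctions `bp_junctions` data frame; one junction per segment
#'   (a cycle).
#' @param depth_mean mean per-base depth over the segments.
#' @param high_coverage fraction in `[0, 1]` of segment bases at or above
#'   the amplified-depth cutoff.
#' @return object of class `ecdna_candidate`.
#' @export
ecdna_candidate <- function(id, segments, junctions,
                            depth_mean = NA_real_, high_coverage = NA_real_) {
  validate_gintervals(segments)
  stopifnot(nrow(segments) >= 1L, all(segments$strand %in% c("+", "-")))
  if (!is.null(junctions) && nrow(junctions) > 0L)
    junctions <- canonicalize_junctions(as.data.frame(junctions))
  else junctions <- empty_junctions()
  if (!is.na(high_coverage))
    stopifnot(high_coverage >= 0, high_coverage <= 1)
  if (!is.na(depth_mean)) stopifnot(depth_mean >= 0)
  structure(list(
    id = as.character(id),
    segments = segments,
    junctions = junctions,
    size = gi_size(segments),
    depth_mean = as.numeric(depth_mean),
    high_coverage = as.numeric(high_coverage)
  ), class = "ecdna_candidate")
}

#' @export
print.ecdna_candidate <- function(x, ...) {
  segs <- sprintf("%s:%d-%d:%s", x$segments$chrom, x$segments$start,
                  x$segments$end, x$segments$strand)
  cat(sprintf("<ecdna_candidate %s> %d segment(s), %s bp\n", x$id,
              nrow(x$segments), format(x$size, big.mark = ",")))
  cat("  ", paste(segs, collapse = " | "), "\n", sep = "")
  cat(sprintf("  depth_mean=%.2f high_coverage=%.3f junctions=%d\n",
              x$depth_mean, x$high_coverage, nrow(x$junctions)))
  invisible(x)
}

candidate_segment_string <- function(cand) {
  paste(sprintf("%s:%d-%d:%s", cand$segments$chrom,
                as.integer(cand$segments$start),
                as.integer(cand$segments$end), cand$segments$strand),
        collapse = ",")
}

#' Write / read candidate tables
#'
#' The candidate TSV has one row per candidate with columns `id`,
#' `n_segments`, `segments` (comma-joined `chrom:start-end:strand`, 0-based
#' half-open), `size`, `depth_mean`, `high_coverage`,
#' `discordant_support_total`. The BED file has one line per segment with
#' the candidate id in the name field.
#'
#' @param candidates list of [ecdna_candidate()] objects.
#' @param path output file path.
#' @return `write_*` return `path` invisibly; `read_candidates_tsv` returns
#'   a list of `ecdna_candidate` objects (without junction detail).
#' @export
write_candidates_tsv <- function(candidates, path) {
  rows <- lapply(candidates, function(cand) {
    data.frame(
      id = cand$id,
      n_segments = nrow(cand$segments),
      segments = candidate_segment_string(cand),
      size = cand$size,
      depth_mean = cand$depth_mean,
      high_coverage = cand$high_coverage,
      discordant_support_total = sum(cand$junctions$discordant_support),
      stringsAsFactors = FALSE
    )
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), n_segments = integer(),
               segments = character(), size = numeric(),
               depth_mean = numeric(), high_coverage = numeric(),
               discordant_support_total = integer())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates_tsv
#' @export
read_candidates_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(segments = "character"))
  lapply(seq_len(nrow(tab)), function(i) {
    parts <- strsplit(strsplit(tab$segments[i], ",", fixed = TRUE)[[1]], ":")
    segs <- do.call(rbind, lapply(parts, function(p) {
      se <- as.numeric(strsplit(p[2], "-", fixed = TRUE)[[1]])
      data.frame(chrom = p[1], start = se[1], end = se[2], strand = p[3],
                 stringsAsFactors = FALSE)
    }))
    ecdna_candidate(tab$id[i], segs, NULL,
                    depth_mean = tab$depth_mean[i],
                    high_coverage = tab$high_coverage[i])
  })
}

#' @rdname write_candidates_tsv
#' @export
write_candidates_bed <- function(candidates, path) {
  rows <- lapply(candidates, function(cand)
    data.frame(chrom = cand$segments$chrom,
               start = as.integer(cand$segments$start),
               end = as.integer(cand$segments$end),
               name = cand$id, score = 0L, strand = cand$segments$strand,
               stringsAsFactors = FALSE))
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), score = integer(), strand = character())
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-junction TSV
#' @param junctions `bp_junctions` data frame.
#' @param path output file path.
#' @export
write_junctions_tsv <- function(junctions, path) {
  utils::write.table(as.data.frame(junctions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Union of a candidate's segments as plain intervals
#' @param cand an `ecdna_candidate`.
#' @return merged interval data frame.
#' @export
candidate_intervals <- function(cand) {
  merge_intervals(cand$segments[, c("chrom", "start", "end")], max_gap = 0)
}
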