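#' Simulate random circular amplicon structures
#'
#' Draws `n_circles` circular amplicons whose total sizes are uniform in
#' `size_range`, each composed of 1..`max_segments` segments at random
#' genomic positions with random ligation directions, ligated sequentially
#' into one circular sequence. Segments are placed without overlap between
#' circles (separated by at least `min_separation`) so that the planted
#' truth stays well-defined on a small genome.
#'
#' @param genome named numeric vector of chromosome lengths.
#' @param n_circles number of circles.
#' @param size_range circle total size bounds, bp.
#' @param max_segments maximum segments per circle.
#' @param min_separation minimum distance between segments of different
#'   circles, bp.
#' @param seed optional seed.
#' @return list of [ecdna_candidate()] truth objects (ids `circle_<i>`),
#'   each with its cycle-closing junctions.
#' @export
simulate_ecdna_structures <- function(genome, n_circles = 100,
                                      size_range = c(500e3, 10e6),
                                      max_segments = 4,
                                      min_separation = 50e3, seed = NULL) {
  stopifnot(size_range[1] < size_range[2], n_circles >= 0)
  if (size_range[2] > max(genome))
    stop("size_range exceeds the longest chromosome")
  if (!is.null(seed)) set.seed(seed)
  if (n_circles == 0) return(list())
  occupied <- gintervals(character(), numeric(), numeric())
  place_segment <- function(len) {
    for (try in 1:500) {
      chr <- sample(names(genome), 1, prob = genome)
      if (genome[[chr]] <= len + 2) next
      start <- floor(stats::runif(1, 0, genome[[chr]] - len))
      cand <- gintervals(chr, start, start + len)
      grown <- gintervals(chr, max(0, start - min_separation),
                          start + len + min_separation)
      if (nrow(occupied) == 0L ||
          sum(quiet_count_overlaps(gi_to_gr(grown),
                                           gi_to_gr(occupied))) == 0) {
        occupied <<- rbind(occupied, cand)
        return(cand)
      }
    }
    stop("could not place segment: genome too crowded for the requested ",
         "number/size of circles")
  }
  lapply(seq_len(n_circles), function(i) {
    total <- stats::runif(1, size_range[1], size_range[2])
    n_seg <- sample.int(max_segments, 1)
    ## segment sizes: proportions with a floor so no sliver segments
    prop <- stats::runif(n_seg, 0.5, 1)
    sizes <- round(total * prop / sum(prop))
    segs <- do.call(rbind, lapply(sizes, place_segment))
    segs$strand <- sample(c("+", "-"), n_seg, replace = TRUE)
    ## junction k joins the exit end of segment k to the entry end of k+1
    exit_pos <- ifelse(segs$strand == "+", segs$end, segs$start)
    exit_side <- ifelse(segs$strand == "+", "right", "left")
    entry_pos <- ifelse(segs$strand == "+", segs$start, segs$end)
    entry_side <- ifelse(segs$strand == "+", "left", "right")
    nxt <- c(seq_len(n_seg)[-1], 1L)
    jx <- bp_junctions(segs$chrom, exit_pos, exit_side,
                       segs$chrom[nxt], entry_pos[nxt], entry_side[nxt])
    ecdna_candidate(sprintf("circle_%d", i), segs, jx)
  })
}

#' Read-simulation configuration
#'
#' @param read_length read length, bp.
#' @param insert_mean,insert_sd template length distribution, bp.
#' @param background_depth mean genome-wide depth of the background
#'   library (the pseudo-bulk accessibility background).
#' @param circle_depth additional local depth over each circle; scalar or
#'   one value per circle.
#' @param barcodes cell barcode pool for background reads.
#' @param circle_cells named list (circle id -> barcodes) of the cells
#'   carrying each circle; defaults to the whole pool.
#' @param chimera_rate fraction of background pairs turned into random
#'   chimeric (artifact) pairs.
#' @return list with class `sim_read_config`.
#' @export
sim_read_config <- function(read_length = 50, insert_mean = 300,
                            insert_sd = 50, background_depth = 4,
                            circle_depth = 20,
                            barcodes = sprintf("BC%04d", 1:200),
                            circle_cells = NULL, chimera_rate = 1e-6) {
  stopifnot(read_length >= 20, background_depth >= 0, all(circle_depth >= 0),
            insert_mean > 2 * read_length)
  structure(list(read_length = read_length, insert_mean = insert_mean,
                 insert_sd = insert_sd, background_depth = background_depth,
                 circle_depth = circle_depth, barcodes = barcodes,
                 circle_cells = circle_cells, chimera_rate = chimera_rate),
            class = "sim_read_config")
}

## map circle coordinates [a, b) to reference pieces through the oriented
## segment list; returns data.frame of pieces in read order
project_circle_interval <- function(a, b, segs, cum) {
  L <- cum[length(cum)]
  pieces <- list()
  while (a < b) {
    ca <- a %% L
    si <- findInterval(ca, cum, rightmost.closed = FALSE)  # 1..n_seg
    seg_lo <- cum[si]
    seg_hi <- cum[si + 1]
    take <- min(b - a, seg_hi - ca)
    off <- ca - seg_lo
    if (segs$strand[si] == "+") {
      ref_start <- segs$start[si] + off
      pieces[[length(pieces) + 1L]] <-
        data.frame(chrom = segs$chrom[si], start = ref_start,
                   end = ref_start + take, strand = "+", len = take)
    } else {
      ref_end <- segs$end[si] - off
      pieces[[length(pieces) + 1L]] <-
        data.frame(chrom = segs$chrom[si], start = ref_end - take,
                   end = ref_end, strand = "-", len = take)
    }
    a <- a + take
  }
  do.call(rbind, pieces)
}

## one aligned record from a read interval on the circle; the largest piece
## aligns, the remainder becomes soft clips at the junction side
record_from_pieces <- function(pieces, flip_strand) {
  main <- which.max(pieces$len)
  before <- if (main > 1) sum(pieces$len[seq_len(main - 1)]) else 0L
  after <- sum(pieces$len) - pieces$len[main] - before
  strand <- pieces$strand[main]
  if (flip_strand) strand <- if (strand == "+") "-" else "+"
  ## bases earlier in circle order sit at the piece's start for a forward
  ## projection (left clip) and at its end for a reverse projection
  if (pieces$strand[main] == "+") {
    clip_left <- before; clip_right <- after
  } else {
    clip_left <- after; clip_right <- before
  }
  list(chrom = pieces$chrom[main], pos = as.integer(pieces$start[main]),
       end = as.integer(pieces$end[main]), strand = strand,
       clip_left = as.integer(clip_left), clip_right = as.integer(clip_right))
}

#' Simulate a barcoded paired-end pseudo-bulk library
#'
#' Background pairs are uniform over the reference at `background_depth`;
#' each circle contributes pairs uniform over its circular sequence at its
#' `circle_depth`, projected back to reference coordinates. Pairs
#' straddling a ligation junction become discordant records; reads crossing
#' a junction are soft-clipped at the exact breakpoint. Reads are
#' error-free and emitted directly as aligned records (a coordinate
#' projection stands in for the align step; [write_sam()] exports them for
#' external tools).
#'
#' @param structures truth circles from [simulate_ecdna_structures()].
#' @param genome named numeric vector of chromosome lengths.
#' @param config [sim_read_config()].
#' @param seed optional seed.
#' @return coordinate-sorted alignment record `data.table` (see
#'   [read_alignments()]); truth structures attached as attribute `truth`.
#' @export
simulate_library <- function(structures, genome, config = sim_read_config(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rl <- config$read_length
  if (length(structures) == 0L && any(config$circle_depth > 0))
    stop("circle_depth > 0 but no circle structures supplied")
  depth <- rep_len(config$circle_depth, length(structures))
  parts <- list()
  pair_id <- 0L  # integer pair ids keep the record table compact
  ## background
  if (config$background_depth > 0) {
    for (chr in names(genome)) {
      len <- genome[[chr]]
      n_pairs <- round(config$background_depth * len / (2 * rl))
      if (n_pairs == 0) next
      ins <- pmax(2 * rl + 2, round(stats::rnorm(n_pairs,
                                                 config$insert_mean,
                                                 config$insert_sd)))
      start <- floor(stats::runif(n_pairs, 0, pmax(1, len - ins)))
      bc <- sample(config$barcodes, n_pairs, replace = TRUE)
      qn <- pair_id + seq_len(n_pairs); pair_id <- pair_id + n_pairs
      start <- as.integer(start); ins <- as.integer(ins)
      r1 <- data.table::data.table(
        qname = qn, first = TRUE, chrom = chr, pos = start,
        end = start + rl, strand = "+", clip_left = 0L, clip_right = 0L,
        mchrom = chr, mpos = start + ins - rl, mstrand = "-",
        tlen = ins, barcode = bc, secondary = FALSE)
      r2 <- data.table::data.table(
        qname = qn, first = FALSE, chrom = chr, pos = start + ins - rl,
        end = start + ins, strand = "-", clip_left = 0L, clip_right = 0L,
        mchrom = chr, mpos = start, mstrand = "+",
        tlen = -ins, barcode = bc, secondary = FALSE)
      parts[[length(parts) + 1L]] <- rbind(r1, r2)
    }
  }
  ## circles
  for (ci in seq_along(structures)) {
    if (depth[ci] <= 0) next
    circ <- structures[[ci]]
    segs <- circ$segments
    cum <- c(0, cumsum(segs$end - segs$start))
    L <- cum[length(cum)]
    n_pairs <- round(L * depth[ci] / (2 * rl))
    if (n_pairs == 0) next
    pool <- config$circle_cells[[circ$id]]
    if (is.null(pool)) pool <- config$barcodes
    ins <- pmax(2 * rl + 2, round(stats::rnorm(n_pairs, config$insert_mean,
                                               config$insert_sd)))
    ins <- pmin(ins, L - 2)
    s <- floor(stats::runif(n_pairs, 0, L))
    bc <- sample(pool, n_pairs, replace = TRUE)
    ## vectorised projection for reads inside one segment; explicit piece
    ## splitting only for the rare junction-crossing reads
    proj_reads <- function(a, flip) {
      am <- a %% L
      si <- findInterval(am, cum, rightmost.closed = FALSE)
      cross <- (am + rl) > cum[si + 1L]
      off <- am - cum[si]
      fwd <- segs$strand[si] == "+"
      pos <- as.integer(ifelse(fwd, segs$start[si] + off,
                               segs$end[si] - off - rl))
      strand <- if (flip) ifelse(fwd, "-", "+") else ifelse(fwd, "+", "-")
      out <- data.table::data.table(
        chrom = segs$chrom[si], pos = pos, end = pos + rl, strand = strand,
        clip_left = 0L, clip_right = 0L)
      for (i in which(cross)) {
        p <- project_circle_interval(am[i], am[i] + rl, segs, cum)
        r <- record_from_pieces(p, flip_strand = flip)
        data.table::set(out, i, names(out),
                        list(r$chrom, r$pos, r$end, r$strand,
                             r$clip_left, r$clip_right))
      }
      out
    }
    a1 <- proj_reads(s, flip = FALSE)
    a2 <- proj_reads(s + ins - rl, flip = TRUE)
    same <- a1$chrom == a2$chrom
    tl <- as.integer(ifelse(same, pmax(a1$end, a2$end) - pmin(a1$pos, a2$pos),
                            0))
    qn <- pair_id + seq_len(n_pairs); pair_id <- pair_id + n_pairs
    r1 <- data.table::data.table(
      qname = qn, first = TRUE, chrom = a1$chrom, pos = a1$pos,
      end = a1$end, strand = a1$strand, clip_left = a1$clip_left,
      clip_right = a1$clip_right, mchrom = a2$chrom, mpos = a2$pos,
      mstrand = a2$strand, tlen = ifelse(a1$pos <= a2$pos, tl, -tl),
      barcode = bc, secondary = FALSE)
    r2 <- data.table::data.table(
      qname = qn, first = FALSE, chrom = a2$chrom, pos = a2$pos,
      end = a2$end, strand = a2$strand, clip_left = a2$clip_left,
      clip_right = a2$clip_right, mchrom = a1$chrom, mpos = a1$pos,
      mstrand = a1$strand, tlen = ifelse(a2$pos < a1$pos, tl, -tl),
      barcode = bc, secondary = FALSE)
    parts[[length(parts) + 1L]] <- rbind(r1, r2)
  }
  if (length(parts) == 0L) {
    aln <- data.table::data.table(
      qname = integer(), first = logical(), chrom = character(),
      pos = integer(), end = integer(), strand = character(),
      clip_left = integer(), clip_right = integer(), mchrom = character(),
      mpos = integer(), mstrand = character(), tlen = integer(),
      barcode = character(), secondary = logical())
  } else {
    aln <- data.table::rbindlist(parts)
  }
  ## rare chimeric artifacts
  n_chim <- stats::rbinom(1, max(0, nrow(aln) %/% 2L), config$chimera_rate)
  if (n_chim > 0) {
    chr1 <- sample(names(genome), n_chim, replace = TRUE)
    chr2 <- sample(names(genome), n_chim, replace = TRUE)
    p1 <- as.integer(floor(stats::runif(n_chim, 0, genome[chr1] - rl)))
    p2 <- as.integer(floor(stats::runif(n_chim, 0, genome[chr2] - rl)))
    bc <- sample(config$barcodes, n_chim, replace = TRUE)
    qn <- pair_id + seq_len(n_chim); pair_id <- pair_id + n_chim
    aln <- rbind(aln, data.table::data.table(
      qname = rep(qn, 2), first = c(rep(TRUE, n_chim), rep(FALSE, n_chim)),
      chrom = c(chr1, chr2), pos = c(p1, p2), end = c(p1, p2) + rl,
      strand = "+", clip_left = 0L, clip_right = 0L,
      mchrom = c(chr2, chr1), mpos = c(p2, p1), mstrand = "+",
      tlen = 0L, barcode = rep(bc, 2), secondary = FALSE))
  }
  data.table::setorder(aln, chrom, pos)
  data.table::setattr(aln, "truth", structures)
  aln[]
}
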