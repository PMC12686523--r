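#' Detector configuration
#'
#' Tuning parameters of the pseudo-bulk ecDNA detector. Defaults follow the
#' published retention filter (sizes 10 kb - 20 Mb, `depth_mean > 5`,
#' `high_coverage > 0.1`) and the default 64 Mb genome chunk; the remaining
#' knobs are this package's documented choices (see the methods vignette).
#'
#' @param chunk_size genome chunk processed at a time, bp.
#' @param bin_size coverage bin, bp.
#' @param depth_floor absolute depth floor for amplified-segment calling.
#' @param enrich_factor relative enrichment over the global median depth.
#' @param merge_gap segments closer than this merge, bp.
#' @param insert_cutoff template length above which a pair is discordant, bp.
#' @param cluster_window clustering window for discordant breakends, bp.
#' @param snap_window window for snapping junction breakends to amplified
#'   segment ends, bp (wider than `cluster_window` because coverage-derived
#'   segment ends are quantised to `bin_size`).
#' @param min_discordant_support minimum read pairs per junction.
#' @param max_segments_per_circle cycle length cap during assembly.
#' @param size_min,size_max candidate size bounds, bp.
#' @param min_depth_mean candidate retained iff `depth_mean >` this.
#' @param min_high_coverage candidate retained iff `high_coverage >` this.
#' @return list with class `detector_config`.
#' @export
detector_config <- function(chunk_size = 64e6, bin_size = 1000,
                            depth_floor = 5, enrich_factor = 2,
                            merge_gap = 10e3, insert_cutoff = 1000,
                            cluster_window = 500, snap_window = 2000,
                            min_discordant_support = 3,
                            max_segments_per_circle = 10,
                            size_min = 10e3, size_max = 20e6,
                            min_depth_mean = 5, min_high_coverage = 0.1) {
  cfg <- list(chunk_size = chunk_size, bin_size = bin_size,
              depth_floor = depth_floor, enrich_factor = enrich_factor,
              merge_gap = merge_gap, insert_cutoff = insert_cutoff,
              cluster_window = cluster_window, snap_window = snap_window,
              min_discordant_support = min_discordant_support,
              max_segments_per_circle = max_segments_per_circle,
              size_min = size_min, size_max = size_max,
              min_depth_mean = min_depth_mean,
              min_high_coverage = min_high_coverage)
  stopifnot(cfg$size_min < cfg$size_max, cfg$bin_size > 0,
            cfg$chunk_size >= cfg$bin_size, cfg$cluster_window > 0,
            cfg$min_discordant_support >= 1)
  class(cfg) <- "detector_config"
  cfg
}

#' Binned coverage of one chromosome
#'
#' Bin value = (total bp of primary-alignment overlap with the bin) divided
#' by `bin_size`, i.e. mean per-base depth over the bin.
#'
#' @param aln alignment record table (primary records of one library).
#' @param chrom chromosome to profile.
#' @param chrom_length chromosome length, bp.
#' @param config [detector_config()].
#' @return list with class `coverage_track`: `chrom`, `bin_size`, `values`.
#' @export
compute_coverage <- function(aln, chrom, chrom_length, config = detector_config()) {
  if (is.na(chrom_length) || chrom_length <= 0)
    stop("unknown chromosome length for ", chrom)
  B <- config$bin_size
  n_bins <- ceiling(chrom_length / B)
  vals <- numeric(n_bins)
  rec <- data.table::as.data.table(aln)
  if ("chrom" %in% names(rec) && !all(rec$chrom == chrom))
    rec <- rec[chrom, on = "chrom", nomatch = NULL]
  if ("secondary" %in% names(rec) && any(rec$secondary))
    rec <- rec[secondary == FALSE]
  if (nrow(rec) > 0L) {
    if (is.unsorted(rec$pos)) stop("alignment records must be position-sorted")
    pos <- pmax(rec$pos, 0); endp <- pmin(rec$end, chrom_length)
    b0 <- floor(pos / B); b1 <- floor((endp - 1) / B)
    span <- b1 - b0
    ## single-bin reads
    one <- span == 0L
    if (any(one)) {
      agg <- rowsum((endp - pos)[one], b0[one])
      idx <- as.integer(rownames(agg)) + 1L
      vals[idx] <- vals[idx] + agg[, 1]
    }
    multi <- which(span > 0L)
    if (length(multi)) {
      for (i in multi) {
        bins <- b0[i]:b1[i]
        ov <- pmin(endp[i], (bins + 1) * B) - pmax(pos[i], bins * B)
        vals[bins + 1L] <- vals[bins + 1L] + ov
      }
    }
  }
  structure(list(chrom = chrom, bin_size = B, chrom_length = chrom_length,
                 values = vals / B),
            class = "coverage_track")
}

#' Amplified-segment calling from a coverage track
#'
#' Maximal runs of bins with depth at or above
#' `max(depth_floor, enrich_factor x global median depth)`; runs separated
#' by at most `merge_gap` are merged.
#'
#' @param track a `coverage_track`.
#' @param config [detector_config()].
#' @param global_median median bin depth across the whole genome (computed
#'   by [detect_ecdna()]; defaults to the track's own median).
#' @return sorted `gintervals` of amplified segments.
#' @export
call_amplified_segments <- function(track, config = detector_config(),
                                    global_median = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  if (is.null(global_median)) global_median <- stats::median(track$values)
  thr <- max(config$depth_floor, config$enrich_factor * global_median)
  hot <- track$values >= thr
  if (!any(hot)) return(gintervals(character(), numeric(), numeric()))
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  B <- track$bin_size
  iv <- gintervals(track$chrom, (starts[keep] - 1) * B,
                   pmin(ends[keep] * B, track$chrom_length))
  merge_intervals(iv, max_gap = config$merge_gap)
}

amplified_threshold <- function(config, global_median) {
  max(config$depth_floor, config$enrich_factor * global_median)
}

## discordance: different chromosomes, same-strand or outward orientation,
## or template length above the insert cutoff (standard SV practice)
classify_discordant <- function(aln, insert_cutoff) {
  paired <- !is.na(aln$mchrom)
  inter <- paired & aln$chrom != aln$mchrom
  same_strand <- paired & !inter & aln$strand == aln$mstrand
  left_read <- aln$pos <= aln$mpos
  outward <- paired & !inter & !same_strand &
    ((left_read & aln$strand == "-") | (!left_read & aln$strand == "+"))
  big_insert <- paired & !inter & !is.na(aln$tlen) &
    abs(aln$tlen) > insert_cutoff
  inter | same_strand | outward | big_insert
}

pair_breakends <- function(aln) {
  ## one row per discordant pair with both breakends, canonically ordered
  dt <- data.table::as.data.table(aln)
  dt[, bp_pos := ifelse(strand == "+", end, pos)]
  dt[, bp_side := ifelse(strand == "+", "right", "left")]
  dt <- dt[, .SD[order(first, decreasing = TRUE)], by = qname]
  two <- dt[, .N, by = qname][N == 2L, qname]
  dt <- dt[qname %in% two]
  r1 <- dt[!duplicated(qname)]
  r2 <- dt[duplicated(qname)]
  pairs <- data.table::data.table(
    qname = r1$qname,
    chrom_a = r1$chrom, pos_a = r1$bp_pos, side_a = r1$bp_side,
    chrom_b = r2$chrom[match(r1$qname, r2$qname)],
    pos_b = r2$bp_pos[match(r1$qname, r2$qname)],
    side_b = r2$bp_side[match(r1$qname, r2$qname)],
    barcode = r1$barcode
  )
  flip <- (pairs$chrom_a > pairs$chrom_b) |
    (pairs$chrom_a == pairs$chrom_b & pairs$pos_a > pairs$pos_b)
  tmp <- pairs[flip, .(chrom_a, pos_a, side_a)]
  pairs[flip, c("chrom_a", "pos_a", "side_a")] <-
    pairs[flip, .(chrom_b, pos_b, side_b)]
  pairs[flip, c("chrom_b", "pos_b", "side_b")] <- tmp
  pairs
}

#' Cluster discordant read pairs into breakpoint junctions
#'
#' A pair is discordant iff its mates map to different chromosomes, share a
#' strand or face outward on the same chromosome, or have template length
#' above `insert_cutoff`. Pairs are grouped by (chrom, side) of both
#' breakends and single-linkage clustered with gap `cluster_window` on each
#' breakend coordinate in turn; clusters with fewer than
#' `min_discordant_support` pairs are dropped. The junction position is the
#' median of member breakend positions.
#'
#' @param aln alignment record table (mate information required).
#' @param config [detector_config()].
#' @return `bp_junctions` data frame.
#' @export
cluster_discordant_pairs <- function(aln, config = detector_config()) {
  aln <- data.table::as.data.table(aln)
  if (any(aln$secondary)) aln <- aln[secondary == FALSE]
  no_mate <- sum(is.na(aln$mchrom))
  if (no_mate > 0)
    message(no_mate, " records without mate information skipped")
  disc <- aln[classify_discordant(aln, config$insert_cutoff)]
  if (nrow(disc) == 0L) return(empty_junctions())
  pairs <- pair_breakends(disc)
  if (nrow(pairs) == 0L) return(empty_junctions())
  W <- config$cluster_window
  data.table::setorder(pairs, chrom_a, side_a, chrom_b, side_b, pos_a, pos_b)
  pairs[, cl_a := cumsum(c(1L, (diff(pos_a) > W) |
                             head(chrom_a, -1) != tail(chrom_a, -1) |
                             head(side_a, -1) != tail(side_a, -1) |
                             head(chrom_b, -1) != tail(chrom_b, -1) |
                             head(side_b, -1) != tail(side_b, -1)))]
  data.table::setorder(pairs, cl_a, pos_b)
  pairs[, cl := cl_a * 1e9 + cumsum(c(1L, diff(pos_b) > W)), by = cl_a]
  jx <- pairs[, .(chrom_a = chrom_a[1],
                  pos_a = round(stats::median(pos_a)), side_a = side_a[1],
                  chrom_b = chrom_b[1],
                  pos_b = round(stats::median(pos_b)), side_b = side_b[1],
                  discordant_support = .N), by = cl]
  jx <- jx[discordant_support >= config$min_discordant_support]
  if (nrow(jx) == 0L) return(empty_junctions())
  jx[, clip_support := 0L]
  canonicalize_junctions(as.data.frame(jx[, -"cl"]))
}

clip_positions <- function(aln) {
  aln <- data.table::as.data.table(aln)
  lefts <- aln[clip_left > 0 & secondary == FALSE,
               .(chrom, pos = pos, side = "left")]
  rights <- aln[clip_right > 0 & secondary == FALSE,
                .(chrom, pos = end, side = "right")]
  rbind(lefts, rights)
}

#' Refine junction breakends with soft-clip positions
#'
#' For each breakend, if at least one clipped read has its clip position on
#' the matching side within `cluster_window`, the breakend is moved to the
#' modal clip position (ties broken towards the smaller coordinate) and the
#' junction's `clip_support` is incremented by the number of supporting
#' clips; otherwise the breakend is left unchanged.
#'
#' @param junctions `bp_junctions` from [cluster_discordant_pairs()].
#' @param aln alignment record table.
#' @param config [detector_config()].
#' @return refined `bp_junctions`.
#' @export
refine_breakpoints_with_clips <- function(junctions, aln,
                                          config = detector_config()) {
  if (nrow(junctions) == 0L) return(junctions)
  clips <- as.data.frame(clip_positions(aln))
  W <- config$cluster_window
  refine_one <- function(qchrom, qpos, qside) {
    hit <- clips[clips$chrom == qchrom & clips$side == qside &
                   abs(clips$pos - qpos) <= W, ]
    if (nrow(hit) == 0L) return(list(pos = qpos, n = 0L))
    tab <- table(hit$pos)
    modal <- as.numeric(names(tab)[tab == max(tab)])
    list(pos = min(modal), n = nrow(hit))
  }
  for (i in seq_len(nrow(junctions))) {
    a <- refine_one(junctions$chrom_a[i], junctions$pos_a[i],
                    junctions$side_a[i])
    b <- refine_one(junctions$chrom_b[i], junctions$pos_b[i],
                    junctions$side_b[i])
    junctions$pos_a[i] <- a$pos
    junctions$pos_b[i] <- b$pos
    junctions$clip_support[i] <- a$n + b$n
  }
  canonicalize_junctions(junctions)
}

## ---- breakpoint graph & cycle assembly ------------------------------------

## Node encoding: segment i has ends 2i-1 (left, at start) and 2i (right,
## at end). Segment edges pair 2i-1 with 2i (a perfect matching); junction
## edges connect the ends their breakends snap to.
snap_junctions_to_segments <- function(segments, junctions, snap_window) {
  n <- nrow(segments)
  ends <- data.frame(
    node = seq_len(2L * n),
    seg = rep(seq_len(n), each = 2L),
    side = rep(c("left", "right"), n),
    chrom = rep(segments$chrom, each = 2L),
    pos = as.vector(rbind(segments$start, segments$end)),
    stringsAsFactors = FALSE
  )
  snap_one <- function(chrom, pos, side) {
    cand <- ends[ends$chrom == chrom & ends$side == side, ]
    if (nrow(cand) == 0L) return(NA_integer_)
    d <- abs(cand$pos - pos)
    if (min(d) > snap_window) return(NA_integer_)
    cand$node[which.min(d)]
  }
  node_a <- mapply(snap_one, junctions$chrom_a, junctions$pos_a,
                   junctions$side_a)
  node_b <- mapply(snap_one, junctions$chrom_b, junctions$pos_b,
                   junctions$side_b)
  ok <- !is.na(node_a) & !is.na(node_b)
  list(ends = ends, node_a = as.integer(node_a[ok]),
       node_b = as.integer(node_b[ok]), junctions = junctions[ok, ],
       kept = ok)
}

#' Assemble circular candidates from a breakpoint graph
#'
#' Builds the breakpoint graph whose nodes are amplified-segment ends,
#' whose segment edges span each segment and whose junction edges are the
#' clustered discordant junctions snapped to the nearest segment end of
#' matching side within `snap_window` (junctions near no segment end are
#' discarded). Every simple cycle alternating segment and junction edges
#' with at most `max_segments_per_circle` segments becomes a candidate;
#' traversing a segment left-to-right gives a forward oriented segment,
#' right-to-left a reverse one. Segment boundaries are sharpened to the
#' (clip-refined) junction positions they snapped to, and `depth_mean` /
#' `high_coverage` are computed from the coverage tracks.
#'
#' @param segments amplified segments (`gintervals`).
#' @param junctions refined `bp_junctions`.
#' @param tracks named list of `coverage_track` per chromosome (optional;
#'   QC fields are NA without it).
#' @param config [detector_config()].
#' @param global_median genome-wide median bin depth for the
#'   `high_coverage` cutoff.
#' @return list of [ecdna_candidate()] objects.
#' @export
assemble_circles <- function(segments, junctions, tracks = NULL,
                             config = detector_config(),
                             global_median = NULL) {
  if (nrow(segments) == 0L || nrow(junctions) == 0L) return(list())
  segments <- as.data.frame(segments)
  snap <- snap_junctions_to_segments(segments, junctions, config$snap_window)
  if (length(snap$node_a) == 0L) return(list())
  ## sharpen segment boundaries to junction breakends
  for (k in seq_along(snap$node_a)) {
    for (nd in c(snap$node_a[k], snap$node_b[k])) {
      seg <- snap$ends$seg[nd]
      side <- snap$ends$side[nd]
      pos_k <- c(snap$junctions$pos_a[k], snap$junctions$pos_b[k])[
        c(snap$node_a[k], snap$node_b[k]) == nd][1]
      if (side == "left" && pos_k < segments$end[seg])
        segments$start[seg] <- pos_k
      if (side == "right" && pos_k > segments$start[seg])
        segments$end[seg] <- pos_k
    }
  }
  n_seg <- nrow(segments)
  ## adjacency over junction edges
  adj <- vector("list", 2L * n_seg)
  for (k in seq_along(snap$node_a)) {
    a <- snap$node_a[k]; b <- snap$node_b[k]
    adj[[a]] <- rbind(adj[[a]], c(b, k))
    adj[[b]] <- rbind(adj[[b]], c(a, k))
  }
  other_end <- function(node) if (node %% 2L == 1L) node + 1L else node - 1L
  seg_of <- function(node) (node + 1L) %/% 2L
  cycles <- list()
  seen <- character()
  ## DFS: state = entry node of current segment; path of (segment, entry)
  walk <- function(entry_node, path_nodes, path_juncs, used_seg, used_junc,
                   start_node) {
    exit_node <- other_end(entry_node)
    cand <- adj[[exit_node]]
    if (is.null(cand)) return(invisible())
    for (r in seq_len(nrow(cand))) {
      nxt <- cand[r, 1]; jid <- cand[r, 2]
      if (used_junc[jid]) next
      if (nxt == start_node) {
        key_nodes <- c(path_nodes)
        cyc <- list(nodes = path_nodes, juncs = c(path_juncs, jid))
        key <- canonical_cycle_key(cyc$nodes, cyc$juncs)
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          cycles[[length(cycles) + 1L]] <<- cyc
        }
        next
      }
      s <- seg_of(nxt)
      if (used_seg[s]) next
      if (length(path_nodes) >= config$max_segments_per_circle) next
      used_seg2 <- used_seg; used_seg2[s] <- TRUE
      used_junc2 <- used_junc; used_junc2[jid] <- TRUE
      walk(nxt, c(path_nodes, nxt), c(path_juncs, jid),
           used_seg2, used_junc2, start_node)
    }
    invisible()
  }
  n_junc <- length(snap$node_a)
  for (s in seq_len(n_seg)) {
    for (entry in c(2L * s - 1L, 2L * s)) {
      used_seg <- logical(n_seg); used_seg[s] <- TRUE
      walk(entry, entry, integer(), used_seg, logical(n_junc), entry)
    }
  }
  thr <- if (!is.null(global_median)) amplified_threshold(config, global_median)
         else NULL
  out <- lapply(seq_along(cycles), function(i) {
    cyc <- cycles[[i]]
    segs <- seg_of(cyc$nodes)
    orient <- ifelse(cyc$nodes %% 2L == 1L, "+", "-")  # entered at left => fwd
    seg_df <- segments[segs, c("chrom", "start", "end"), drop = FALSE]
    seg_df$strand <- orient
    rownames(seg_df) <- NULL
    qc <- candidate_qc(seg_df, tracks, thr)
    ecdna_candidate(sprintf("ecdna_%d", i), seg_df,
                    snap$junctions[cyc$juncs, ],
                    depth_mean = qc$depth_mean,
                    high_coverage = qc$high_coverage)
  })
  out
}

## canonical key: minimal rotation/reflection of the (segment, orientation)
## sequence, so each cycle is emitted once
canonical_cycle_key <- function(nodes, juncs) {
  seg <- (nodes + 1L) %/% 2L
  ori <- nodes %% 2L
  enc <- paste(seg, ori, sep = ":")
  rots <- function(v) lapply(seq_along(v), function(i)
    c(v[i:length(v)], v[seq_len(i - 1L)]))
  rev_enc <- paste(rev(seg), 1L - rev(ori), sep = ":")
  keys <- vapply(c(rots(enc), rots(rev_enc)), paste, character(1),
                 collapse = "|")
  min(keys)
}

candidate_qc <- function(seg_df, tracks, thr) {
  if (is.null(tracks) || is.null(thr))
    return(list(depth_mean = NA_real_, high_coverage = NA_real_))
  tot_bp <- 0; tot_depth <- 0; hi_bp <- 0
  for (i in seq_len(nrow(seg_df))) {
    tr <- tracks[[seg_df$chrom[i]]]
    if (is.null(tr)) next
    B <- tr$bin_size
    b0 <- floor(seg_df$start[i] / B) + 1L
    b1 <- floor((seg_df$end[i] - 1) / B) + 1L
    v <- tr$values[b0:b1]
    bp <- rep(B, length(v))
    bp[1] <- min(seg_df$end[i], b0 * B) - seg_df$start[i]
    if (length(v) > 1L) bp[length(bp)] <- seg_df$end[i] - (b1 - 1L) * B
    tot_bp <- tot_bp + sum(bp)
    tot_depth <- tot_depth + sum(v * bp)
    hi_bp <- hi_bp + sum(bp[v >= thr])
  }
  list(depth_mean = tot_depth / tot_bp, high_coverage = hi_bp / tot_bp)
}

#' Filter candidates on the published QC rule
#'
#' Keeps candidates with `size_min <= size <= size_max`,
#' `depth_mean > min_depth_mean` and `high_coverage > min_high_coverage`.
#'
#' @param candidates list of `ecdna_candidate`.
#' @param config [detector_config()].
#' @return filtered list.
#' @export
filter_candidates <- function(candidates, config = detector_config()) {
  Filter(function(cand) {
    !is.na(cand$depth_mean) && !is.na(cand$high_coverage) &&
      cand$size >= config$size_min && cand$size <= config$size_max &&
      cand$depth_mean > config$min_depth_mean &&
      cand$high_coverage > config$min_high_coverage
  }, candidates)
}

#' Detect ecDNA candidates from a pseudo-bulk scATAC-seq library
#'
#' End-to-end pseudo-bulk detection: binned coverage and amplified-segment
#' calling per genome chunk, global clustering of discordant pairs (so the
#' result is independent of `chunk_size`), clip refinement, breakpoint-graph
#' cycle assembly and QC filtering.
#'
#' @param x alignment record table (see [read_alignments()]) or a BAM/SAM
#'   file path.
#' @param genome named numeric vector of chromosome lengths; taken from the
#'   BAM header when `x` is a path.
#' @param config [detector_config()].
#' @return list of retained [ecdna_candidate()] objects; the coverage
#'   tracks, junctions and pre-filter candidates are attached as attributes
#'   `tracks`, `junctions` and `unfiltered`.
#' @export
detect_ecdna <- function(x, genome = NULL, config = detector_config()) {
  if (is.character(x)) {
    if (grepl("\\.sam$", x))
      x <- Rsamtools::asBam(x, sub("\\.sam$", "", x), overwrite = TRUE,
                            indexDestination = TRUE)
    if (is.null(genome)) {
      hdr <- Rsamtools::scanBamHeader(x)[[1]]$targets
      genome <- stats::setNames(as.numeric(hdr), names(hdr))
    }
    x <- read_alignments(x)
  }
  if (is.null(genome)) stop("genome (chromosome lengths) required")
  aln <- data.table::as.data.table(x)
  if (any(aln$secondary)) aln <- aln[secondary == FALSE]
  ## chunked coverage: chunks aligned to the bin grid; a record contributes
  ## to the chunk its start falls in, its full span added to the global
  ## per-chromosome track, so output does not depend on chunk_size
  chunk <- config$bin_size * max(1, floor(config$chunk_size / config$bin_size))
  tracks <- list()
  for (chr in names(genome)) {
    chr_len <- genome[[chr]]
    rec <- aln[chr, on = "chrom", .(pos, end), nomatch = NULL]
    vals <- numeric(ceiling(chr_len / config$bin_size))
    n_chunks <- max(1L, ceiling(chr_len / chunk))
    for (ci in seq_len(n_chunks)) {
      lo <- (ci - 1L) * chunk; hi <- min(ci * chunk, chr_len)
      part <- rec[pos >= lo & pos < hi]
      if (nrow(part) == 0L) next
      tr <- compute_coverage(part, chr, chr_len, config)
      vals <- vals + tr$values
      rm(part)
    }
    rm(rec)
    tracks[[chr]] <- structure(
      list(chrom = chr, bin_size = config$bin_size, chrom_length = chr_len,
           values = vals), class = "coverage_track")
  }
  global_median <- stats::median(unlist(lapply(tracks, `[[`, "values")))
  seg_list <- lapply(tracks, call_amplified_segments, config = config,
                     global_median = global_median)
  segments <- do.call(rbind, seg_list)
  if (is.null(segments)) segments <- gintervals(character(), numeric(),
                                                numeric())
  rownames(segments) <- NULL
  junctions <- cluster_discordant_pairs(aln, config)
  junctions <- refine_breakpoints_with_clips(junctions, aln, config)
  candidates <- assemble_circles(segments, junctions, tracks, config,
                                 global_median)
  kept <- filter_candidates(candidates, config)
  kept <- lapply(seq_along(kept), function(i) {
    kept[[i]]$id <- sprintf("ecdna_%d", i); kept[[i]]
  })
  attr(kept, "tracks") <- tracks
  attr(kept, "junctions") <- junctions
  attr(kept, "unfiltered") <- candidates
  kept
}
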