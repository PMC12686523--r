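test_that("binned coverage equals a naive per-base pileup", {
  cfg <- detector_config(bin_size = 1000)
  empty <- aln_row(integer(), character(), integer(), integer())[0]
  tr <- compute_coverage(empty, "chr1", 10e3, cfg)
  expect_equal(tr$values, rep(0, 10))

  one <- aln_row(1, "chr1", 2100, 2150)
  tr <- compute_coverage(one, "chr1", 10e3, cfg)
  expect_equal(tr$values[3], 0.05)
  expect_equal(sum(tr$values), 0.05)

  set.seed(5)
  n <- 200
  pos <- sort(sample(0:9000, n, TRUE))
  len <- sample(30:900, n, TRUE)  # spans of 1..2+ bins
  reads <- aln_row(seq_len(n), "chr1", pos, pmin(pos + len, 10e3))
  tr <- compute_coverage(reads, "chr1", 10e3, cfg)
  depth <- numeric(10e3)
  for (i in seq_len(n)) {
    idx <- (reads$pos[i] + 1):reads$end[i]
    depth[idx] <- depth[idx] + 1
  }
  oracle <- colMeans(matrix(depth, nrow = 1000))
  expect_equal(tr$values, oracle)
  expect_error(compute_coverage(reads, "chr1", NA, cfg))
  expect_error(compute_coverage(reads[c(2, 1)], "chr1", 10e3, cfg))
})

test_that("amplified segments are threshold runs merged across small gaps", {
  cfg <- detector_config(bin_size = 1000, depth_floor = 5,
                         enrich_factor = 2, merge_gap = 10e3)
  mk_track <- function(vals) structure(
    list(chrom = "chr1", bin_size = 1000, chrom_length = 1000 * length(vals),
         values = vals), class = "coverage_track")
  expect_equal(nrow(call_amplified_segments(mk_track(rep(4, 100)), cfg,
                                            global_median = 1)), 0)
  v <- rep(1, 100); v[21:50] <- 20
  seg <- call_amplified_segments(mk_track(v), cfg, global_median = 1)
  expect_equal(seg$start, 20e3)
  expect_equal(seg$end, 50e3)
  # two runs separated by a 5 kb gap merge under a 10 kb merge_gap
  v2 <- rep(1, 100); v2[11:30] <- 20; v2[36:60] <- 20
  seg2 <- call_amplified_segments(mk_track(v2), cfg, global_median = 1)
  expect_equal(nrow(seg2), 1)
  expect_equal(c(seg2$start, seg2$end), c(10e3, 60e3))
  # run-length oracle at the effective threshold
  thr <- max(cfg$depth_floor, 2 * 1)
  hot <- v2 >= thr
  expect_equal(sum(seg2$end - seg2$start) >= sum(hot) * 1000, TRUE)
})

test_that("discordant pairs cluster into junctions with support filtering", {
  cfg <- detector_config(cluster_window = 500, min_discordant_support = 3)
  # concordant-only library yields nothing
  conc <- do.call(rbind, lapply(1:5, function(i) rbind(
    aln_row(i, "chr1", 1000 + i, 1050 + i, "+", "chr1", 1250 + i, "-", 300L),
    aln_row(i, "chr1", 1250 + i, 1300 + i, "-", "chr1", 1000 + i, "+",
            -300L, first = FALSE))))
  expect_equal(nrow(cluster_discordant_pairs(conc, cfg)), 0)

  # 10 pairs spanning one head-to-tail junction, ends within 100 bp
  set.seed(2)
  prs <- do.call(rbind, lapply(1:10, function(i)
    disc_pair(i, "chr1", 5000 + sample(-50:50, 1), "chr2",
              9000 + sample(-50:50, 1))))
  jx <- cluster_discordant_pairs(prs, cfg)
  expect_equal(nrow(jx), 1)
  expect_equal(jx$discordant_support, 10L)
  expect_lt(abs(jx$pos_a - 5000), 60)
  expect_equal(jx$side_a, "right")
  expect_equal(jx$side_b, "left")
  # exhaustive pairwise-distance oracle: all members within one cluster
  ends_a <- prs[prs$strand == "+", ]$end
  expect_lt(max(dist(ends_a)), cfg$cluster_window)

  # below min support the cluster is dropped
  two <- rbind(disc_pair(1, "chr1", 5000, "chr2", 9000),
               disc_pair(2, "chr1", 5010, "chr2", 9010))
  expect_equal(nrow(cluster_discordant_pairs(two, cfg)), 0)
})

test_that("clip refinement moves breakends to the modal clip position", {
  cfg <- detector_config()
  jx <- bp_junctions("chr1", 5010, "right", "chr2", 9005, "left", 5L, 0L)
  no_clips <- disc_pair(1, "chr1", 5000, "chr2", 9000)
  out <- refine_breakpoints_with_clips(jx, no_clips, cfg)
  expect_identical(out$pos_a, jx$pos_a)
  expect_equal(out$clip_support, 0L)

  clips5 <- do.call(rbind, lapply(1:5, function(i)
    aln_row(i, "chr1", 4950 + i, 5003, clip_right = 10L)))
  out <- refine_breakpoints_with_clips(jx, clips5, cfg)
  expect_equal(out$pos_a, 5003)
  expect_equal(out$clip_support, 5L)

  # mode with tie {p, p, p+1} resolves to the smaller coordinate
  tie <- rbind(aln_row(1, "chr1", 4950, 5003, clip_right = 10L),
               aln_row(2, "chr1", 4951, 5003, clip_right = 10L),
               aln_row(3, "chr1", 4952, 5004, clip_right = 10L),
               aln_row(4, "chr1", 4950, 5004, clip_right = 10L))
  out <- refine_breakpoints_with_clips(jx, tie, cfg)
  expect_equal(out$pos_a, 5003)
})

test_that("cycle assembly enumerates alternating cycles of the graph", {
  cfg <- detector_config(snap_window = 2000)
  # one segment joined head-to-tail: a single one-segment circle
  segs <- gintervals("chr1", 10e3, 60e3)
  jx <- bp_junctions("chr1", 60e3, "right", "chr1", 10e3, "left", 10L, 5L)
  circ <- assemble_circles(segs, jx, config = cfg)
  expect_equal(length(circ), 1)
  expect_equal(nrow(circ[[1]]$segments), 1)
  expect_equal(circ[[1]]$segments$strand, "+")

  # A.right-B.left and B.right-A.left: one two-segment circle
  segs2 <- gintervals(c("chr1", "chr2"), c(10e3, 20e3), c(60e3, 90e3))
  jx2 <- rbind(
    bp_junctions("chr1", 60e3, "right", "chr2", 20e3, "left", 8L, 2L),
    bp_junctions("chr2", 90e3, "right", "chr1", 10e3, "left", 9L, 3L))
  circ2 <- assemble_circles(segs2, jx2, config = cfg)
  expect_equal(length(circ2), 1)
  expect_equal(nrow(circ2[[1]]$segments), 2)

  # no junction edges: nothing to assemble
  expect_equal(length(assemble_circles(segs2, jx2[0, ], config = cfg)), 0)

  # junctions too far from any segment end are discarded
  far <- bp_junctions("chr1", 200e3, "right", "chr2", 300e3, "left", 5L, 0L)
  expect_equal(length(assemble_circles(segs2, far, config = cfg)), 0)
})

test_that("assembly agrees with brute-force cycle enumeration", {
  # oracle: try every segment subset, order, and orientation assignment;
  # a cycle is valid when each consecutive (exit, entry) breakend pair is
  # a listed junction
  brute_cycles <- function(segments, junctions) {
    n <- nrow(segments)
    key <- function(c1, p1, s1, c2, p2, s2) {
      j <- bp_junctions(c1, p1, s1, c2, p2, s2)
      paste(j$chrom_a, j$pos_a, j$side_a, j$chrom_b, j$pos_b, j$side_b)
    }
    have <- unlist(lapply(seq_len(nrow(junctions)), function(i)
      key(junctions$chrom_a[i], junctions$pos_a[i], junctions$side_a[i],
          junctions$chrom_b[i], junctions$pos_b[i], junctions$side_b[i])))
    ends <- function(i, o) {
      if (o == "+") list(entry = c(segments$chrom[i], segments$start[i],
                                   "left"),
                         exit = c(segments$chrom[i], segments$end[i],
                                  "right"))
      else list(entry = c(segments$chrom[i], segments$end[i], "right"),
                exit = c(segments$chrom[i], segments$start[i], "left"))
    }
    found <- character()
    subsets <- unlist(lapply(seq_len(n), function(k)
      combn(n, k, simplify = FALSE)), recursive = FALSE)
    for (sub in subsets) {
      perms <- if (length(sub) == 1) list(sub) else {
        p <- gtools_perm <- function(v) {
          if (length(v) <= 1) return(list(v))
          out <- list()
          for (i in seq_along(v))
            for (rest in gtools_perm(v[-i]))
              out[[length(out) + 1]] <- c(v[i], rest)
          out
        }
        p(sub)
      }
      for (perm in perms) {
        k <- length(perm)
        oris <- expand.grid(rep(list(c("+", "-")), k),
                            stringsAsFactors = FALSE)
        for (r in seq_len(nrow(oris))) {
          oo <- unlist(oris[r, ])
          es <- lapply(seq_len(k), function(t) ends(perm[t], oo[t]))
          ok <- TRUE
          for (t in seq_len(k)) {
            e1 <- es[[t]]$exit
            e2 <- es[[if (t == k) 1 else t + 1]]$entry
            if (!(key(e1[1], as.numeric(e1[2]), e1[3],
                      e2[1], as.numeric(e2[2]), e2[3]) %in% have)) {
              ok <- FALSE; break
            }
          }
          if (ok) {
            enc <- paste(perm, oo, sep = ":")
            rots <- vapply(seq_len(k), function(s)
              paste(c(enc[s:k], enc[seq_len(s - 1)]), collapse = "|"),
              character(1))
            flip <- rev(paste(perm, ifelse(oo == "+", "-", "+"), sep = ":"))
            rots2 <- vapply(seq_len(k), function(s)
              paste(c(flip[s:k], flip[seq_len(s - 1)]), collapse = "|"),
              character(1))
            found <- union(found, min(c(rots, rots2)))
          }
        }
      }
    }
    length(found)
  }
  set.seed(13)
  g <- tiny_genome(4, 3e6)
  for (rep in 1:6) {
    truth <- simulate_ecdna_structures(g, n_circles = 2,
                                       size_range = c(120e3, 260e3),
                                       max_segments = 3)
    segments <- do.call(rbind, lapply(truth, function(x)
      x$segments[, c("chrom", "start", "end")]))
    junctions <- do.call(rbind, lapply(truth, `[[`, "junctions"))
    got <- assemble_circles(segments, junctions,
                            config = detector_config())
    expect_equal(length(got), brute_cycles(segments, junctions))
  }
})

test_that("the published QC filter removes undersized or weak candidates", {
  cfg <- detector_config()
  mk <- function(size, depth, hc) {
    segs <- data.frame(chrom = "chr1", start = 0, end = size, strand = "+")
    jx <- bp_junctions("chr1", size, "right", "chr1", 0, "left", 5L, 0L)
    ecdna_candidate("x", segs, jx, depth_mean = depth, high_coverage = hc)
  }
  keep <- mk(1e6, 20, 0.9)
  expect_equal(length(filter_candidates(list(keep), cfg)), 1)
  expect_equal(length(filter_candidates(list(mk(5e3, 20, 0.9)), cfg)), 0)
  expect_equal(length(filter_candidates(list(mk(25e6, 20, 0.9)), cfg)), 0)
  expect_equal(length(filter_candidates(list(mk(1e6, 4, 0.9)), cfg)), 0)
  expect_equal(length(filter_candidates(list(mk(1e6, 20, 0.05)), cfg)), 0)
})

test_that("end-to-end detection recovers planted circles and ignores a
           junction-free library", {
  fx <- tiny_library(seed = 21, n_circles = 2, circle_depth = 15)
  det <- quiet(detect_ecdna(fx$lib, fx$genome))
  m <- quiet(match_detections(det, fx$truth))
  expect_equal(m$tp, 2)
  expect_equal(m$fp, 0)
  # boundaries within one bin of truth
  for (p in seq_len(nrow(m$pairs)))
    expect_gt(m$pairs$overlap[p], 0.98)
  # every retained candidate satisfies the QC filter post-hoc
  for (cand in det) {
    expect_gte(cand$size, 10e3)
    expect_gt(cand$depth_mean, 5)
    expect_gt(cand$high_coverage, 0.1)
  }
  # background-only library (no junctions) yields nothing
  bg <- quiet(simulate_library(list(), fx$genome,
                               sim_read_config(background_depth = 4,
                                               circle_depth = 0)))
  expect_equal(length(quiet(detect_ecdna(bg, fx$genome))), 0)
})

test_that("detection is invariant to the processing chunk size", {
  fx <- tiny_library(seed = 33, n_circles = 2, circle_depth = 15)
  strip <- function(d) lapply(d, function(x)
    x[c("segments", "junctions", "size", "depth_mean", "high_coverage")])
  d_big <- quiet(detect_ecdna(fx$lib, fx$genome,
                              detector_config(chunk_size = 64e6)))
  d_small <- quiet(detect_ecdna(fx$lib, fx$genome,
                                detector_config(chunk_size = 1e6)))
  d_tiny <- quiet(detect_ecdna(fx$lib, fx$genome,
                               detector_config(chunk_size = 128e3)))
  expect_identical(strip(d_big), strip(d_small))
  expect_identical(strip(d_big), strip(d_tiny))
})
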