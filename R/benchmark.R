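#' Precision / recall / F1 from counts
#'
#' Precision is 0 by convention when nothing is detected; F1 is 0 when
#' both precision and recall are 0.
#'
#' @param tp,fp,fn counts.
#' @return data frame `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
prf <- function(tp, fp, fn) {
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  data.frame(tp = tp, fp = fp, fn = fn, precision = precision,
             recall = recall, f1 = f1)
}

#' Match detected candidates to planted truth
#'
#' Greedy 1-to-1 matching by descending reciprocal overlap of the
#' candidates' segment footprints; a pair matches iff its reciprocal
#' overlap is at least `min_reciprocal`. Order-invariant with respect to
#' input permutations (ties broken by overlap, then by index).
#'
#' @param detected,truth lists of [ecdna_candidate()].
#' @param min_reciprocal minimum reciprocal overlap for a match.
#' @return list: `tp`, `fp`, `fn`, `pairs` (data frame of matched index
#'   pairs and overlaps), plus `prf` row.
#' @export
match_detections <- function(detected, truth, min_reciprocal = 0.5) {
  nd <- length(detected); nt <- length(truth)
  if (nd == 0 || nt == 0) {
    res <- prf(0, nd, nt)
    return(list(tp = 0L, fp = nd, fn = nt,
                pairs = data.frame(detected = integer(), truth = integer(),
                                   overlap = numeric()),
                prf = res))
  }
  di <- lapply(detected, candidate_intervals)
  ti <- lapply(truth, candidate_intervals)
  ov <- matrix(0, nd, nt)
  for (i in seq_len(nd)) for (j in seq_len(nt))
    ov[i, j] <- reciprocal_overlap(di[[i]], ti[[j]])
  pairs <- data.frame(detected = integer(), truth = integer(),
                      overlap = numeric())
  used_d <- logical(nd); used_t <- logical(nt)
  repeat {
    ov_masked <- ov
    ov_masked[used_d, ] <- -1
    ov_masked[, used_t] <- -1
    best <- which.max(ov_masked)
    if (ov_masked[best] < min_reciprocal) break
    i <- (best - 1) %% nd + 1
    j <- (best - 1) %/% nd + 1
    pairs <- rbind(pairs, data.frame(detected = i, truth = j,
                                     overlap = ov[i, j]))
    used_d[i] <- TRUE; used_t[j] <- TRUE
    if (all(used_d) || all(used_t)) break
  }
  tp <- nrow(pairs)
  list(tp = tp, fp = nd - tp, fn = nt - tp, pairs = pairs,
       prf = prf(tp, nd - tp, nt - tp))
}

#' Detection benchmark over circle local depth
#'
#' For each depth in the grid: plant circles on a synthetic mini-genome,
#' simulate the barcoded paired-end library over a uniform accessibility
#' background, run the detector with default filters, and score the
#' detections against truth by greedy reciprocal-overlap matching.
#'
#' @param depths circle local depths to sweep.
#' @param genome named chromosome lengths (default 6 x 10 Mb).
#' @param n_circles circles per library.
#' @param size_range circle sizes, bp (scaled-down protocol).
#' @param background_depth background depth.
#' @param min_reciprocal matching threshold.
#' @param config [detector_config()].
#' @param seed seed (one library per depth, derived deterministically).
#' @return data frame, one row per depth: counts plus precision / recall /
#'   F1.
#' @export
run_detection_benchmark <- function(depths = c(5, 10, 20, 30),
                                    genome = synthetic_genome(6, 10e6),
                                    n_circles = 24,
                                    size_range = c(150e3, 900e3),
                                    background_depth = 4,
                                    min_reciprocal = 0.5,
                                    config = detector_config(),
                                    seed = 1) {
  rows <- lapply(seq_along(depths), function(k) {
    set.seed(seed + 1000L * k)
    truth <- simulate_ecdna_structures(genome, n_circles = n_circles,
                                       size_range = size_range,
                                       max_segments = 3)
    lib <- simulate_library(truth, genome,
                            sim_read_config(background_depth =
                                              background_depth,
                                            circle_depth = depths[k]))
    det <- detect_ecdna(lib, genome, config)
    m <- match_detections(det, truth, min_reciprocal)
    cbind(data.frame(depth = depths[k], n_truth = length(truth),
                     n_detected = length(det)), m$prf)
  })
  do.call(rbind, rows)
}

#' GMM classification benchmark over the m x copy-ratio grid
#'
#' For each grid cell (`m` amplified groups x copy ratio, `n_repeats`
#' repeats, `n_regions` ecDNA regions per repeat): simulate the Poisson
#' bin-by-cell matrix, compute per-cell log2 CPM over the ecDNA bins, fit
#' the two-component GMM, label the higher-mean component as amplified and
#' score against the planted truth labels.
#'
#' @param m_values amplified-group counts.
#' @param copy_ratios focal amplification ratios.
#' @param cfg base [sim_matrix_config()] (its `m` / `copy_ratio` are
#'   overridden per grid cell).
#' @param n_regions ecDNA regions simulated per repeat.
#' @param seed seed.
#' @return data frame with one row per (m, copy_ratio, repeat, region):
#'   counts plus precision / recall / F1.
#' @export
run_gmm_benchmark <- function(m_values = 1:4, copy_ratios = c(3, 5, 10, 20),
                              cfg = sim_matrix_config(), n_regions = 4,
                              seed = 1) {
  rows <- list()
  for (m in m_values) for (cr in copy_ratios) {
    for (rep_i in seq_len(cfg$n_repeats)) {
      cell_cfg <- cfg
      cell_cfg$m <- m; cell_cfg$copy_ratio <- cr
      set.seed(seed + 7919L * m + 104729L * match(cr, copy_ratios) +
                 1299709L * rep_i)
      baseline <- make_baseline_lambda(cell_cfg)
      for (reg in seq_len(n_regions)) {
        bins <- sample_ecdna_bins(cell_cfg, baseline)
        cn <- make_copy_number_matrix(cell_cfg, bins)
        X <- simulate_count_matrix(baseline$lambda, cn$C,
                                   cell_cfg$sparse_fac)
        sig <- region_log2_cpm(X, bins)
        ok <- is.finite(sig)
        fit <- fit_two_component_gmm(sig[ok])
        labels <- assign_by_gmm(fit)
        truth <- cn$truth_labels[ok]
        tp <- sum(labels & truth); fp <- sum(labels & !truth)
        fn <- sum(!labels & truth)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(m = m, copy_ratio = cr, repeat_i = rep_i,
                           region = reg, region_bins = length(bins)),
                prf(tp, fp, fn))
      }
    }
  }
  do.call(rbind, rows)
}

#' Mixture-proportion benchmark
#'
#' Builds an amplified and a diploid cell population from the count-matrix
#' simulator, mixes them at each proportion (without replacement), runs the
#' signal classifier ([classify_signals()]: dip test then GMM or k-means)
#' and scores the labels against the mixture truth.
#'
#' @param proportions positive-cell proportions to sweep.
#' @param n mixture size per draw.
#' @param repeats repeats per proportion (distinct seeds).
#' @param cfg [sim_matrix_config()] for the source populations; the default
#'   simulates 2500 cells (2 of 5 groups amplified) so both pools can
#'   donate up to 90% of a 1000-cell mixture without replacement.
#' @param n_boot dip-test Monte-Carlo replicates.
#' @param seed seed.
#' @return data frame with one row per (proportion, repeat): method used
#'   plus counts and precision / recall / F1.
#' @export
run_mixture_benchmark <- function(proportions = seq(0.1, 0.9, by = 0.1),
                                  n = 1000, repeats = 10,
                                  cfg = sim_matrix_config(n_cells = 2500,
                                                          m = 2,
                                                          copy_ratio = 10),
                                  n_boot = 2000, seed = 1) {
  set.seed(seed)
  baseline <- make_baseline_lambda(cfg)
  bins <- sample_ecdna_bins(cfg, baseline)
  cn <- make_copy_number_matrix(cfg, bins)
  X <- simulate_count_matrix(baseline$lambda, cn$C, cfg$sparse_fac)
  sig <- region_log2_cpm(X, bins)
  pop_pos <- sig[cn$truth_labels & is.finite(sig)]
  pop_neg <- sig[!cn$truth_labels & is.finite(sig)]
  rows <- list()
  for (p in proportions) for (r in seq_len(repeats)) {
    mix <- mix_cells(pop_pos, pop_neg, p, n = n,
                     seed = seed + round(1e4 * p) + 17L * r)
    cls <- classify_signals(mix$values, n_boot = n_boot,
                            seed = seed + round(1e4 * p) + 17L * r)
    tp <- sum(cls$labels & mix$truth); fp <- sum(cls$labels & !mix$truth)
    fn <- sum(!cls$labels & mix$truth)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(proportion = p, repeat_i = r, method = cls$method),
            prf(tp, fp, fn))
  }
  do.call(rbind, rows)
}
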