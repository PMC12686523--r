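#' Count-matrix simulation configuration
#'
#' Bin-by-cell Poisson simulation of ecDNA focal amplification:
#' `X_ij ~ Poisson(sparse_fac * C_ij * lambda_ij)` with baseline Poisson
#' means `lambda`, copy-number matrix `C` (diploid 2 everywhere, amplified
#' entries scaled by the copy ratio) and sparsity factor 0.5, so the
#' diploid expectation equals `lambda`.
#'
#' @param n_cells number of cells (divisible by `n_groups`).
#' @param n_groups equal-sized cell groups.
#' @param m number of amplified groups (`0 <= m < n_groups`).
#' @param copy_ratio focal amplification copy ratio (> 1).
#' @param bin_size bin width, bp.
#' @param n_bins number of genomic bins in the simulated matrix.
#' @param sparse_fac sparsity factor in (0, 1].
#' @param size_range ecDNA region size bounds, bp (lower bound follows the
#'   50 kb protocol; both bounds configurable).
#' @param min_peak_overlap minimum fraction of an ecDNA region's bins that
#'   overlap accessible ("peak", nonzero-lambda) bins; sparser regions are
#'   discarded and resampled.
#' @param n_repeats repeats per grid cell in the benchmark.
#' @param peak_prob,bin_meanlog,bin_sdlog,cell_sdlog synthetic baseline
#'   parameters: Bernoulli peak mask probability, log-normal bin magnitude
#'   and per-cell depth factor.
#' @return list with class `sim_matrix_config`.
#' @export
sim_matrix_config <- function(n_cells = 1000, n_groups = 5, m = 1,
                              copy_ratio = 5, bin_size = 10e3,
                              n_bins = 5000, sparse_fac = 0.5,
                              size_range = c(50e3, 10e6),
                              min_peak_overlap = 0.03, n_repeats = 3,
                              peak_prob = 0.1, bin_meanlog = 0,
                              bin_sdlog = 1, cell_sdlog = 0.3) {
  stopifnot(n_cells %% n_groups == 0, m >= 0, m < n_groups,
            copy_ratio > 1, sparse_fac > 0, sparse_fac <= 1,
            size_range[1] < size_range[2])
  structure(list(n_cells = n_cells, n_groups = n_groups, m = m,
                 copy_ratio = copy_ratio, bin_size = bin_size,
                 n_bins = n_bins, sparse_fac = sparse_fac,
                 size_range = size_range,
                 min_peak_overlap = min_peak_overlap,
                 n_repeats = n_repeats, peak_prob = peak_prob,
                 bin_meanlog = bin_meanlog, bin_sdlog = bin_sdlog,
                 cell_sdlog = cell_sdlog),
            class = "sim_matrix_config")
}

#' Baseline Poisson mean matrix
#'
#' Either learned from a template bins x cells count matrix by rank-one
#' moment matching (`lambda_ij = rowsum_i * colsum_j / total`, which
#' reproduces the template's bin and cell means exactly) or synthesised as
#' (Bernoulli peak mask) x (log-normal bin magnitude) x (log-normal
#' per-cell depth), mimicking the sparsity of 10 kb scATAC bins where most
#' bins carry no accessible signal.
#'
#' @param cfg [sim_matrix_config()].
#' @param template optional template count matrix (bins x cells).
#' @param seed optional seed.
#' @return list: `lambda` (bins x cells), `peak_bins` (indices of bins with
#'   nonzero baseline), `bin_size`.
#' @export
make_baseline_lambda <- function(cfg, template = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(template)) {
    if (!is.null(attr(template, "bin_size")) &&
        attr(template, "bin_size") != cfg$bin_size)
      stop("template bin_size does not match the configuration")
    rs <- rowSums(template); cs <- colSums(template)
    tot <- sum(template)
    if (tot == 0) stop("empty template matrix")
    lambda <- outer(rs, cs) / tot
  } else {
    mask <- stats::rbinom(cfg$n_bins, 1, cfg$peak_prob)
    mag <- stats::rlnorm(cfg$n_bins, cfg$bin_meanlog, cfg$bin_sdlog)
    dep <- stats::rlnorm(cfg$n_cells, 0, cfg$cell_sdlog)
    dep <- dep / mean(dep)
    lambda <- outer(mask * mag, dep)
  }
  list(lambda = lambda, peak_bins = which(rowSums(lambda) > 0),
       bin_size = cfg$bin_size)
}

#' Sample an ecDNA bin region for the matrix simulation
#'
#' Draws a contiguous bin run whose genomic size is log-uniform in
#' `size_range`, resampling until at least `min_peak_overlap` of its bins
#' are accessible (peak) bins -- mirroring the retention rule that ecDNA
#' regions need a minimal overlap with peak regions to be simulable at all.
#'
#' @param cfg [sim_matrix_config()].
#' @param baseline result of [make_baseline_lambda()].
#' @param seed optional seed.
#' @return integer vector of bin indices.
#' @export
sample_ecdna_bins <- function(cfg, baseline, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_bins <- nrow(baseline$lambda)
  for (try in 1:1000) {
    size <- exp(stats::runif(1, log(cfg$size_range[1]),
                             log(cfg$size_range[2])))
    w <- max(1L, min(n_bins, round(size / cfg$bin_size)))
    start <- sample.int(n_bins - w + 1L, 1)
    bins <- start:(start + w - 1L)
    if (mean(bins %in% baseline$peak_bins) >= cfg$min_peak_overlap)
      return(bins)
  }
  stop("could not sample an ecDNA region with the required peak overlap")
}

#' Copy-number matrix for grouped focal amplification
#'
#' Cells are partitioned into `n_groups` equal groups; the first `m` groups
#' are amplified: `C = 2 * copy_ratio` on (ecDNA bins x amplified cells)
#' so the expected count there is `copy_ratio` times the diploid baseline,
#' and `C = 2` (diploid) everywhere else.
#'
#' @param cfg [sim_matrix_config()].
#' @param ecdna_bins bin indices of the amplified region.
#' @return list: `C` (bins x cells), `truth_labels` (logical per cell).
#' @export
make_copy_number_matrix <- function(cfg, ecdna_bins) {
  if (cfg$m >= cfg$n_groups) stop("m must be < n_groups")
  group <- rep(seq_len(cfg$n_groups), each = cfg$n_cells / cfg$n_groups)
  truth <- group <= cfg$m
  C <- matrix(2, nrow = cfg$n_bins, ncol = cfg$n_cells)
  if (cfg$m > 0 && length(ecdna_bins))
    C[ecdna_bins, truth] <- 2 * cfg$copy_ratio
  list(C = C, truth_labels = truth)
}

#' Draw the simulated count matrix
#'
#' Independent draws `X_ij ~ Poisson(sparse_fac * C_ij * lambda_ij)`.
#'
#' @param lambda baseline Poisson mean matrix.
#' @param C copy-number matrix of the same shape.
#' @param sparse_fac sparsity factor in (0, 1].
#' @param seed optional seed.
#' @return integer matrix of the same shape.
#' @export
simulate_count_matrix <- function(lambda, C, sparse_fac = 0.5, seed = NULL) {
  stopifnot(all(dim(lambda) == dim(C)))
  if (any(lambda < 0)) stop("negative lambda")
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(stats::rpois(length(lambda), sparse_fac * C * lambda),
              nrow = nrow(lambda))
  dimnames(X) <- dimnames(lambda)
  X
}

#' Per-cell log2 CPM over a bin region
#'
#' The normalised per-cell signal of a simulated ecDNA region:
#' `log2((counts in region + pseudocount) / total counts * 1e6)`.
#'
#' @param X bins x cells count matrix.
#' @param bins region bin indices.
#' @param pseudocount added to the region count.
#' @return numeric vector per cell (cells with zero totals are NA).
#' @export
region_log2_cpm <- function(X, bins, pseudocount = 1) {
  region <- colSums(X[bins, , drop = FALSE])
  total <- colSums(X)
  out <- log2((region + pseudocount) / total * 1e6)
  out[total == 0] <- NA_real_
  out
}

#' Mix amplified and non-amplified cell populations
#'
#' Samples without replacement `round(proportion * n)` cells from the
#' positive pool and the remainder from the negative pool, attaching truth
#' labels; used for the proportion-sweep benchmark (10%..90% positives).
#'
#' @param pop_pos,pop_neg vectors of per-cell signals (or any per-cell
#'   values) for the two pools.
#' @param proportion fraction of positive cells in the mixture.
#' @param n mixture size.
#' @param seed optional seed.
#' @return list `values`, `truth` (logical), `idx_pos`, `idx_neg`.
#' @export
mix_cells <- function(pop_pos, pop_neg, proportion, n = 1000, seed = NULL) {
  stopifnot(proportion >= 0, proportion <= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- round(proportion * n)
  if (length(pop_pos) < k || length(pop_neg) < n - k)
    stop("insufficient pool for the requested mixture")
  idx_pos <- sample(length(pop_pos), k)
  idx_neg <- sample(length(pop_neg), n - k)
  list(values = c(pop_pos[idx_pos], pop_neg[idx_neg]),
       truth = c(rep(TRUE, k), rep(FALSE, n - k)),
       idx_pos = idx_pos, idx_neg = idx_neg)
}
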