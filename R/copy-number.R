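#' Sliding-window grid with named marker intervals
#'
#' Genome-wide sliding windows (default 5 Mb, 1 Mb step) used for per-cell
#' copy-number signal. `markers` carries named intervals whose matching
#' grid window is reported per cell; the defaults are the canonical
#' oncogene windows used for ecDNA copy estimates on hg38 (EGFR, PDGFRA,
#' MDM4, MDM2, MYC), given here as 0-based half-open coordinates.
#'
#' @param genome named numeric vector of chromosome lengths.
#' @param window window size, bp.
#' @param step window step, bp (`window >= step > 0`).
#' @param markers data frame `name`, `chrom`, `start`, `end` or NULL.
#' @return list with class `window_grid`: `windows` (data frame with
#'   `chrom`, `start`, `end`), `window`, `step`, `markers`.
#' @export
build_windows <- function(genome, window = 5e6, step = 1e6,
                          markers = NULL) {
  stopifnot(window >= step, step > 0)
  rows <- lapply(names(genome), function(chr) {
    len <- genome[[chr]]
    starts <- seq(0, len - 1, by = step)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + window, len), stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, rows)
  structure(list(windows = windows, window = window, step = step,
                 markers = markers), class = "window_grid")
}

#' Default marker intervals for GBM/colon ecDNA oncogenes (hg38)
#' @return data frame `name`, `chrom`, `start`, `end` (0-based half-open).
#' @export
default_cnv_markers <- function() {
  data.frame(
    name = c("EGFR", "PDGFRA", "MDM4", "MDM2", "MYC"),
    chrom = c("chr7", "chr4", "chr1", "chr12", "chr8"),
    start = c(51000000, 52000000, 203000000, 64000000, 124000000),
    end = c(56000000, 57000000, 208000000, 69000000, 129000000),
    stringsAsFactors = FALSE
  )
}

#' Fragment counts per window and cell
#'
#' Counts each fragment once per tiling phase by its midpoint: a fragment
#' whose midpoint falls inside a window is counted there, so totals over
#' any non-overlapping phase of the grid are conserved.
#'
#' @param fragments fragments `data.table`.
#' @param grid a `window_grid`.
#' @param whitelist optional barcode whitelist.
#' @return integer matrix windows x cells.
#' @export
window_cell_counts <- function(fragments, grid, whitelist = NULL) {
  frags <- data.table::as.data.table(fragments)
  if (!is.null(whitelist)) frags <- frags[barcode %in% whitelist]
  barcodes <- sort(unique(frags$barcode))
  w <- grid$windows
  counts <- matrix(0L, nrow = nrow(w), ncol = length(barcodes),
                   dimnames = list(NULL, barcodes))
  if (nrow(frags) == 0L) return(counts)
  mid <- floor((frags$start + frags$end) / 2)
  gr_m <- GenomicRanges::GRanges(frags$chrom,
                                 IRanges::IRanges(mid + 1, mid + 1))
  gr_w <- GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start + 1,
                                                           w$end))
  ov <- quiet_find_overlaps(gr_m, gr_w)
  if (length(ov)) {
    tab <- data.table::data.table(
      win = S4Vectors::subjectHits(ov),
      bc = match(frags$barcode[S4Vectors::queryHits(ov)], barcodes))
    agg <- tab[, .N, by = .(win, bc)]
    counts[cbind(agg$win, agg$bc)] <- agg$N
  }
  counts
}

#' Per-cell window z-scores and copy estimates
#'
#' Per cell: `v = log2(1 + CPM per window)`, `z = (v - trimmed mean) /
#' trimmed SD` over that cell's windows (10% trim by default, robust to the
#' heavy tail amplification creates), and `copy = 2 * CPM / median CPM`
#' (diploid scale). Cells with zero total counts are excluded with a
#' message. Marker rows report the grid window matching each marker
#' interval.
#'
#' @param counts windows x cells matrix from [window_cell_counts()].
#' @param grid the `window_grid`.
#' @param trim trim fraction for the background moments.
#' @return list with class `cnv_profile`: `z` and `copy` (windows x cells),
#'   `markers` (long data frame `barcode`, `marker`, `z`, `copy_estimate`)
#'   when the grid has markers.
#' @export
cnv_zscore <- function(counts, grid, trim = 0.1) {
  if (nrow(counts) < 30)
    warning("fewer than 30 windows; background moments may be unstable")
  totals <- colSums(counts)
  drop <- totals == 0
  if (any(drop)) {
    message(sum(drop), " cell(s) with zero counts excluded")
    counts <- counts[, !drop, drop = FALSE]
    totals <- totals[!drop]
  }
  cpm <- sweep(counts, 2, totals, "/") * 1e6
  v <- log2(1 + cpm)
  tmean <- apply(v, 2, mean, trim = trim)
  tsd <- apply(v, 2, function(col) {
    q <- stats::quantile(col, c(trim, 1 - trim))
    stats::sd(col[col >= q[1] & col <= q[2]])
  })
  tsd[tsd == 0 | is.na(tsd)] <- 1
  z <- sweep(sweep(v, 2, tmean), 2, tsd, "/")
  med <- apply(cpm, 2, stats::median)
  med[med == 0] <- NA
  copy <- sweep(cpm, 2, med, "/") * 2
  markers <- NULL
  if (!is.null(grid$markers)) {
    w <- grid$windows
    idx <- vapply(seq_len(nrow(grid$markers)), function(i) {
      hit <- which(w$chrom == grid$markers$chrom[i] &
                     w$start == grid$markers$start[i] &
                     w$end == grid$markers$end[i])
      if (length(hit)) hit[1] else
        which.max((w$chrom == grid$markers$chrom[i]) *
                    -abs(w$start - grid$markers$start[i]))
    }, integer(1))
    markers <- do.call(rbind, lapply(seq_along(idx), function(i)
      data.frame(barcode = colnames(counts),
                 marker = grid$markers$name[i],
                 z = z[idx[i], ], copy_estimate = copy[idx[i], ],
                 row.names = NULL, stringsAsFactors = FALSE)))
  }
  structure(list(z = z, copy = copy, markers = markers),
            class = "cnv_profile")
}
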