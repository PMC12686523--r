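#' Per-cell normalised signal within an ecDNA region
#'
#' For each whitelisted barcode, counts the fragments overlapping any
#' candidate segment and normalises to counts per million per cell:
#' `log2_eccpm = log2((reads_in_ecdna + pseudocount) / total_reads * 1e6)`.
#' The pseudocount keeps zero-signal cells finite so the mixture fit can
#' ingest them.
#'
#' @param fragments fragments `data.table` (`chrom`, `start`, `end`,
#'   `barcode`, `support`).
#' @param ecdna an [ecdna_candidate()] (or a plain interval data frame).
#' @param whitelist character vector of qualified barcodes.
#' @param pseudocount added to `reads_in_ecdna` before CPM.
#' @return `data.table` with `barcode`, `reads_in_ecdna`, `total_reads`,
#'   `log2_eccpm`; cells with zero total reads are excluded.
#' @export
compute_cell_signals <- function(fragments, ecdna, whitelist,
                                 pseudocount = 1) {
  if (length(whitelist) == 0L) stop("empty barcode whitelist")
  region <- if (inherits(ecdna, "ecdna_candidate"))
    candidate_intervals(ecdna) else merge_intervals(ecdna)
  frags <- data.table::as.data.table(fragments)[barcode %in% whitelist]
  totals <- frags[, .(total_reads = .N), by = barcode]
  gr_f <- GenomicRanges::GRanges(frags$chrom,
                                 IRanges::IRanges(frags$start + 1, frags$end))
  hits <- quiet_count_overlaps(gr_f, gi_to_gr(region)) > 0
  inside <- frags[hits, .(reads_in_ecdna = .N), by = barcode]
  sig <- merge(totals, inside, by = "barcode", all.x = TRUE)
  sig[is.na(reads_in_ecdna), reads_in_ecdna := 0L]
  sig <- sig[total_reads > 0]
  sig[, log2_eccpm := log2((reads_in_ecdna + pseudocount) /
                             total_reads * 1e6)]
  data.table::setorder(sig, barcode)
  sig[, .(barcode, reads_in_ecdna, total_reads, log2_eccpm)]
}

#' Gene-score matrix over a gene set
#'
#' A dense surrogate for sparse peak signals: per cell and gene,
#' `log2(1 + CPM)` of the fragments overlapping the gene body extended
#' `promoter_ext` bp upstream (by strand), then per-gene standardised to
#' zero mean and unit variance across cells. Genes with no fragments in any
#' cell are dropped with a message.
#'
#' @param fragments fragments `data.table`.
#' @param genes data frame `name`, `chrom`, `start`, `end`, `strand`.
#' @param whitelist character vector of qualified barcodes.
#' @param promoter_ext upstream promoter extension, bp.
#' @return cells x genes numeric matrix (rownames = barcodes).
#' @export
gene_score_matrix <- function(fragments, genes, whitelist,
                              promoter_ext = 2000) {
  stopifnot(nrow(genes) > 0L)
  frags <- data.table::as.data.table(fragments)[barcode %in% whitelist]
  ext_start <- ifelse(genes$strand == "-", genes$start,
                      pmax(0, genes$start - promoter_ext))
  ext_end <- ifelse(genes$strand == "-", genes$end + promoter_ext,
                    genes$end)
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(ext_start + 1, ext_end))
  gr_f <- GenomicRanges::GRanges(frags$chrom,
                                 IRanges::IRanges(frags$start + 1, frags$end))
  ov <- quiet_find_overlaps(gr_f, gr_g)
  barcodes <- sort(unique(frags$barcode))
  totals <- frags[, .N, by = barcode]
  tot <- stats::setNames(totals$N, totals$barcode)[barcodes]
  counts <- matrix(0, nrow = length(barcodes), ncol = nrow(genes),
                   dimnames = list(barcodes, genes$name))
  if (length(ov)) {
    tab <- data.table::data.table(
      bc = frags$barcode[S4Vectors::queryHits(ov)],
      gene = S4Vectors::subjectHits(ov))
    agg <- tab[, .N, by = .(bc, gene)]
    counts[cbind(match(agg$bc, barcodes), agg$gene)] <- agg$N
  }
  keep <- colSums(counts) > 0
  if (!all(keep))
    message(sum(!keep), " gene(s) with zero fragments dropped")
  counts <- counts[, keep, drop = FALSE]
  if (ncol(counts) == 0L) stop("no gene has any fragment coverage")
  cpm <- log2(1 + counts / tot * 1e6)
  scale(cpm)
}

#' k-means cell assignment on a gene-score matrix
#'
#' Best-of-`n_restarts` k-means (k = 2); the amplified cluster is the one
#' with the higher mean row-sum of scores, so the label is invariant to
#' cluster-index permutation.
#'
#' @param scores cells x genes matrix from [gene_score_matrix()].
#' @param k number of clusters.
#' @param n_restarts random restarts.
#' @param seed optional seed.
#' @return logical vector per cell (TRUE = ecDNA-positive), named by
#'   rownames of `scores`.
#' @export
kmeans_assign <- function(scores, k = 2, n_restarts = 10, seed = NULL) {
  stopifnot(ncol(scores) >= 1)
  if (nrow(scores) < k) stop("fewer cells than clusters")
  if (!is.null(seed)) set.seed(seed)
  km <- suppressWarnings(stats::kmeans(scores, centers = k,
                                       nstart = n_restarts))
  cluster_mean <- tapply(rowSums(scores), km$cluster, mean)
  pos_cluster <- as.integer(names(cluster_mean)[which.max(cluster_mean)])
  stats::setNames(km$cluster == pos_cluster, rownames(scores))
}

#' Gold-standard barcodes from discordant reads at candidate junctions
#'
#' Cells owning at least one discordant read pair or clipped read whose
#' breakend falls within `window` bp of any candidate junction breakend.
#' These cells carry direct structural evidence of the circle and anchor
#' the Fisher validation of the classifier.
#'
#' @param aln alignment record table (barcoded).
#' @param junctions `bp_junctions` of the detected candidate.
#' @param window matching window around junction breakends, bp.
#' @param insert_cutoff template-length cutoff for discordance, bp.
#' @return character vector of barcodes (set semantics).
#' @export
extract_discordant_barcodes <- function(aln, junctions, window = 500,
                                        insert_cutoff = 1000) {
  if (nrow(junctions) == 0L) return(character())
  aln <- data.table::as.data.table(aln)[secondary == FALSE &
                                          !is.na(barcode)]
  disc <- aln[classify_discordant(aln, insert_cutoff)]
  clip <- aln[clip_left > 0 | clip_right > 0]
  ends <- rbind(
    disc[, .(chrom, pos = ifelse(strand == "+", end, pos), barcode)],
    clip[clip_left > 0, .(chrom, pos = pos, barcode)],
    clip[clip_right > 0, .(chrom, pos = end, barcode)]
  )
  if (nrow(ends) == 0L) return(character())
  bps <- rbind(
    data.frame(chrom = junctions$chrom_a, pos = junctions$pos_a),
    data.frame(chrom = junctions$chrom_b, pos = junctions$pos_b)
  )
  near <- rep(FALSE, nrow(ends))
  for (i in seq_len(nrow(bps)))
    near <- near | (ends$chrom == bps$chrom[i] &
                      abs(ends$pos - bps$pos[i]) <= window)
  sort(unique(ends$barcode[near]))
}

#' One-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric tail probability; with table
#' `[[a, b], [c, d]]` and `alternative = "greater"` the p-value is
#' `P(X >= a)` for `X ~ Hypergeom`. The odds ratio is the sample ratio
#' `(a d)/(b c)` (Inf when `b c = 0` and `a d > 0`). A zero row or column
#' margin gives p = 1 and an NA odds ratio.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return list `p_value`, `odds_ratio`.
#' @export
fisher_exact <- function(table, alternative = c("greater", "less",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(table), all(dim(table) == 2L),
            all(table >= 0), all(table == round(table)))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + c; n2 <- b + d; k <- a + b
  if (m == 0 || n2 == 0 || k == 0 || (c + d) == 0)
    return(list(p_value = 1, odds_ratio = NA_real_))
  p <- switch(alternative,
    greater = stats::phyper(a - 1, m, n2, k, lower.tail = FALSE),
    less = stats::phyper(a, m, n2, k),
    two.sided = {
      dobs <- stats::dhyper(a, m, n2, k)
      supp <- max(0, k - n2):min(k, m)
      sum(stats::dhyper(supp, m, n2, k)[
        stats::dhyper(supp, m, n2, k) <= dobs * (1 + 1e-7)])
    })
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * c)
  list(p_value = min(1, p), odds_ratio = or)
}

#' Classify per-cell signals as amplified / not amplified
#'
#' The decision core shared by [assign_ecdna()] and the mixture benchmark:
#' a dip test decides whether the signal distribution is multimodal; if
#' `dip p < alpha` a two-component GMM labels cells by posterior for the
#' higher-mean component, otherwise labels come from k-means (on the
#' gene-score matrix when available, else on the signal itself).
#'
#' @param values per-cell `log2_eccpm` signal.
#' @param scores optional cells x genes gene-score matrix for the k-means
#'   branch (rows aligned with `values`).
#' @param alpha dip-test significance level.
#' @param n_boot dip-test Monte-Carlo replicates.
#' @param threshold GMM posterior threshold.
#' @param seed optional seed.
#' @return list `labels` (logical), `method` (`"gmm"`/`"kmeans"`),
#'   `dip` (`dip_test`), `fit` (`mixture_fit` or NULL).
#' @export
classify_signals <- function(values, scores = NULL, alpha = 0.05,
                             n_boot = 2000, threshold = 0.5, seed = NULL) {
  dip <- dip_test(values, n_boot = n_boot, seed = seed)
  if (dip$p_value < alpha) {
    fit <- fit_two_component_gmm(values, seed = seed)
    labels <- assign_by_gmm(fit, threshold)
    list(labels = labels, method = "gmm", dip = dip, fit = fit)
  } else {
    sc <- if (is.null(scores)) matrix(values, ncol = 1) else scores
    labels <- unname(kmeans_assign(sc, seed = seed))
    list(labels = labels, method = "kmeans", dip = dip, fit = NULL)
  }
}

#' Assign an ecDNA candidate to individual cells
#'
#' Computes per-cell `log2_eccpm` within the candidate, tests for
#' multimodality, classifies cells by GMM or gene-score k-means, extracts
#' discordant-read gold-standard cells from the alignments and validates
#' the classification with a one-sided Fisher's exact test (are predicted
#' ecDNA-positive cells enriched for direct junction evidence?).
#'
#' @param fragments fragments `data.table`.
#' @param aln alignment record table (for gold-standard extraction); may be
#'   NULL to skip the Fisher step.
#' @param candidate an [ecdna_candidate()].
#' @param whitelist character vector of qualified barcodes (>= 10 cells).
#' @param genes optional gene table for the k-means branch (see
#'   [gene_score_matrix()]); genes overlapping the candidate are used.
#' @param alpha dip significance level; `p < alpha` selects the GMM branch.
#' @param n_boot dip Monte-Carlo replicates.
#' @param pseudocount see [compute_cell_signals()].
#' @param seed optional seed.
#' @return list with class `assignment_result`: `cells` (signal table plus
#'   `label`, `responsibility`), `method`, `dip_p`, `fit`, `fisher_p`,
#'   `odds_ratio`, `gold_standard_barcodes`.
#' @export
assign_ecdna <- function(fragments, aln, candidate, whitelist,
                         genes = NULL, alpha = 0.05, n_boot = 2000,
                         pseudocount = 1, seed = NULL) {
  sig <- compute_cell_signals(fragments, candidate, whitelist, pseudocount)
  if (nrow(sig) < 10)
    stop("underpowered assignment: fewer than 10 qualified cells")
  scores <- NULL
  if (!is.null(genes)) {
    region <- candidate_intervals(candidate)
    gr_g <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$start + 1,
                                                    genes$end))
    on_ec <- quiet_count_overlaps(gr_g, gi_to_gr(region)) > 0
    if (any(on_ec)) {
      scores <- gene_score_matrix(fragments, genes[on_ec, , drop = FALSE],
                                  whitelist)
      scores <- scores[match(sig$barcode, rownames(scores)), , drop = FALSE]
    }
  }
  cls <- classify_signals(sig$log2_eccpm, scores = scores, alpha = alpha,
                          n_boot = n_boot, seed = seed)
  sig[, label := ifelse(cls$labels, "ecDNA+", "ecDNA-")]
  sig[, responsibility := if (cls$method == "gmm")
    cls$fit$responsibilities else as.numeric(cls$labels)]
  gold <- character()
  fisher <- list(p_value = NA_real_, odds_ratio = NA_real_)
  if (!is.null(aln)) {
    gold <- extract_discordant_barcodes(aln, candidate$junctions)
    in_gold <- sig$barcode %in% gold
    tab <- matrix(c(sum(cls$labels & in_gold), sum(cls$labels & !in_gold),
                    sum(!cls$labels & in_gold), sum(!cls$labels & !in_gold)),
                  nrow = 2, byrow = TRUE)
    fisher <- fisher_exact(tab, alternative = "greater")
  }
  structure(list(cells = sig[], method = cls$method,
                 dip_p = cls$dip$p_value, fit = cls$fit,
                 fisher_p = fisher$p_value, odds_ratio = fisher$odds_ratio,
                 gold_standard_barcodes = gold),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  n_pos <- sum(x$cells$label == "ecDNA+")
  cat(sprintf("ecDNA assignment over %d cells: %d ecDNA+ / %d ecDNA- (%s)\n",
              nrow(x$cells), n_pos, nrow(x$cells) - n_pos, x$method))
  cat(sprintf("  dip p = %.4g; Fisher p = %.4g, OR = %.3g; %d gold cells\n",
              x$dip_p, x$fisher_p, x$odds_ratio,
              length(x$gold_standard_barcodes)))
  invisible(x)
}

#' Write an assignment result to disk
#'
#' Emits the per-cell TSV (barcode, counts, signal, label, responsibility)
#' and a JSON summary (dip p, method, mixture parameters, Fisher p, odds
#' ratio, number of gold-standard cells).
#'
#' @param result an `assignment_result`.
#' @param dir output directory (created if needed).
#' @export
write_assignment <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary <- list(dip_p = result$dip_p, method = result$method,
                  fisher_p = result$fisher_p,
                  odds_ratio = result$odds_ratio,
                  n_gold = length(result$gold_standard_barcodes))
  if (!is.null(result$fit))
    summary$mixture <- result$fit[c("w", "mu1", "mu2", "sigma1", "sigma2")]
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
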