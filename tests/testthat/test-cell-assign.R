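frag_row <- function(chrom, start, end, barcode) {
  data.table::data.table(chrom = chrom, start = start, end = end,
                         barcode = barcode, support = 1L)
}

test_that("per-cell ecCPM follows the printed normalisation", {
  region <- ecdna_candidate(
    "e", data.frame(chrom = "chr1", start = 0, end = 1e6, strand = "+"),
    bp_junctions("chr1", 1e6, "right", "chr1", 0, "left"))
  # one cell: 100 reads inside out of 1e6 total
  frags <- rbind(
    frag_row("chr1", seq(0, by = 100, length.out = 100),
             seq(0, by = 100, length.out = 100) + 50, "A"),
    frag_row("chr2", seq(0, by = 10, length.out = 1e6 - 100),
             seq(0, by = 10, length.out = 1e6 - 100) + 5, "A"))
  sig <- compute_cell_signals(frags, region, "A", pseudocount = 0)
  expect_equal(sig$reads_in_ecdna, 100L)
  expect_equal(sig$total_reads, 1000000L)
  expect_equal(sig$log2_eccpm, log2(100), tolerance = 1e-12)
  # zero signal with the default pseudocount
  frags0 <- frag_row("chr2", seq(0, by = 10, length.out = 1e6),
                     seq(0, by = 10, length.out = 1e6) + 5, "B")
  sig0 <- compute_cell_signals(frags0, region, "B", pseudocount = 1)
  expect_equal(sig0$log2_eccpm, 0)
  expect_error(compute_cell_signals(frags, region, character()))
})

test_that("cell signals match a naive group-by oracle and are monotone", {
  set.seed(44)
  region <- ecdna_candidate(
    "e", data.frame(chrom = "chr1", start = 1e5, end = 3e5, strand = "+"),
    bp_junctions("chr1", 3e5, "right", "chr1", 1e5, "left"))
  bcs <- sprintf("C%02d", 1:20)
  n <- 3000
  frags <- frag_row(sample(c("chr1", "chr2"), n, TRUE),
                    s <- sample(0:5e5, n, TRUE), s + 100,
                    sample(bcs, n, TRUE))
  sig <- compute_cell_signals(frags, region, bcs)
  for (i in sample(nrow(sig), 5)) {
    bc <- sig$barcode[i]
    sub <- frags[barcode == bc]
    inside <- sub$chrom == "chr1" & sub$start < 3e5 & sub$end > 1e5
    expect_equal(sig$reads_in_ecdna[i], sum(inside))
    expect_equal(sig$total_reads[i], nrow(sub))
    expect_equal(sig$log2_eccpm[i],
                 log2((sum(inside) + 1) / nrow(sub) * 1e6))
  }
  # monotone in reads_in_ecdna at fixed total: three cells, 50 fragments
  # each, with 5 / 20 / 40 inside the region
  fixed <- data.table::rbindlist(lapply(seq_along(k <- c(5, 20, 40)),
    function(i) {
      inside <- frag_row("chr1", rep(2e5, k[i]), rep(2.1e5, k[i]),
                         sprintf("M%d", i))
      outside <- frag_row("chr2", rep(1e3, 50 - k[i]), rep(2e3, 50 - k[i]),
                          sprintf("M%d", i))
      rbind(inside, outside)
    }))
  sigf <- compute_cell_signals(fixed, region, sprintf("M%d", 1:3))
  expect_true(all(diff(sigf$log2_eccpm[order(sigf$reads_in_ecdna)]) > 0))
})

test_that("gene scores count promoter-extended overlaps then standardise", {
  genes <- data.frame(name = c("g1", "g2"),
                      chrom = c("chr1", "chr1"),
                      start = c(10e3, 50e3), end = c(20e3, 60e3),
                      strand = c("+", "-"))
  # no fragments in any gene: error after dropping all columns
  off <- frag_row("chr2", 1:10 * 100, 1:10 * 100 + 50,
                  rep(c("A", "B"), 5))
  expect_error(suppressMessages(gene_score_matrix(off, genes, c("A", "B"))))
  # all fragments inside g1's body: single informative column
  inb <- rbind(frag_row("chr1", rep(12e3, 6), rep(12.1e3, 6),
                        c("A", "A", "A", "B", "B", "C")),
               frag_row("chr2", rep(1e3, 3), rep(1.1e3, 3),
                        c("A", "B", "C")))
  sc <- suppressMessages(gene_score_matrix(inb, genes, c("A", "B", "C")))
  expect_equal(colnames(sc), "g1")
  expect_equal(rownames(sc), c("A", "B", "C"))
  expect_equal(mean(sc[, 1]), 0, tolerance = 1e-12)
  expect_gt(sc["A", 1], sc["C", 1])
  # promoter extension: fragment 1.5 kb upstream of g1 counts for g1,
  # and 1.5 kb downstream of g2 (minus strand promoter) counts for g2
  pro <- rbind(frag_row("chr1", 8500, 8600, "A"),
               frag_row("chr1", 61e3, 61.1e3, "B"),
               frag_row("chr2", rep(1e3, 2), rep(1.1e3, 2), c("A", "B")))
  sc2 <- suppressMessages(gene_score_matrix(pro, genes, c("A", "B")))
  expect_equal(dim(sc2), c(2L, 2L))
  expect_gt(sc2["A", "g1"], sc2["B", "g1"])
  expect_gt(sc2["B", "g2"], sc2["A", "g2"])
})

test_that("k-means assignment recovers separated groups symmetrically", {
  set.seed(45)
  scores <- rbind(matrix(rnorm(40 * 3, 0), ncol = 3),
                  matrix(rnorm(25 * 3, 6), ncol = 3))
  rownames(scores) <- sprintf("B%02d", 1:65)
  lab <- kmeans_assign(scores, seed = 7)
  expect_identical(unname(lab), c(rep(FALSE, 40), rep(TRUE, 25)))
  # invariance of the semantics to row permutation
  perm <- sample(65)
  lab2 <- kmeans_assign(scores[perm, ], seed = 7)
  expect_identical(lab2[rownames(scores)], lab)
  expect_error(kmeans_assign(scores[1, , drop = FALSE]))
})

test_that("discordant gold-standard barcodes come from junction evidence", {
  jx <- bp_junctions("chr1", 5000, "right", "chr2", 9000, "left", 10L, 0L)
  expect_identical(extract_discordant_barcodes(
    aln_row(1, "chr1", 100, 150, barcode = "A"), jx), character())
  prs <- rbind(disc_pair(1, "chr1", 5000, "chr2", 9000, barcode = "A"),
               disc_pair(2, "chr1", 5010, "chr2", 9005, barcode = "A"),
               disc_pair(3, "chr1", 4990, "chr2", 9010, barcode = "B"),
               disc_pair(4, "chr1", 900e3, "chr2", 700e3, barcode = "C"))
  got <- extract_discordant_barcodes(prs, jx, window = 500)
  expect_identical(got, c("A", "B"))  # C far away; A collapses to one entry
})

test_that("Fisher exact equals hypergeometric enumeration", {
  # balanced table: observed count equals its expectation, upper tail
  # includes the mode (the stats::fisher.test convention)
  bal <- fisher_exact(matrix(c(5, 5, 5, 5), 2))
  expect_equal(bal$p_value,
               stats::fisher.test(matrix(c(5, 5, 5, 5), 2),
                                  alternative = "greater")$p.value,
               tolerance = 1e-9)
  expect_equal(bal$odds_ratio, 1)
  strong <- fisher_exact(matrix(c(10, 0, 0, 10), 2))
  expect_equal(strong$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_identical(strong$odds_ratio, Inf)
  expect_equal(fisher_exact(matrix(c(0, 10, 10, 0), 2))$p_value, 1)
  expect_true(is.na(fisher_exact(matrix(c(0, 0, 3, 4), 2))$odds_ratio))

  # full enumeration over random tables with margins <= 30, plus the
  # independent stats::fisher.test cross-check
  set.seed(46)
  for (rep in 1:40) {
    m <- sample(1:30, 1); n2 <- sample(1:30, 1); k <- sample(1:(m + n2), 1)
    rng <- max(0, k - n2):min(k, m)
    a <- rng[sample.int(length(rng), 1)]
    tab <- matrix(c(a, m - a, k - a, n2 - k + a), 2)  # cols: gold yes/no
    got <- fisher_exact(tab, "greater")
    supp <- max(0, k - n2):min(k, m)
    probs <- choose(m, supp) * choose(n2, k - supp) / choose(m + n2, k)
    expect_equal(got$p_value, sum(probs[supp >= a]), tolerance = 1e-9)
    expect_equal(got$p_value,
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("assign_ecdna takes the GMM branch on bimodal libraries and
           validates against gold-standard cells", {
  bcs <- sprintf("BC%04d", 1:100)
  pos <- bcs[1:40]
  g <- tiny_genome(3, 4e6)
  set.seed(49)
  truth <- simulate_ecdna_structures(g, n_circles = 1,
                                     size_range = c(250e3, 400e3),
                                     max_segments = 2)
  lib <- quiet(simulate_library(truth, g, sim_read_config(
    background_depth = 4, circle_depth = 12, barcodes = bcs,
    circle_cells = setNames(list(pos), truth[[1]]$id))))
  frags <- fragments_from_alignments(lib)
  res <- quiet(assign_ecdna(frags, lib, truth[[1]], whitelist = bcs,
                            n_boot = 500, seed = 2))
  expect_equal(res$method, "gmm")
  expect_lt(res$dip_p, 0.05)
  expect_lt(res$fisher_p, 0.05)
  expect_true(all(res$gold_standard_barcodes %in% pos))
  pred <- res$cells$barcode[res$cells$label == "ecDNA+"]
  acc <- mean(c(pred %in% pos, setdiff(bcs, pred) %in% setdiff(bcs, pos)))
  expect_gt(acc, 0.95)
  expect_error(assign_ecdna(frags, lib, truth[[1]], whitelist = bcs[1:5]))
})

test_that("assign_ecdna falls back to k-means when signals are unimodal", {
  # a region nobody is amplified in: unimodal background signal
  g <- tiny_genome(2, 3e6)
  set.seed(50)
  bcs <- sprintf("BC%04d", 1:80)
  lib <- quiet(simulate_library(list(), g, sim_read_config(
    background_depth = 6, circle_depth = 0, barcodes = bcs)))
  frags <- fragments_from_alignments(lib)
  cand <- ecdna_candidate(
    "flat", data.frame(chrom = "chr1", start = 1e6, end = 1.4e6,
                       strand = "+"),
    bp_junctions("chr1", 1.4e6, "right", "chr1", 1e6, "left"))
  genes <- data.frame(name = c("gA", "gB"), chrom = "chr1",
                      start = c(1.05e6, 1.2e6), end = c(1.1e6, 1.3e6),
                      strand = c("+", "-"))
  res <- quiet(assign_ecdna(frags, NULL, cand, whitelist = bcs,
                            genes = genes, n_boot = 500, seed = 3))
  expect_equal(res$method, "kmeans")
  expect_gte(res$dip_p, 0.05)
  expect_true(is.na(res$fisher_p))
})
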