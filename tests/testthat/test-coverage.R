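toy_reads <- function(n, contig_len = 50000, seed = 1) {
  set.seed(seed)
  gr <- GRanges("chrT", IRanges(sample.int(contig_len - 300, n,
                                           replace = TRUE), width = 1),
                strand = sample(c("+", "-"), n, replace = TRUE))
  seqlengths(gr) <- c(chrT = contig_len)
  gr
}

test_that("read extension and scaling behave as defined", {
  gr <- GRanges("chrT", IRanges(100, width = 1), strand = "+")
  seqlengths(gr) <- c(chrT = 1000)
  trk <- build_coverage(gr, extension = 250, target_depth = 1)
  d <- as.numeric(trk$plus$chrT)
  expect_equal(which(d > 0), 100:349)          # [100, 350) in 0-based terms
  expect_true(all(d[100:349] == 1))
  expect_equal(trk$scale_factor, 1)
  ## 20 M reads -> scale factor exactly 1 by construction
  expect_equal(build_coverage(gr, target_depth = 1)$total_reads, 1L)
  expect_error(build_coverage(gr[0]), "zero mapped reads")
})

test_that("pileup equals a naive per-read oracle and conserves depth", {
  gr <- toy_reads(1000, seed = 2)
  trk <- build_coverage(gr, extension = 250, target_depth = 1000)
  for (str in c("+", "-")) {
    rs <- gr[strand(gr) == str]
    ext_start <- if (str == "+") start(rs) else pmax(1L, start(rs) - 249L)
    ext_end <- if (str == "+") pmin(50000L, start(rs) + 249L) else start(rs)
    oracle <- naive_pileup(ext_start, ext_end, 50000)
    got <- as.numeric((if (str == "+") trk$plus else trk$minus)$chrT)
    expect_identical(got, oracle)
  }
  ## conservation: sum of normalized depth = target_depth * extension
  gr2 <- toy_reads(500, contig_len = 50000, seed = 3)
  gr2 <- shift(gr2, 300)  # keep extensions clear of contig bounds
  trk2 <- build_coverage(gr2, extension = 100, target_depth = 2e4)
  expect_equal(sum(as.numeric(trk2$plus$chrT)) +
                 sum(as.numeric(trk2$minus$chrT)), 2e4 * 100)
})

test_that("transcript selection keeps the longest isoform at >= 30 kb", {
  ann <- make_annotation(50, c(20000, 80000), ale_fraction = 0.5, seed = 4)
  sel <- select_transcripts(ann)
  ## independent re-filter: scan the raw table
  tx <- ann$transcripts
  by_gene <- split(seq_along(tx), tx$gene_id)
  expected <- vapply(by_gene, function(ix) {
    w <- width(tx)[ix]
    best <- ix[order(-w, tx$transcript_id[ix])][1]
    if (width(tx)[best] >= 30000) tx$transcript_id[best] else NA_character_
  }, character(1))
  expected <- sort(unname(expected[!is.na(expected)]))
  expect_identical(sort(sel$transcript_id), expected)
  expect_true(all(width(sel) >= 30000))
  expect_true(!any(duplicated(sel$gene_id)))
})

test_that("gene windows are TSS-anchored and strand-oriented", {
  ## hand-built coverage: ramp on + strand, mirrored ramp on - strand
  gr_p <- GRanges("chrT", IRanges(48000:48009, width = 1), strand = "+")
  gr_m <- GRanges("chrT", IRanges(52000:52009, width = 1), strand = "-")
  gr <- c(gr_p, gr_m)
  seqlengths(gr) <- c(chrT = 200000)
  trk <- build_coverage(gr, extension = 1, target_depth = 20)
  tx_p <- GRanges("chrT", IRanges(50000, 90000), strand = "+")
  mcols(tx_p)$gene_id <- "GP"
  tx_m <- GRanges("chrT", IRanges(10000, 50009), strand = "-")
  mcols(tx_m)$gene_id <- "GM"
  wp <- gene_window(trk, tx_p)
  expect_equal(length(wp$depth), 122001L)
  expect_equal(wp$offsets[1], -2000L)
  ## + gene: reads at 48000..48009 sit at offsets -2000..-1991
  expect_equal(which(wp$depth > 0), 1:10)
  ## - gene with TSS at 50009: reads at 52000..52009 are upstream
  ## offsets -1991..-2000; window reversal puts them at the start
  wm <- gene_window(trk, tx_m)
  expect_equal(which(wm$depth > 0), 1:10)
  ## truncation flag when the window leaves the contig
  tx_edge <- GRanges("chrT", IRanges(500, 40000), strand = "+")
  mcols(tx_edge)$gene_id <- "GE"
  expect_true(gene_window(trk, tx_edge)$truncated)
  expect_false(wp$truncated)
})

test_that("trimmed-mean meta-profile matches a sort-drop-average oracle", {
  set.seed(5)
  depths <- lapply(1:20, function(i) rpois(101, 4) + i)
  wins <- lapply(seq_along(depths), function(i)
    make_window(depths[[i]], gene_id = paste0("G", i)))
  mp <- metagene(wins, trim = 0.05)
  expect_equal(mp$n_genes, 20L)
  for (k in c(1, 50, 101)) {
    vals <- vapply(depths, `[`, numeric(1), k)
    expect_equal(mp$depth[k], sort_trim_mean(vals, 0.05))
  }
  ## trim 0 is the arithmetic mean; identical windows reproduce any one
  mp0 <- metagene(wins, trim = 0)
  expect_equal(mp0$depth[7], mean(vapply(depths, `[`, numeric(1), 7)))
  same <- metagene(wins[c(1, 1, 1)], trim = 0.05)
  expect_equal(same$depth, depths[[1]])
  expect_error(metagene(wins, trim = 0.5), "trim")
})

test_that("single-gene profile bins log-depth and smooths it", {
  w <- make_window(rep(3, 2500))
  p <- single_gene_profile(w, bin = 500)
  expect_equal(p$raw, rep(log2(4), 5))
  expect_equal(p$smooth, rep(log2(4), 5), tolerance = 1e-6)
  ## one bin spanning the window
  p1 <- single_gene_profile(w, bin = 2500)
  expect_equal(p1$raw, log2(4))
  ## step profile: raw bin means equal a manual block average
  step <- make_window(c(rep(8, 1000), rep(2, 1500)))
  ps <- single_gene_profile(step, bin = 500)
  expect_equal(ps$raw, c(log2(9), log2(9), log2(3), log2(3), log2(3)))
  expect_error(single_gene_profile(make_window(rep(1, 10)), bin = 500),
               "shorter")
})

test_that("rpkm matches its unit definition and a brute-force count", {
  gr <- GRanges("chrT", IRanges(1500, width = 1), strand = "+")
  seqlengths(gr) <- c(chrT = 100000)
  iv <- GRanges("chrT", IRanges(1001, 2000), strand = "+")
  expect_equal(rpkm(gr, iv, total_mapped_reads = 1e6), 1.0)
  expect_equal(rpkm(gr, shift(iv, 5000), total_mapped_reads = 1e6), 0.0)
  expect_error(rpkm(gr, GRanges("chrT", IRanges(10, 9))), "zero-length")
  ## random toy set vs brute-force overlap count
  rs <- toy_reads(2000, seed = 6)
  trk <- build_coverage(rs, extension = 250, target_depth = 2000)
  iv2 <- GRanges("chrT", IRanges(20001, 25000), strand = "+")
  ext <- trk$reads[strand(trk$reads) == "+"]
  brute <- sum(start(ext) <= 25000 & end(ext) >= 20001)
  expect_equal(rpkm(trk, iv2), brute * 1e9 / (5000 * 2000))
})

test_that("downstream recovery normalizes region means to untreated", {
  base <- make_window(rep(2, 122001), first_offset = -2000L)
  half <- make_window(rep(1, 122001), first_offset = -2000L)
  r <- downstream_recovery(list(UN = list(base), UV2h = list(half),
                                UV8h = list(base)))
  expect_equal(unname(r), c(1, 0.5, 1))
  expect_error(downstream_recovery(list(UV = list(base))), "untreated")
  zero <- make_window(rep(0, 122001), first_offset = -2000L)
  expect_error(downstream_recovery(list(UN = list(zero))), "zero")
})
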