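test_that("the island caller finds the transition point", {
  cfg <- analysis_config()
  ## depth >= 3 over [0, 10000), zero after: front at the last covered bp
  w <- make_window(c(rep(5, 10000), rep(0, 110001)), first_offset = 0L)
  cl <- call_wavefront(w, cfg)
  expect_equal(cl$position, 9999)
  expect_equal(cl$status, "called")
  expect_length(cl$flags, 0)

  ## sub-gap interruptions do not halt; the first qualifying gap does
  d <- c(rep(5, 2000), rep(0, 4999), rep(5, 1000), rep(0, 4999),
         rep(5, 500), rep(0, 6000), rep(5, 3000))
  d <- c(d, rep(0, 120001 - length(d)))
  cl2 <- call_wavefront(make_window(d, first_offset = 0L), cfg)
  expect_equal(cl2$position, 2000 + 4999 + 1000 + 4999 + 500 - 1)

  ## all-zero window: no island
  cl3 <- call_wavefront(make_window(rep(0, 120001), first_offset = 0L), cfg)
  expect_equal(cl3$status, "no_island")
  expect_true(is.na(cl3$position))

  ## signal to the window end: called at last covered bp, flagged
  cl4 <- call_wavefront(make_window(rep(4, 20000), first_offset = 0L), cfg)
  expect_equal(cl4$position, 19999)
  expect_equal(cl4$flags, "window_end")

  expect_error(call_wavefront(make_window(rep(1, 100), first_offset = 0L),
                              cfg, exon_mask = 0:99), "masked")
})

test_that("masked exonic bases neither extend nor break islands", {
  cfg <- analysis_config()
  ## contamination spike inside a long gap: without the mask it would
  ## restart the island and push the front downstream
  d <- c(rep(5, 3000), rep(0, 3000), rep(9, 200), rep(0, 3000))
  d <- c(d, rep(0, 20001 - length(d)))
  spike <- 6000:6199
  with_mask <- call_wavefront(make_window(d, first_offset = 0L), cfg,
                              exon_mask = spike)
  expect_equal(with_mask$position, 2999)    # 3000+3000+3000 unmasked gap
  without <- call_wavefront(make_window(d, first_offset = 0L), cfg)
  expect_equal(without$position, 6199)      # spike ends the gap count
  ## masked sub-threshold bases do not count toward the gap either:
  ## 4000 real zeros + 2000 masked zeros + 4000 real zeros is one
  ## 8000-bp unmasked gap
  d2 <- c(rep(5, 1000), rep(0, 10000), rep(5, 1000))
  d2 <- c(d2, rep(0, 20001 - length(d2)))
  m2 <- 5000:6999
  cl <- call_wavefront(make_window(d2, first_offset = 0L), cfg,
                       exon_mask = m2)
  expect_equal(cl$position, 999)
})

test_that("caller agrees with the gap-enumeration oracle on random windows", {
  set.seed(11)
  cfg <- analysis_config()
  for (i in 1:200) {
    lambda <- sample(c(0.5, 2, 5), 1)
    d <- rpois(20001, lambda) *
      rep(sample(0:1, 41, replace = TRUE), length.out = 20001)
    mask <- if (i %% 3 == 0) sample(0:20000, 500) else integer(0)
    w <- make_window(d, first_offset = 0L)
    got <- call_wavefront(w, cfg, exon_mask = mask)
    want <- oracle_front(d, 0:20000, cfg$depth_threshold, cfg$halt_gap,
                         mask)
    expect_equal(got$status, want$status, info = paste("window", i))
    if (want$status == "called")
      expect_equal(got$position, want$position, info = paste("window", i))
  }
})

test_that("increasing the halt gap never moves a front upstream", {
  set.seed(12)
  for (i in 1:50) {
    d <- rpois(20001, 1.2) * rep(sample(0:1, 21, replace = TRUE),
                                 length.out = 20001)
    w <- make_window(d, first_offset = 0L)
    fronts <- vapply(c(1000, 3000, 5000, 8000), function(g) {
      cl <- call_wavefront(w, analysis_config(halt_gap = g))
      if (is.na(cl$position)) -1 else cl$position
    }, numeric(1))
    expect_true(all(diff(fronts) >= 0))
  }
})

test_that("gene-set filters apply each exclusion rule", {
  tx <- GRanges("chrT", IRanges(1, 80000), strand = "+")
  mcols(tx)$gene_id <- "G1"; mcols(tx)$transcript_id <- "G1.T1"
  times <- c(10, 25, 40)

  ok <- calls_table("G1", c(12000, 39000, 65000), times)
  expect_equal(filter_gene_set(ok, tx)$retained, "G1")

  nonmono <- calls_table("G1", c(12000, 39000, 35000), times)
  f <- filter_gene_set(nonmono, tx)
  expect_length(f$retained, 0)
  expect_equal(f$exclusions$reason, "non_monotonic")

  beyond <- calls_table("G1", c(12000, 39000, 81000), times)
  expect_equal(filter_gene_set(beyond, tx)$exclusions$reason,
               "front_beyond_tts")

  uncalled <- calls_table("G1", c(12000, NA, 65000), times)
  uncalled$status[2] <- "no_island"
  expect_equal(filter_gene_set(uncalled, tx)$exclusions$reason,
               "front_not_called_in_all_samples")

  ## a gene lacking one of the cohort's samples is a hard error
  tx2 <- rep(tx, 2); mcols(tx2)$gene_id <- c("G1", "G2")
  two <- rbind(ok, calls_table("G2", c(12000, 39000), times[1:2]))
  expect_error(filter_gene_set(two, tx2), "missing samples")
})

test_that("filtering a mixed cohort equals rule-by-rule re-application", {
  set.seed(13)
  n <- 30
  times <- c(10, 25, 40)
  tx <- GRanges("chrT", IRanges(1, width = 60000), strand = "+")
  tx <- rep(tx, n)
  mcols(tx)$gene_id <- sprintf("G%02d", 1:n)
  calls <- do.call(rbind, lapply(1:n, function(i) {
    pos <- sort(sample(5000:70000, 3))          # some beyond the 60 kb TTS
    if (i %% 4 == 0) pos <- rev(pos)            # inject non-monotone genes
    calls_table(sprintf("G%02d", i), pos, times)
  }))
  got <- filter_gene_set(calls, tx)$retained
  expected <- Filter(function(g) {
    p <- calls$position[calls$gene_id == g][order(times)]
    all(diff(p) > 0) && all(p <= 60000)
  }, sprintf("G%02d", 1:n))
  expect_identical(sort(got), sort(unlist(expected)))
})

test_that("recovery-mode filters add expression and UV-reduction rules", {
  tx <- GRanges("chrT", IRanges(1, 80000), strand = "+")
  tx <- rep(tx, 3)
  mcols(tx)$gene_id <- c("G1", "G2", "G3")
  calls <- rbind(
    rbind(calls_table("G1", c(20000, 40000), c(2, 8), "UN"),
          calls_table("G1", c(10000, 30000), c(2, 8), "UV")),
    rbind(calls_table("G2", c(20000, 40000), c(2, 8), "UN"),
          calls_table("G2", c(10000, 30000), c(2, 8), "UV")),
    rbind(calls_table("G3", c(20000, 40000), c(2, 8), "UN"),
          calls_table("G3", c(50000, 60000), c(2, 8), "UV")))
  rpkm_tab <- data.frame(gene_id = c("G1", "G2", "G3"),
                         rpkm_tss = c(1.0, 0.1, 1.0),
                         rpkm_sustained = c(0.8, 0.8, 0.8))
  f <- filter_gene_set(calls, tx, mode = "recovery", rpkm_table = rpkm_tab)
  expect_equal(f$retained, "G1")
  expect_setequal(f$exclusions$reason, c("not_expressed", "no_uv_reduction"))
})

test_that("interfering neighbours within the window are detected on either strand", {
  tx <- GRanges("chrT",
                IRanges(c(10000, 100000, 600000), width = 50000),
                strand = c("+", "-", "+"))
  mcols(tx)$gene_id <- c("A", "B", "C")
  seqlengths(tx) <- c(chrT = 1e6)
  ## A's window (8,000..130,001) reaches into B; B's window
  ## (30,000..152,000, leftward from its TSS at 149,999) reaches into A;
  ## C is isolated
  expect_setequal(overlapping_genes(tx), c("A", "B"))
  ## generated annotations are spaced so windows never collide
  ann <- make_annotation(10, c(30000, 119000), seed = 16)
  expect_length(overlapping_genes(select_transcripts(ann)), 0)
})

test_that("median front and rate estimators satisfy their definitions", {
  expect_equal(median_wavefront(10000), 10000)
  expect_equal(median_wavefront(c(10000, 20000)), 15000)
  set.seed(14)
  x <- sample(1:120000, 101)
  expect_equal(median_wavefront(x), sort(x)[51])
  expect_error(median_wavefront(numeric(0)), "no called fronts")

  expect_equal(round(pairwise_rate(12500, 39000, 15), 2), 1.77)
  expect_equal(round(pairwise_rate(17300, 21000, 15), 2), 0.25)
  expect_equal(pairwise_rate(5000, 5000, 12), 0)
  expect_error(pairwise_rate(0, 100, 0), "dt")

  ## collinear points: exact slope; two points: equals the pairwise rate
  t <- c(120, 300, 480, 600, 720)
  expect_equal(fit_rate(t, 40 * t + 2000)$rate, 0.04)
  expect_equal(fit_rate(c(10, 25), c(12500, 39000))$rate,
               pairwise_rate(12500, 39000, 15))
  expect_error(fit_rate(c(5, 5), c(1, 2)), "distinct")

  ## noisy points: matches the normal-equations solution
  set.seed(15)
  tt <- c(10, 20, 30, 40, 50, 60)
  pp <- 1500 * tt + rnorm(6, 0, 800)
  slope <- sum((tt - mean(tt)) * (pp - mean(pp))) / sum((tt - mean(tt))^2)
  expect_equal(fit_rate(tt, pp)$rate, slope / 1000)
})
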