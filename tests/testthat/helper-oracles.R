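## Independent oracles and small fixture builders used across tests.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## naive per-read pileup of extended intervals on one contig/strand
naive_pileup <- function(starts, ends, contig_len) {
  depth <- numeric(contig_len)
  for (i in seq_along(starts)) {
    s <- max(1L, starts[i]); e <- min(contig_len, ends[i])
    if (s <= e) depth[s:e] <- depth[s:e] + 1
  }
  depth
}

## symmetric trimmed mean by explicit sort-drop-average
sort_trim_mean <- function(x, trim) {
  k <- floor(length(x) * trim)
  s <- sort(x)
  if (k > 0) s <- s[(k + 1):(length(s) - k)]
  mean(s)
}

## wave-front by gap-lengths between consecutive above-threshold positions
## (independent formulation of the island/halt-gap rule)
oracle_front <- function(depth, offsets, threshold, gap,
                         masked_offsets = integer(0)) {
  keep <- offsets >= 0 & !(offsets %in% masked_offsets)
  d <- depth[keep]; o <- offsets[keep]
  ab <- which(d >= threshold)
  if (!length(ab)) return(list(status = "no_island", position = NA_real_))
  between <- diff(ab) - 1L
  hit <- which(between >= gap)
  if (length(hit))
    return(list(status = "called", position = o[ab[hit[1]]],
                window_end = FALSE))
  trailing <- length(d) - ab[length(ab)]
  list(status = "called", position = o[ab[length(ab)]],
       window_end = trailing < gap)
}

## Pr(Y > X) for X~Beta(a1,b1), Y~Beta(a2,b2), integer parameters
## (closed-form finite sum); Pr(X > Y) is its complement.
pr_second_greater <- function(a1, b1, a2, b2) {
  i <- 0:(a2 - 1)
  sum(exp(lbeta(a1 + i, b1 + b2) - log(b2 + i) -
            lbeta(1 + i, b2) - lbeta(a1, b1)))
}

## minimal GeneWindowCoverage-like object for caller tests
make_window <- function(depth, gene_id = "G0001", sample = "S",
                        first_offset = 0L) {
  structure(list(gene_id = gene_id, sample = sample,
                 offsets = seq(first_offset, length.out = length(depth)),
                 depth = depth, tss = 1L,
                 gene_length = length(depth), truncated = FALSE),
            class = "GeneWindowCoverage")
}

## wave-front calls table for filter tests
calls_table <- function(gene_id, positions, times, condition = "UN",
                        status = "called") {
  data.frame(gene_id = gene_id,
             sample = paste0(condition, "_t", times),
             position = positions, status = status, flags = "",
             condition = condition, time = times,
             stringsAsFactors = FALSE)
}
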