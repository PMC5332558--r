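## Synthetic gene/transcript annotation with optional two-isoform ALE genes.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic transcript annotation
#'
#' Lays out `n_genes` non-overlapping genes on one synthetic contig,
#' alternating strands, each with a multi-exon transcript whose length is
#' drawn uniformly from `length_range`. A fraction `ale_fraction` of genes
#' receives a second, short isoform that shares the 5' exons and ends in a
#' unique TSS-proximal terminal exon located in an intron of the long
#' isoform — the alternative-last-exon (ALE) configuration in which a
#' proximal poly-A site competes with the distal one.
#'
#' Gene spacing is chosen so that the standard analysis window (2 kb
#' upstream to 120 kb downstream of the TSS) of one gene never overlaps a
#' neighbouring gene.
#'
#' @param n_genes number of genes (>= 1).
#' @param length_range two-element numeric, min/max gene length in bp
#'   (min >= 1000).
#' @param ale_fraction fraction of genes carrying a short ALE isoform,
#'   in \[0, 1\].
#' @param seed integer seed; output is deterministic given the seed.
#' @param contig name of the synthetic contig.
#' @param spacing gap between consecutive gene bodies (bp); defaults to
#'   132 kb so that -2 kb..+120 kb windows never touch a neighbour.
#' @return list with `transcripts` and `exons` (`GRanges`, 1-based closed;
#'   mcols `gene_id`, `transcript_id`, `isoform`), and `seed`. Seqlengths
#'   are set on the contig.
#' @export
make_annotation <- function(n_genes, length_range = c(30000, 120000),
                            ale_fraction = 0, seed = 1,
                            contig = "chrS", spacing = 132000) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (length(length_range) != 2 || min(length_range) < 1000)
    stop("length_range must span at least 1 kb")
  if (ale_fraction < 0 || ale_fraction > 1)
    stop("ale_fraction must be in [0, 1]")

  with_seed(seed, {
    lens <- if (length_range[1] == length_range[2]) rep(length_range[1], n_genes)
            else round(runif(n_genes, length_range[1], length_range[2]))
    has_ale <- runif(n_genes) < ale_fraction
    starts <- 10000 + cumsum(c(0, head(lens, -1) + spacing))
    strands <- rep(c("+", "-"), length.out = n_genes)

    tx_rows <- list(); ex_rows <- list()
    for (i in seq_len(n_genes)) {
      gid <- sprintf("G%04d", i)
      L <- lens[i]; s <- starts[i]; e <- s + L - 1; str <- strands[i]
      ## exon scaffold in gene-relative coordinates (1 = TSS)
      n_int <- sample(3:8, 1)
      int_starts <- sort(round(runif(n_int, 0.1 * L, 0.9 * L)))
      int_w <- sample(100:300, n_int, replace = TRUE)
      rel <- data.frame(
        start = c(1, int_starts, L - 999),
        end = c(300, pmin(int_starts + int_w - 1, L - 1500), L),
        stringsAsFactors = FALSE)
      rel <- rel[rel$start < rel$end, , drop = FALSE]
      ## drop internal exons colliding with first/last exon or each other
      keep <- rep(TRUE, nrow(rel))
      for (j in seq_len(nrow(rel))[-1])
        if (rel$start[j] <= max(rel$end[which(keep)[which(keep) < j]]))
          keep[j] <- FALSE
      rel <- rel[keep, , drop = FALSE]

      tx1 <- paste0(gid, ".T1")
      tx_rows[[length(tx_rows) + 1]] <-
        data.frame(gene_id = gid, transcript_id = tx1, isoform = "long",
                   rel_start = 1, rel_end = L, strand = str,
                   gene_start = s, stringsAsFactors = FALSE)
      ex_rows[[length(ex_rows) + 1]] <-
        data.frame(gene_id = gid, transcript_id = tx1, isoform = "long",
                   rel_start = rel$start, rel_end = rel$end, strand = str,
                   gene_start = s, stringsAsFactors = FALSE)

      if (has_ale[i]) {
        ## short isoform: shares 5' exons, unique terminal exon in an
        ## intron of the long isoform, ending 20-40% into the gene
        aend <- round(runif(1, 0.2, 0.4) * L)
        shared <- rel[rel$end < aend - 1200, , drop = FALSE]
        term <- c(aend - 999, aend)
        ## ensure the unique exon does not overlap a long-isoform exon
        while (any(rel$start <= term[2] & rel$end >= term[1]) &&
               term[2] < 0.9 * L) {
          term <- term + 1500
        }
        tx2 <- paste0(gid, ".T2")
        tx_rows[[length(tx_rows) + 1]] <-
          data.frame(gene_id = gid, transcript_id = tx2, isoform = "short",
                     rel_start = 1, rel_end = term[2], strand = str,
                     gene_start = s, stringsAsFactors = FALSE)
        ex_rows[[length(ex_rows) + 1]] <-
          data.frame(gene_id = gid, transcript_id = tx2, isoform = "short",
                     rel_start = c(shared$start, term[1]),
                     rel_end = c(shared$end, term[2]), strand = str,
                     gene_start = s, stringsAsFactors = FALSE)
      }
    }
    txd <- do.call(rbind, tx_rows); exd <- do.call(rbind, ex_rows)

    to_gr <- function(d) {
      ## gene-relative -> genomic; minus-strand genes read right-to-left
      gs <- d$gene_start
      glen <- lens[match(d$gene_id, sprintf("G%04d", seq_len(n_genes)))]
      st <- ifelse(d$strand == "+", gs + d$rel_start - 1,
                   gs + glen - d$rel_end)
      en <- ifelse(d$strand == "+", gs + d$rel_end - 1,
                   gs + glen - d$rel_start)
      gr <- GRanges(contig, IRanges(st, en), strand = d$strand)
      mcols(gr) <- S4Vectors::DataFrame(gene_id = d$gene_id,
                                        transcript_id = d$transcript_id,
                                        isoform = d$isoform)
      gr
    }
    tx <- to_gr(txd); ex <- to_gr(exd)
    clen <- max(end(tx)) + 132000
    seqlengths(tx) <- clen; seqlengths(ex) <- clen
    list(transcripts = tx, exons = ex, seed = seed)
  })
}

#' Internal exons of a transcript
#'
#' Returns the annotated exons of `transcript_id` excluding the first and
#' last exon in transcription order — the mask used by the wave-front
#' caller to ignore mature-RNA contamination spikes.
#'
#' @param annotation annotation list from [make_annotation()] or
#'   [read_annotation_gtf()].
#' @param transcript_id transcript whose internal exons to return.
#' @param max_width drop exons wider than this (bp); internal exons are
#'   typically far below the halt gap, but the cap is configurable.
#' @return `GRanges` of internal exons.
#' @export
internal_exons <- function(annotation, transcript_id, max_width = 5000) {
  ex <- annotation$exons
  ex <- ex[ex$transcript_id == transcript_id]
  if (length(ex) <= 2L) return(ex[0])
  ord <- order(start(ex))
  if (as.character(strand(ex)[1]) == "-") ord <- rev(ord)
  ex <- ex[ord][-c(1L, length(ex))]
  ex[width(ex) <= max_width]
}
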