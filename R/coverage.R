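## Normalized strand-specific pileup, TSS-anchored gene windows, trimmed-mean
## meta-gene profiles, RPKM and downstream-recovery summaries.

#' Build normalized strand-specific coverage from aligned reads
#'
#' Each read is extended in its 3' direction to `extension` bp from its 5'
#' start (GRO-seq reads mark the polymerase 5' position), piled up per
#' strand, and depth is scaled by `target_depth / total mapped reads`.
#'
#' @param alignments `GRanges` of reads (strand required) or path to a
#'   BED6 file.
#' @param extension read-extension length in bp (default 250).
#' @param target_depth read depth every sample is normalized to
#'   (default 20 million).
#' @param keep_reads keep the extended reads on the object (needed for
#'   [rpkm()] read counting).
#' @return `CoverageTrack`: list with per-strand `RleList` depth (`plus`,
#'   `minus`), `total_reads`, `scale_factor`, `extension`, and the
#'   extended `reads` when kept.
#' @export
build_coverage <- function(alignments, extension = 250,
                           target_depth = 2e7, keep_reads = TRUE) {
  if (is.character(alignments)) alignments <- read_alignments_bed(alignments)
  n <- length(alignments)
  if (n == 0L) stop("zero mapped reads: cannot normalize coverage")
  if (any(strand(alignments) == "*")) stop("alignments must be stranded")
  ext <- suppressWarnings(resize(alignments, width = extension, fix = "start"))
  clipped <- sum(start(ext) < 1) +
    if (!all(is.na(seqlengths(ext))))
      sum(end(ext) > seqlengths(ext)[as.character(seqnames(ext))], na.rm = TRUE)
    else 0L
  ext <- suppressWarnings(trim(ext))
  ext <- restrict(ext, start = 1L)
  if (clipped > 0)
    message(clipped, " reads clipped at contig bounds during extension")
  scale <- target_depth / n
  structure(list(
    plus = coverage(ext[strand(ext) == "+"]) * scale,
    minus = coverage(ext[strand(ext) == "-"]) * scale,
    total_reads = n, scale_factor = scale, extension = extension,
    reads = if (keep_reads) ext else NULL),
    class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", x$total_reads, "reads, extension", x$extension,
      "bp, scale factor", signif(x$scale_factor, 4), "\n")
  invisible(x)
}

#' Select the analysis transcript set
#'
#' Keeps the largest transcript per gene, then drops transcripts shorter
#' than `min_length` (30 kb by default, restricting wave-front analysis to
#' genes long enough to resolve elongation over tens of minutes). Length
#' ties break on the lexicographically smallest transcript id.
#'
#' @param annotation annotation list (`transcripts`/`exons` `GRanges`).
#' @param min_length minimum transcript length in bp.
#' @return `GRanges` of one transcript per retained gene.
#' @export
select_transcripts <- function(annotation, min_length = 30000) {
  tx <- annotation$transcripts
  ord <- order(tx$gene_id, -width(tx), tx$transcript_id)
  tx <- tx[ord]
  tx <- tx[!duplicated(tx$gene_id)]
  tx[width(tx) >= min_length]
}

#' Extract a TSS-anchored, strand-oriented gene coverage window
#'
#' Slices the sense-strand depth over `-upstream`..`+downstream` bp
#' relative to the transcript's TSS, re-oriented so that increasing offset
#' means travel in the direction of transcription (minus-strand genes are
#' reversed). Positions outside the contig are zero-filled and flagged.
#'
#' @param track a `CoverageTrack`.
#' @param transcript single-row `GRanges` (the gene's transcript).
#' @param upstream,downstream window extent in bp (defaults 2 kb / 120 kb).
#' @param sample label recorded on the window.
#' @return `GeneWindowCoverage`: list with `gene_id`, `sample`, `offsets`
#'   (`-upstream..downstream`), `depth`, `tss`, `gene_length`, `truncated`.
#' @export
gene_window <- function(track, transcript, upstream = 2000,
                        downstream = 120000, sample = NA_character_) {
  stopifnot(inherits(track, "CoverageTrack"), length(transcript) == 1L)
  chr <- as.character(seqnames(transcript))
  str <- as.character(strand(transcript))
  cov <- if (str == "-") track$minus else track$plus
  if (!chr %in% names(cov))
    cov_chr <- Rle(0, 0)
  else cov_chr <- cov[[chr]]
  clen <- length(cov_chr)
  tss <- if (str == "+") start(transcript) else end(transcript)
  lo <- if (str == "+") tss - upstream else tss - downstream
  hi <- if (str == "+") tss + downstream else tss + upstream
  depth <- numeric(hi - lo + 1L)
  s <- max(lo, 1L); e <- min(hi, clen)
  truncated <- s > lo || e < hi
  if (s <= e)
    depth[(s - lo + 1L):(e - lo + 1L)] <-
      as.numeric(S4Vectors::window(cov_chr, start = s, end = e))
  if (str == "-") depth <- rev(depth)
  structure(list(gene_id = transcript$gene_id,
                 sample = sample,
                 offsets = (-upstream):downstream,
                 depth = depth,
                 tss = tss,
                 gene_length = width(transcript),
                 truncated = truncated),
            class = "GeneWindowCoverage")
}

#' Windows for a whole transcript set
#'
#' @param track a `CoverageTrack`.
#' @param transcripts `GRanges` from [select_transcripts()].
#' @inheritParams gene_window
#' @return named list of `GeneWindowCoverage` (names = gene ids).
#' @export
gene_windows <- function(track, transcripts, upstream = 2000,
                         downstream = 120000, sample = NA_character_) {
  out <- lapply(seq_along(transcripts), function(i)
    gene_window(track, transcripts[i], upstream, downstream, sample))
  names(out) <- transcripts$gene_id
  out
}

#' Trimmed-mean meta-gene profile
#'
#' At every offset, drops `floor(n * trim)` genes from each tail of the
#' depth distribution and averages the rest — robust to single-gene
#' outliers in cohort profiles.
#'
#' @param windows list of `GeneWindowCoverage` on a common offset grid.
#' @param trim fraction trimmed from each tail, in \[0, 0.5).
#' @return `MetaProfile`: list with `offsets`, `depth`, `trim`, `n_genes`.
#' @export
metagene <- function(windows, trim = 0.05) {
  if (length(windows) < 1L) stop("need at least one window")
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  offs <- windows[[1]]$offsets
  mat <- vapply(windows, function(w) {
    if (!identical(w$offsets, offs)) stop("windows on different offset grids")
    w$depth
  }, numeric(length(offs)))
  ## floor(n * trim) dropped per tail; when that is zero the trimmed
  ## mean reduces to the arithmetic mean
  k <- floor(length(windows) * trim)
  depth <- if (k == 0L) rowMeans(mat) else apply(mat, 1L, mean, trim = trim)
  structure(list(offsets = offs, depth = unname(depth), trim = trim,
                 n_genes = length(windows)),
            class = "MetaProfile")
}

#' Binned, spline-smoothed single-gene profile
#'
#' Computes `log2(1 + depth)`, averages it over consecutive `bin`-bp bins
#' and overlays a smoothing spline (smoothness chosen by generalized
#' cross-validation).
#'
#' @param window a `GeneWindowCoverage`.
#' @param bin bin width in bp (default 500).
#' @param spar optional fixed smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` uses GCV.
#' @return list with `bin_offsets` (bin centers), `raw` (bin means of
#'   `log2(1+depth)`) and `smooth` (fitted values).
#' @export
single_gene_profile <- function(window, bin = 500, spar = NULL) {
  n <- length(window$depth)
  if (n < bin) stop("window shorter than one bin")
  x <- log2(1 + window$depth)
  grp <- (seq_len(n) - 1L) %/% bin
  raw <- as.numeric(tapply(x, grp, mean))
  centers <- as.numeric(tapply(window$offsets, grp, mean))
  sm <- if (length(raw) >= 4L) {
    fit <- if (is.null(spar)) smooth.spline(centers, raw)
           else smooth.spline(centers, raw, spar = spar)
    predict(fit, centers)$y
  } else raw
  list(bin_offsets = centers, raw = raw, smooth = sm)
}

#' Reads-per-kilobase-per-million for an interval
#'
#' `reads overlapping interval * 1e9 / (interval width * total mapped
#' reads)`. Reads are the extended alignments retained on the track.
#'
#' @param x a `CoverageTrack` built with `keep_reads = TRUE`, or a
#'   `GRanges` of reads.
#' @param interval single-row `GRanges`; when stranded, only same-strand
#'   reads are counted.
#' @param total_mapped_reads denominator; defaults to the track's (or
#'   read set's) total.
#' @return RPKM (numeric scalar).
#' @export
rpkm <- function(x, interval, total_mapped_reads = NULL) {
  stopifnot(length(interval) == 1L)
  if (width(interval) <= 0L) stop("zero-length interval")
  reads <- if (inherits(x, "CoverageTrack")) {
    if (is.null(x$reads)) stop("track was built with keep_reads = FALSE")
    if (is.null(total_mapped_reads)) total_mapped_reads <- x$total_reads
    x$reads
  } else x
  if (is.null(total_mapped_reads)) total_mapped_reads <- length(reads)
  ov <- if (as.character(strand(interval)) == "*")
    countOverlaps(interval, reads, ignore.strand = TRUE)
  else countOverlaps(interval, reads)
  as.numeric(ov) * 1e9 / (as.numeric(width(interval)) * total_mapped_reads)
}

#' Downstream transcription recovery relative to untreated
#'
#' Mean window depth over a far-downstream region (90-120 kb by default)
#' per sample, normalized to the untreated sample — tracks restoration of
#' elongation at gene 3' ends during recovery time courses.
#'
#' @param windows_by_sample named list; each element a list of
#'   `GeneWindowCoverage` (one cohort per sample) or a `MetaProfile`.
#' @param region two-element numeric, offset range in bp.
#' @param untreated name of the reference sample.
#' @return named numeric vector of recovery ratios (untreated = 1).
#' @export
downstream_recovery <- function(windows_by_sample,
                                region = c(90000, 120000),
                                untreated = "UN") {
  if (!untreated %in% names(windows_by_sample))
    stop("untreated sample '", untreated, "' not present")
  region_mean <- function(x) {
    if (inherits(x, "MetaProfile")) {
      sel <- x$offsets >= region[1] & x$offsets <= region[2]
      mean(x$depth[sel])
    } else {
      mean(vapply(x, function(w) {
        sel <- w$offsets >= region[1] & w$offsets <= region[2]
        mean(w$depth[sel])
      }, numeric(1)))
    }
  }
  vals <- vapply(windows_by_sample, region_mean, numeric(1))
  ref <- vals[[untreated]]
  if (ref == 0) stop("untreated mean signal is zero")
  vals / ref
}
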