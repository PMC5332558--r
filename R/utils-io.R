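## Thin I/O wrappers around rtracklayer so every stage can read/write the
## standard plain-text genomics formats.

#' Read aligned-read intervals from a BED file
#'
#' @param path BED6 file of aligned reads (0-based, half-open on disk;
#'   returned as a 1-based `GRanges`).
#' @return `GRanges` with strand set.
#' @export
read_alignments_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(strand(gr) == "*"))
    stop("alignments must be stranded (+/-): ", path)
  gr
}

#' Write aligned-read intervals to a BED6 file
#'
#' @param reads `GRanges` of reads.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments_bed <- function(reads, path) {
  if (is.null(mcols(reads)$name)) mcols(reads)$name <- "read"
  if (is.null(mcols(reads)$score)) mcols(reads)$score <- 0L
  rtracklayer::export(reads, path, format = "BED")
  invisible(path)
}

#' Read a transcript annotation from GTF
#'
#' Parses exon features into the transcript-model list used throughout the
#' package: a `GRanges` of transcripts (mcols `gene_id`, `transcript_id`)
#' and a `GRanges` of exons.
#'
#' @param path GTF file (1-based, closed intervals on disk).
#' @return list with elements `transcripts` and `exons` (both `GRanges`).
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "GTF")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  sp <- split(ex, ex$transcript_id)
  tx <- unlist(range(sp), use.names = FALSE)
  mcols(tx)$transcript_id <- names(sp)
  gid <- vapply(sp, function(g) as.character(g$gene_id[1]), character(1))
  mcols(tx)$gene_id <- unname(gid)
  list(transcripts = tx, exons = ex)
}

#' Write a transcript annotation to GTF and BED12
#'
#' @param annotation list with `transcripts` and `exons` `GRanges`.
#' @param gtf,bed12 output paths (either may be `NULL` to skip).
#' @return invisible list of written paths.
#' @export
write_annotation <- function(annotation, gtf = NULL, bed12 = NULL) {
  tx <- annotation$transcripts
  ex <- annotation$exons
  if (!is.null(gtf)) {
    txg <- tx
    mcols(txg) <- S4Vectors::DataFrame(
      source = "polwave", type = "transcript",
      gene_id = tx$gene_id, transcript_id = tx$transcript_id)
    exg <- ex
    mcols(exg) <- S4Vectors::DataFrame(
      source = "polwave", type = "exon",
      gene_id = ex$gene_id, transcript_id = ex$transcript_id)
    rtracklayer::export(c(txg, exg), gtf, format = "GTF")
  }
  if (!is.null(bed12)) {
    sp <- split(ex, ex$transcript_id)
    bed <- rtracklayer::asBED(sp)
    rtracklayer::export(bed, bed12, format = "BED")
  }
  invisible(list(gtf = gtf, bed12 = bed12))
}

#' Write per-strand normalized coverage as bedGraph
#'
#' @param track a `CoverageTrack`.
#' @param prefix output path prefix; files `<prefix>.plus.bedGraph` and
#'   `<prefix>.minus.bedGraph` are written.
#' @return invisible character vector of the two paths.
#' @export
write_coverage_bedgraph <- function(track, prefix) {
  stopifnot(inherits(track, "CoverageTrack"))
  paths <- c(plus = paste0(prefix, ".plus.bedGraph"),
             minus = paste0(prefix, ".minus.bedGraph"))
  rtracklayer::export(track$plus, paths[["plus"]], format = "bedGraph")
  rtracklayer::export(track$minus, paths[["minus"]], format = "bedGraph")
  invisible(paths)
}

#' Write a data frame as a TSV with header
#' @param x data.frame. @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with header
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) read.delim(path, sep = "\t", check.names = FALSE)
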