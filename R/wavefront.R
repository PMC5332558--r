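## Per-gene wave-front calling (island/gap change-point), cohort filters,
## and elongation-rate estimation.

#' Analysis configuration for wave-front calling and filtering
#'
#' All thresholds used by the caller and the gene filters, surfaced in one
#' place so every run can echo them.
#'
#' @param depth_threshold island membership threshold, normalized reads/bp
#'   (default 3).
#' @param halt_gap consecutive sub-threshold bp that end elongation
#'   (default 5000).
#' @param max_exon_width internal exons wider than this are not masked
#'   (default 5000 bp).
#' @param min_transcript_length transcript-length filter, bp (default
#'   30000).
#' @param rpkm_threshold expressed-gene threshold over TSS..+250 bp
#'   (default 0.3; recovery mode).
#' @param sustained_from,sustained_to_tts sustained-signal region: from
#'   this offset (default +30000 bp) to this many bp past the TTS
#'   (default 1000); recovery mode.
#' @param strict_monotone require strictly increasing fronts over time.
#' @param trim meta-profile trim fraction carried for provenance.
#' @return object of class `AnalysisConfig`.
#' @export
analysis_config <- function(depth_threshold = 3, halt_gap = 5000,
                            max_exon_width = 5000,
                            min_transcript_length = 30000,
                            rpkm_threshold = 0.3,
                            sustained_from = 30000,
                            sustained_to_tts = 1000,
                            strict_monotone = TRUE,
                            trim = 0.05) {
  vals <- c(depth_threshold, halt_gap, max_exon_width,
            min_transcript_length, rpkm_threshold, sustained_from,
            sustained_to_tts)
  if (any(vals <= 0)) stop("all thresholds must be > 0")
  structure(list(depth_threshold = depth_threshold, halt_gap = halt_gap,
                 max_exon_width = max_exon_width,
                 min_transcript_length = min_transcript_length,
                 rpkm_threshold = rpkm_threshold,
                 sustained_from = sustained_from,
                 sustained_to_tts = sustained_to_tts,
                 strict_monotone = strict_monotone, trim = trim),
            class = "AnalysisConfig")
}

#' Call the transcription wave-front in one gene window
#'
#' Scans downstream from the TSS (offsets < 0 are ignored). Unmasked
#' positions with depth >= the threshold form islands of elongation
#' evidence; once at least one island exists, the first run of
#' `halt_gap` consecutive unmasked sub-threshold positions marks halted
#' elongation, and the front is called at the transition point — the last
#' above-threshold position before that gap. Masked (exonic) positions
#' neither extend islands nor count toward the gap: mature-RNA
#' contamination over exons must not create or break islands. If the
#' island signal runs to the window end without a qualifying gap, the
#' front is called at the last above-threshold position and flagged
#' (`window_end`); the downstream TTS filter removes such calls.
#'
#' @param window a `GeneWindowCoverage`.
#' @param config an `AnalysisConfig`.
#' @param exon_mask optional integer vector of masked offsets (bp
#'   downstream of TSS, 0-based), e.g. from [exon_mask_offsets()].
#' @return `WaveFrontCall`: list with `gene_id`, `sample`, `position` (bp
#'   downstream of TSS, or `NA`), `status` (`"called"`, `"no_island"`),
#'   and `flags`.
#' @export
call_wavefront <- function(window, config = analysis_config(),
                           exon_mask = integer(0)) {
  sel <- window$offsets >= 0
  depth <- window$depth[sel]
  offs <- window$offsets[sel]
  n <- length(depth)
  masked <- logical(n)
  if (length(exon_mask)) {
    idx <- exon_mask - offs[1] + 1L
    idx <- idx[idx >= 1L & idx <= n]
    masked[idx] <- TRUE
  }
  if (all(masked)) stop("window is entirely exon-masked")

  keep <- !masked
  d <- depth[keep]
  o <- offs[keep]
  above <- d >= config$depth_threshold
  if (!any(above))
    return(structure(list(gene_id = window$gene_id, sample = window$sample,
                          position = NA_real_, status = "no_island",
                          flags = character(0)),
                     class = "WaveFrontCall"))

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  front_idx <- NA_integer_; flags <- character(0)
  seen_island <- FALSE
  last_above <- NA_integer_
  for (j in seq_along(r$lengths)) {
    if (r$values[j]) {
      seen_island <- TRUE
      last_above <- ends[j]
    } else if (seen_island && r$lengths[j] >= config$halt_gap) {
      front_idx <- last_above
      break
    }
  }
  if (is.na(front_idx)) {
    front_idx <- last_above
    flags <- "window_end"
  }
  structure(list(gene_id = window$gene_id, sample = window$sample,
                 position = as.numeric(o[front_idx]), status = "called",
                 flags = flags),
            class = "WaveFrontCall")
}

#' Exon-mask offsets for a transcript
#'
#' Converts a transcript's internal exons into 0-based offsets downstream
#' of its TSS, for use as `exon_mask` in [call_wavefront()].
#'
#' @param annotation annotation list.
#' @param transcript single-row `GRanges`.
#' @param max_width internal exons wider than this are not masked.
#' @return integer vector of offsets.
#' @export
exon_mask_offsets <- function(annotation, transcript, max_width = 5000) {
  ie <- internal_exons(annotation, transcript$transcript_id, max_width)
  if (!length(ie)) return(integer(0))
  str <- as.character(strand(transcript))
  tss <- if (str == "+") start(transcript) else end(transcript)
  off <- unlist(lapply(seq_along(ie), function(j) {
    if (str == "+") (start(ie)[j]:end(ie)[j]) - tss
    else tss - (start(ie)[j]:end(ie)[j])
  }))
  sort(off[off >= 0])
}

#' Call wave-fronts for a cohort of windows
#'
#' @param windows_by_sample named list (sample -> named list of
#'   `GeneWindowCoverage`).
#' @param config an `AnalysisConfig`.
#' @param masks optional named list (gene id -> masked offsets).
#' @return data.frame with columns `gene_id`, `sample`, `position`,
#'   `status`, `flags`.
#' @export
call_wavefronts <- function(windows_by_sample, config = analysis_config(),
                            masks = list()) {
  rows <- list()
  for (s in names(windows_by_sample)) {
    for (g in names(windows_by_sample[[s]])) {
      w <- windows_by_sample[[s]][[g]]
      m <- if (g %in% names(masks)) masks[[g]] else integer(0)
      cl <- call_wavefront(w, config, m)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, sample = s,
        position = if (is.null(cl$position)) NA_real_ else cl$position,
        status = cl$status,
        flags = paste(cl$flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Filter the wave-front gene set
#'
#' Applies the cohort filters: fronts must be called in every required
#' sample; front position must increase over time within each condition
#' (strictly by default); no front may lie downstream of the transcription
#' termination site. In `mode = "recovery"` three further filters apply:
#' the gene must be expressed (RPKM >= threshold over TSS..+250 bp), must
#' show sustained signal from +30 kb to 1 kb past the TTS (operationalized
#' as RPKM >= the same threshold over that region), and the UV front must
#' lie upstream of the untreated front. Every exclusion is labeled.
#'
#' @param calls data.frame from [call_wavefronts()] with added numeric
#'   `time` and character `condition` columns (parsed from `sample` as
#'   `<condition>_t<time>` when absent).
#' @param transcripts `GRanges` of the analysed transcripts (for TTS).
#' @param config an `AnalysisConfig`.
#' @param mode `"drb"` (time-course filters only) or `"recovery"`.
#' @param rpkm_table optional data.frame `gene_id`, `rpkm_tss`,
#'   `rpkm_sustained` (required for recovery mode).
#' @param untreated_condition,uv_condition condition labels used by the
#'   recovery-mode front comparison.
#' @return list with `retained` (character gene ids) and `exclusions`
#'   (data.frame `gene_id`, `reason`).
#' @export
filter_gene_set <- function(calls, transcripts, config = analysis_config(),
                            mode = c("drb", "recovery"),
                            rpkm_table = NULL,
                            untreated_condition = "UN",
                            uv_condition = "UV") {
  mode <- match.arg(mode)
  if (!"time" %in% names(calls) || !"condition" %in% names(calls)) {
    parts <- regmatches(calls$sample,
                        regexec("^(.*)_t([0-9.]+)", calls$sample))
    calls$condition <- vapply(parts, `[`, character(1), 2L)
    calls$time <- as.numeric(vapply(parts, `[`, character(1), 3L))
    if (anyNA(calls$time))
      stop("cannot parse time/condition from sample labels; ",
           "supply 'time' and 'condition' columns")
  }
  samples <- unique(calls$sample)
  genes <- unique(calls$gene_id)
  tts_len <- setNames(width(transcripts), transcripts$gene_id)
  excl <- list()
  retained <- character(0)
  for (g in genes) {
    cg <- calls[calls$gene_id == g, , drop = FALSE]
    miss <- setdiff(samples, cg$sample)
    if (length(miss))
      stop("gene ", g, " missing samples: ", paste(miss, collapse = ", "))
    reason <- NULL
    if (any(cg$status != "called" | is.na(cg$position))) {
      reason <- "front_not_called_in_all_samples"
    } else if (!is.na(tts_len[g]) && any(cg$position > tts_len[g])) {
      reason <- "front_beyond_tts"
    } else {
      for (cond in unique(cg$condition)) {
        cc <- cg[cg$condition == cond, , drop = FALSE]
        cc <- cc[order(cc$time), , drop = FALSE]
        dp <- diff(cc$position)
        bad <- if (config$strict_monotone) any(dp <= 0) else any(dp < 0)
        if (nrow(cc) > 1L && bad) { reason <- "non_monotonic"; break }
      }
    }
    if (is.null(reason) && mode == "recovery") {
      if (is.null(rpkm_table)) stop("recovery mode requires rpkm_table")
      rt <- rpkm_table[rpkm_table$gene_id == g, , drop = FALSE]
      if (nrow(rt) == 0L) {
        reason <- "no_rpkm"
      } else if (rt$rpkm_tss[1] < config$rpkm_threshold) {
        reason <- "not_expressed"
      } else if (rt$rpkm_sustained[1] < config$rpkm_threshold) {
        reason <- "no_sustained_signal"
      } else {
        un <- cg[cg$condition == untreated_condition, , drop = FALSE]
        uv <- cg[cg$condition == uv_condition, , drop = FALSE]
        if (nrow(un) && nrow(uv)) {
          tmin <- min(uv$time)
          un_ref <- un$position[which.max(un$time)]
          uv_first <- uv$position[uv$time == tmin][1]
          if (!(uv_first < un_ref)) reason <- "no_uv_reduction"
        }
      }
    }
    if (is.null(reason)) retained <- c(retained, g)
    else excl[[length(excl) + 1L]] <-
        data.frame(gene_id = g, reason = reason, stringsAsFactors = FALSE)
  }
  list(retained = retained,
       exclusions = if (length(excl)) do.call(rbind, excl)
                    else data.frame(gene_id = character(0),
                                    reason = character(0)))
}

#' Genes with an interfering neighbour inside the analysis window
#'
#' Automated stand-in for manual curation of antisense and convergent
#' transcription: flags genes whose TSS-anchored analysis window
#' overlaps any other annotated gene body on either strand. Flagged
#' genes should be dropped from wave-front cohorts, since a
#' neighbouring gene's signal can masquerade as (or interrupt) the
#' wave.
#'
#' @param transcripts `GRanges` of analysis transcripts (one per gene,
#'   mcols `gene_id`).
#' @param upstream,downstream window extent around the TSS (bp).
#' @return character vector of gene ids with interfering neighbours.
#' @export
overlapping_genes <- function(transcripts, upstream = 2000,
                              downstream = 120000) {
  win <- promoters(transcripts, upstream = upstream,
                   downstream = downstream + 1)
  win <- suppressWarnings(trim(win))
  hits <- findOverlaps(win, transcripts, ignore.strand = TRUE)
  hits <- hits[queryHits(hits) != subjectHits(hits)]
  unique(transcripts$gene_id[queryHits(hits)])
}

#' Median wave-front position for one sample
#'
#' @param positions numeric vector of called front positions (bp).
#' @return median position; even counts average the central pair.
#' @export
median_wavefront <- function(positions) {
  positions <- positions[!is.na(positions)]
  if (!length(positions)) stop("no called fronts")
  median(positions)
}

#' Pairwise elongation rate between two wave-front positions
#'
#' @param p1,p2 front positions in bp (earlier, later time point).
#' @param dt time interval in minutes (> 0).
#' @return rate in kb/min.
#' @export
pairwise_rate <- function(p1, p2, dt) {
  if (any(dt <= 0)) stop("dt must be > 0")
  (p2 - p1) / 1000 / dt
}

#' Best-fit-line elongation rate
#'
#' Ordinary least-squares slope of front position against time; the slope
#' of the line is the elongation rate.
#'
#' @param times time points in minutes (>= 2 distinct values).
#' @param positions front positions in bp.
#' @return `ElongationRateEstimate`: list with `rate` (kb/min),
#'   `intercept` (bp), `method`, `times`, `positions`.
#' @export
fit_rate <- function(times, positions) {
  if (length(unique(times)) < 2L) stop("need >= 2 distinct time points")
  if (length(times) != length(positions)) stop("length mismatch")
  fit <- lm(positions ~ times)
  structure(list(rate = unname(coef(fit)[2]) / 1000,
                 intercept = unname(coef(fit)[1]),
                 method = "best_fit",
                 times = times, positions = positions),
            class = "ElongationRateEstimate")
}

#' @export
print.ElongationRateEstimate <- function(x, ...) {
  cat(sprintf("Elongation rate (%s): %.3f kb/min\n", x$method, x$rate))
  invisible(x)
}
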