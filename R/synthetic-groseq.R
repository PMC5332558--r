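## DRB-release GRO-seq coverage simulator: promoter-proximal peak plus an
## elongation wave advancing at configurable speed, with background and
## optional exonic mRNA-contamination spikes.

#' Wave-kinetics configuration for the GRO-seq simulator
#'
#' Heights are expected read depth after the consumer's read extension
#' (reads/bp on `extension`-bp extended reads); the simulator draws 1-bp 5'
#' read starts at rate height/extension so that downstream pileup recovers
#' the configured depth. With `extension = 1` the generator is exact per
#' base pair.
#'
#' @param conditions character vector of condition labels.
#' @param times numeric vector of time points (minutes since DRB release).
#' @param speeds numeric matrix, `length(conditions)` x `length(times)`:
#'   wave speed (kb/min) over each inter-time-point interval (column k
#'   covers `(times[k-1], times[k]]`, with `times[0] = 0`). A single number
#'   is recycled.
#' @param promoter_height,promoter_width promoter-proximal peak depth
#'   (reads/bp) and width (bp).
#' @param plateau wave plateau depth (reads/bp) from the TSS to the front.
#' @param background uniform background depth (reads/bp) across the gene
#'   window.
#' @param contamination extra depth (reads/bp) over internal exons,
#'   emulating mature-RNA contamination (default 0).
#' @param noise `"poisson"` (counts drawn per bp) or `"none"`
#'   (deterministic expectation).
#' @param extension read-extension length (bp) the consumer will apply;
#'   defines the depth units as described above.
#' @param window_downstream extent of simulated signal downstream of the
#'   TSS (bp).
#' @param cap_at_tts logical; stop the wave at the annotated gene end.
#' @param seed integer seed fixing all randomness.
#' @return object of class `WaveKineticsConfig`.
#' @export
wave_kinetics_config <- function(conditions = c("UN", "UV"),
                                 times = c(10, 25, 40),
                                 speeds = matrix(c(1.77, 1.72, 1.72,
                                                   0.47, 0.25, 0.25),
                                                 nrow = 2, byrow = TRUE),
                                 promoter_height = 10, promoter_width = 600,
                                 plateau = 5, background = 0,
                                 contamination = 0,
                                 noise = c("poisson", "none"),
                                 extension = 250,
                                 window_downstream = 120000,
                                 cap_at_tts = TRUE,
                                 seed = 1) {
  noise <- match.arg(noise)
  if (length(speeds) == 1L)
    speeds <- matrix(speeds, length(conditions), length(times))
  speeds <- as.matrix(speeds)
  if (nrow(speeds) != length(conditions) || ncol(speeds) != length(times))
    stop("speeds must be a conditions x times matrix")
  if (any(speeds < 0)) stop("speeds must be >= 0")
  if (any(c(promoter_height, plateau, background, contamination) < 0))
    stop("heights must be >= 0")
  if (extension < 1) stop("extension must be >= 1")
  structure(list(conditions = conditions, times = times, speeds = speeds,
                 promoter_height = promoter_height,
                 promoter_width = promoter_width,
                 plateau = plateau, background = background,
                 contamination = contamination, noise = noise,
                 extension = extension,
                 window_downstream = window_downstream,
                 cap_at_tts = cap_at_tts, seed = as.integer(seed)),
            class = "WaveKineticsConfig")
}

#' True wave-front positions implied by a kinetics configuration
#'
#' @param kinetics a `WaveKineticsConfig`.
#' @return numeric matrix (conditions x times) of front positions, bp
#'   downstream of the TSS.
#' @export
true_fronts <- function(kinetics) {
  dt <- diff(c(0, kinetics$times))
  fr <- t(apply(kinetics$speeds * 1000, 1,
                function(v) cumsum(v * dt)))
  dimnames(fr) <- list(kinetics$conditions, paste0("t", kinetics$times))
  fr
}

# per-bp expected extended depth over offsets 0..win for one gene/sample
.expected_depth <- function(kinetics, front, gene_len, exon_offsets) {
  win <- kinetics$window_downstream
  lambda <- rep(kinetics$background, win + 1L)
  wave_end <- if (kinetics$cap_at_tts) min(front, gene_len) else front
  if (wave_end >= 1) {
    idx <- seq_len(min(wave_end, win + 1L))
    lambda[idx] <- lambda[idx] + kinetics$plateau
  }
  pk <- seq_len(min(kinetics$promoter_width, win + 1L))
  lambda[pk] <- lambda[pk] + kinetics$promoter_height
  if (kinetics$contamination > 0 && length(exon_offsets))
    lambda[exon_offsets] <- lambda[exon_offsets] + kinetics$contamination
  lambda
}

# deterministic integer read counts preserving the cumulative expectation
.floor_counts <- function(rate) diff(c(0, floor(cumsum(rate))))

#' Simulate DRB-release GRO-seq read starts
#'
#' For every gene (largest transcript per gene) and every
#' (condition, time) sample, emits 1-bp 5' read-start positions whose
#' expected `extension`-bp pileup is: promoter peak over
#' `[TSS, TSS + promoter_width)`, plateau over `[TSS, TSS + v t)`,
#' plus uniform background and optional contamination over internal exons.
#' Read strand matches the gene; minus-strand genes emit positions walking
#' leftward from the TSS.
#'
#' @param annotation annotation list (see [make_annotation()]).
#' @param kinetics a `WaveKineticsConfig`.
#' @param reads_target optional expected total read count per sample; when
#'   given, all rates are scaled to meet it in expectation.
#' @return `GRanges` of 1-bp reads with mcols `sample`, `condition`,
#'   `time`; the kinetics config is attached as attribute `kinetics`.
#' @export
simulate_groseq <- function(annotation, kinetics, reads_target = NULL) {
  stopifnot(inherits(kinetics, "WaveKineticsConfig"))
  if (!is.null(reads_target) && reads_target < 0)
    stop("reads_target must be >= 0")
  tx <- select_transcripts(annotation, min_length = 0)
  fronts <- true_fronts(kinetics)
  win <- kinetics$window_downstream

  ## per-gene internal-exon offsets (0-based from TSS)
  exoff <- lapply(seq_along(tx), function(i) {
    if (kinetics$contamination <= 0) return(integer(0))
    ie <- internal_exons(annotation, tx$transcript_id[i])
    if (!length(ie)) return(integer(0))
    tss <- if (as.character(strand(tx)[i]) == "+") start(tx)[i] else end(tx)[i]
    off <- if (as.character(strand(tx)[i]) == "+")
      unlist(lapply(seq_along(ie), function(j) start(ie)[j]:end(ie)[j])) - tss
    else tss - unlist(lapply(seq_along(ie), function(j) start(ie)[j]:end(ie)[j]))
    off <- off[off >= 0 & off <= win]
    off + 1L
  })

  scale <- 1
  if (!is.null(reads_target)) {
    tot <- 0
    for (ci in seq_along(kinetics$conditions))
      for (ti in seq_along(kinetics$times))
        for (gi in seq_along(tx))
          tot <- tot + sum(.expected_depth(kinetics, fronts[ci, ti],
                                           width(tx)[gi], exoff[[gi]]))
    tot <- tot / (kinetics$extension * length(kinetics$conditions) *
                    length(kinetics$times))
    if (tot <= 0) stop("configuration yields zero expected reads")
    scale <- reads_target / tot
  }

  out <- vector("list", length(kinetics$conditions) * length(kinetics$times))
  k <- 0L
  with_seed(kinetics$seed, {
    for (ci in seq_along(kinetics$conditions)) {
      for (ti in seq_along(kinetics$times)) {
        pos_all <- integer(0); str_all <- character(0)
        for (gi in seq_along(tx)) {
          rate <- scale * .expected_depth(kinetics, fronts[ci, ti],
                                          width(tx)[gi], exoff[[gi]]) /
            kinetics$extension
          counts <- if (kinetics$noise == "poisson") rpois(length(rate), rate)
                    else .floor_counts(rate)
          nz <- which(counts > 0L)
          if (!length(nz)) next
          offs <- rep.int(nz - 1L, counts[nz])
          gstr <- as.character(strand(tx)[gi])
          tss <- if (gstr == "+") start(tx)[gi] else end(tx)[gi]
          gp <- if (gstr == "+") tss + offs else tss - offs
          keep <- gp >= 1
          pos_all <- c(pos_all, gp[keep])
          str_all <- c(str_all, rep(gstr, sum(keep)))
        }
        k <- k + 1L
        gr <- GRanges(seqlevels(annotation$transcripts)[1],
                      IRanges(pos_all, width = 1L), strand = str_all)
        lab <- paste0(kinetics$conditions[ci], "_t", kinetics$times[ti])
        mcols(gr) <- S4Vectors::DataFrame(
          sample = Rle(lab, length(gr)),
          condition = Rle(kinetics$conditions[ci], length(gr)),
          time = Rle(kinetics$times[ti], length(gr)))
        out[[k]] <- gr
      }
    }
  })
  res <- suppressWarnings(do.call(c, out))
  seqlengths(res) <- seqlengths(annotation$transcripts)[seqlevels(res)]
  attr(res, "kinetics") <- kinetics
  res
}
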