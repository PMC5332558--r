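## Cohort wave-fronts from meta-profile differences: loess smoothing, zero
## crossing, derivative-half refinement.

#' Difference of two meta-gene profiles
#'
#' Signed per-offset difference, treated minus untreated: after UV the
#' treated profile shows excess signal near the TSS and a deficit
#' downstream of the stalled front, so the difference crosses zero
#' downward at the front.
#'
#' @param treated,untreated `MetaProfile` objects on the same offset grid.
#' @return `DifferenceProfile`: list with `offsets` and `diff`.
#' @export
difference_profile <- function(treated, untreated) {
  if (!identical(treated$offsets, untreated$offsets))
    stop("profiles are on different offset grids")
  structure(list(offsets = treated$offsets,
                 diff = treated$depth - untreated$depth),
            class = "DifferenceProfile")
}

#' Locate the cohort wave-front from a difference profile
#'
#' Fits a degree-1 loess curve to the difference profile, takes the first
#' downward zero crossing past the promoter region as the initial front
#' estimate, then refines it to the first downstream position where the
#' magnitude of the fitted curve's derivative has fallen to half its value
#' at the initial estimate. If the derivative never halves before the
#' window end, the refined estimate equals the initial one and is flagged.
#'
#' @param diff a `DifferenceProfile`.
#' @param span loess span as a fraction of the window (default 0.2),
#'   degree-1 local fits.
#' @param grid evaluation/derivative resolution in bp (default 100).
#' @param min_offset crossing search starts past this offset (default
#'   1000 bp), skipping the promoter-peak sign flip.
#' @return list with `initial` (bp), `refined` (bp), `flags` (character),
#'   `fit` (data.frame `offset`, `value` of the fitted curve).
#' @export
loess_wavefront <- function(diff, span = 0.2, grid = 100,
                            min_offset = 1000) {
  stopifnot(inherits(diff, "DifferenceProfile"))
  d <- data.frame(x = diff$offsets, y = diff$diff)
  ## fit on a grid thinned to ~grid/4 bp spacing: loess on >1e5 per-bp
  ## points is needless at 100 bp front resolution
  step <- stats::median(base::diff(d$x))
  thin <- d[seq(1L, nrow(d), by = max(1L, round(grid / 4 / step))), ]
  fit <- loess(y ~ x, data = thin, span = span, degree = 1,
               family = "gaussian")
  gx <- seq(min(d$x), max(d$x), by = grid)
  gy <- unname(predict(fit, data.frame(x = gx)))

  sel <- which(gx > min_offset)
  cross <- NULL
  for (i in sel[-length(sel)]) {
    if (!is.na(gy[i]) && !is.na(gy[i + 1]) &&
        gy[i] > 0 && gy[i + 1] <= 0) { cross <- i; break }
  }
  if (is.null(cross)) stop("no front detectable: fitted curve has no ",
                           "downward zero crossing past the promoter")
  ## linear interpolation inside the crossing interval
  x0 <- gx[cross] + grid * gy[cross] / (gy[cross] - gy[cross + 1])

  deriv <- c(NA, (gy[-(1:2)] - gy[seq_len(length(gy) - 2L)]) / (2 * grid), NA)
  d0 <- approx(gx, deriv, xout = x0)$y
  flags <- character(0)
  refined <- x0
  if (is.na(d0) || d0 == 0) {
    flags <- "derivative_undefined"
  } else {
    after <- which(gx > x0)
    hit <- after[!is.na(deriv[after]) & abs(deriv[after]) <= abs(d0) / 2]
    if (length(hit)) refined <- gx[hit[1]]
    else flags <- "no_half_derivative"
  }
  list(initial = x0, refined = refined, flags = flags,
       fit = data.frame(offset = gx, value = gy))
}

#' Elongation rate from mathematically determined fronts over hours
#'
#' Best-fit line of median front position against time, with hours
#' converted to minutes so the slope is in kb/min.
#'
#' @param times_hr time points in hours.
#' @param fronts front positions in bp.
#' @return `ElongationRateEstimate` (see [fit_rate()]).
#' @export
cohort_rate_from_math_fronts <- function(times_hr, fronts) {
  est <- fit_rate(times_hr * 60, fronts)
  est$method <- "mathematical"
  est
}
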