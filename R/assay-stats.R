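## Closed-form assay statistics: Livak delta-delta-CT, fraction
## enrichment, and the EU low/high transcription ratio.

#' Livak (delta-delta-CT) fold change
#'
#' `2^-ddCT` with
#' `ddCT = (ct_target_v - ct_ref_v) - (ct_target_c - ct_ref_c)`:
#' reference-gene-normalized expression in a variable condition relative
#' to a control condition.
#'
#' @param ct_target_v,ct_ref_v target and reference-gene CT in the
#'   variable (e.g. UV-treated) condition.
#' @param ct_target_c,ct_ref_c the same in the control condition.
#' @return fold change (linear scale).
#' @export
livak_fold_change <- function(ct_target_v, ct_ref_v,
                              ct_target_c, ct_ref_c) {
  cts <- c(ct_target_v, ct_ref_v, ct_target_c, ct_ref_c)
  if (any(!is.finite(cts))) stop("CT values must be finite")
  ddct <- (ct_target_v - ct_ref_v) - (ct_target_c - ct_ref_c)
  2^(-ddct)
}

#' Subcellular-fraction enrichment
#'
#' `2^-(ct_fraction - ct_reference_fraction)`; no reference-gene
#' normalization — CT values from the two fractions are compared directly.
#'
#' @param ct_fraction CT in the fraction of interest.
#' @param ct_reference_fraction CT in the reference fraction.
#' @return enrichment ratio.
#' @export
fraction_enrichment <- function(ct_fraction, ct_reference_fraction) {
  if (any(!is.finite(c(ct_fraction, ct_reference_fraction))))
    stop("CT values must be finite")
  2^(-(ct_fraction - ct_reference_fraction))
}

#' EU-assay low/high transcription ratio
#'
#' Fraction of nuclei below the low-transcription threshold divided by the
#' fraction above the high-transcription threshold, normalized to the same
#' quantity in a control sample (control set to 1). Thresholds are
#' explicit inputs — in practice they are set manually from the intensity
#' histogram; [suggest_thresholds()] can propose density valleys.
#'
#' @param intensities numeric per-nucleus intensities of the sample.
#' @param control_intensities the same for the control sample.
#' @param low,high thresholds (low <= high).
#' @return list with `ratio` (normalized), `sample_ratio`,
#'   `control_ratio`, `undefined`.
#' @export
low_high_ratio <- function(intensities, control_intensities, low, high) {
  if (low > high) stop("low threshold must be <= high threshold")
  if (!length(intensities) || !length(control_intensities))
    stop("both intensity sets must be non-empty")
  ratio_of <- function(x) {
    frac_low <- mean(x < low)
    frac_high <- mean(x > high)
    if (frac_high == 0) return(NA_real_)
    frac_low / frac_high
  }
  sr <- ratio_of(intensities)
  cr <- ratio_of(control_intensities)
  if (is.na(cr) || cr == 0) stop("control low/high ratio is zero or undefined")
  list(ratio = sr / cr, sample_ratio = sr, control_ratio = cr,
       undefined = is.na(sr))
}

#' Suggest low/high thresholds from an intensity histogram
#'
#' Proposes the deepest valley of a kernel-density estimate between the
#' two largest modes. Advisory only — thresholds are never applied
#' silently.
#'
#' @param intensities numeric per-nucleus intensities.
#' @return numeric vector `c(low, high)` (equal when a single valley is
#'   proposed for both).
#' @export
suggest_thresholds <- function(intensities) {
  d <- density(intensities)
  y <- d$y
  valleys <- which(diff(sign(diff(y))) == 2) + 1L
  if (!length(valleys)) return(c(low = NA_real_, high = NA_real_))
  v <- valleys[which.min(y[valleys])]
  c(low = d$x[v], high = d$x[v])
}

#' Average fold changes across biological replicates
#'
#' Linear-scale mean with standard error; optionally the geometric mean.
#'
#' @param fold_changes numeric vector of per-replicate fold changes.
#' @param geometric use the geometric mean.
#' @return list with `mean` and `sem` (sem on the chosen scale).
#' @export
average_fold_changes <- function(fold_changes, geometric = FALSE) {
  n <- length(fold_changes)
  if (geometric) {
    lg <- log(fold_changes)
    list(mean = exp(mean(lg)),
         sem = if (n > 1) exp(mean(lg)) * stats::sd(lg) / sqrt(n) else NA_real_)
  } else {
    list(mean = mean(fold_changes),
         sem = if (n > 1) stats::sd(fold_changes) / sqrt(n) else NA_real_)
  }
}
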