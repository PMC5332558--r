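## Alternative-isoform quantification: PSI with a conjugate two-proportion
## Bayes factor, splicing-index effect sizes, replicated filtering, ALE
## direction calls, isoform-length statistics and terminal-exon ratios.

## Pr(X > Y) for X ~ Beta(a1,b1), Y ~ Beta(a2,b2), by quadrature over the
## posterior mass of X. Bounds from quantiles keep the integrand resolved
## even for very concentrated posteriors.
.pr_greater <- function(a1, b1, a2, b2) {
  lo <- qbeta(1e-12, a1, b1); hi <- qbeta(1 - 1e-12, a1, b1)
  f <- function(x) dbeta(x, a1, b1) * pbeta(x, a2, b2)
  val <- integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 0,
                   subdivisions = 500L)$value
  min(max(val, 0), 1)
}

#' PSI, delta-PSI and Bayes factor for one splicing event
#'
#' PSI is the length-normalized inclusion fraction,
#' `(inc/len_inc) / (inc/len_inc + exc/len_exc)`. Evidence for a
#' treatment effect comes from a conjugate two-proportion model: each
#' condition's inclusion/exclusion read split gets an independent
#' Beta(1,1)-binomial posterior on the read-level inclusion probability,
#' and the Bayes factor is the posterior odds that delta-PSI has the
#' observed sign (the prior odds are 1, so posterior odds equal the
#' Bayes factor). With shared effective lengths across conditions the
#' read-level probability is a monotone transform of PSI, so the sign
#' event is identical on both scales.
#'
#' @param inc_treated,exc_treated,inc_control,exc_control read counts
#'   (inclusion / exclusion region) in the two conditions.
#' @param len_inc,len_exc effective region lengths (bp).
#' @return list with `psi_treated`, `psi_control`, `delta_psi`,
#'   `bayes_factor`, `undefined` (logical).
#' @export
estimate_psi <- function(inc_treated, exc_treated, inc_control, exc_control,
                         len_inc = 1, len_exc = 1) {
  counts <- c(inc_treated, exc_treated, inc_control, exc_control)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (len_inc <= 0 || len_exc <= 0) stop("effective lengths must be > 0")
  psi <- function(i, e) {
    di <- i / len_inc; de <- e / len_exc
    if (di + de == 0) return(NA_real_)
    di / (di + de)
  }
  p_t <- psi(inc_treated, exc_treated)
  p_c <- psi(inc_control, exc_control)
  if (is.na(p_t) || is.na(p_c))
    return(list(psi_treated = p_t, psi_control = p_c,
                delta_psi = NA_real_, bayes_factor = NA_real_,
                undefined = TRUE))
  dpsi <- p_t - p_c
  p_up <- .pr_greater(inc_treated + 1, exc_treated + 1,
                      inc_control + 1, exc_control + 1)
  p_sign <- if (dpsi >= 0) p_up else 1 - p_up
  p_sign <- min(p_sign, 1 - 1e-12)
  bf <- p_sign / (1 - p_sign)
  list(psi_treated = p_t, psi_control = p_c, delta_psi = dpsi,
       bayes_factor = bf, undefined = FALSE)
}

#' Single-region splicing index
#'
#' Effect size for events affecting one exon or intron (skipped exon,
#' retained intron): `log2((exon_uv/gene_uv) / (exon_un/gene_un))`.
#'
#' @param exon_uv,gene_uv,exon_un,gene_un read counts.
#' @return log2 splicing index; `NA` with a warning-free undefined flag
#'   when any denominator is zero.
#' @export
si_single <- function(exon_uv, gene_uv, exon_un, gene_un) {
  if (any(c(gene_uv, gene_un, exon_un) == 0) || exon_uv == 0)
    return(NA_real_)
  log2((exon_uv / gene_uv) / (exon_un / gene_un))
}

#' Switch splicing index
#'
#' Effect size for events where splicing shifts from one region to
#' another (alternative first/last exon; alternative 5'/3' splice sites
#' restricted to reads unique to each variant):
#' `log2((exon2_uv/exon2_un) / (exon1_uv/exon1_un))`.
#'
#' @param exon1_uv,exon1_un,exon2_uv,exon2_un read counts for the two
#'   regions in the two conditions.
#' @return log2 splicing index; `NA` when undefined.
#' @export
si_switch <- function(exon1_uv, exon1_un, exon2_uv, exon2_un) {
  if (any(c(exon1_un, exon2_un, exon1_uv) == 0) || exon2_uv == 0)
    return(NA_real_)
  log2((exon2_uv / exon2_un) / (exon1_uv / exon1_un))
}

#' Quantify splicing events from a count table
#'
#' Computes, per event and replicate, PSI in both conditions, delta-PSI,
#' the Bayes factor and the log2 splicing index (switch form for
#' AFE/ALE/A5SS/A3SS, single form for SE/RI using the gene-body count).
#'
#' @param counts data.frame with columns `event_id`, `type`, `replicate`,
#'   `condition`, `count_inc` (proximal/inclusion region), `count_exc`
#'   (distal/exclusion region), `count_gene`, `len_inc`, `len_exc`;
#'   conditions labeled by `treated`/`control`.
#' @param treated,control condition labels.
#' @return data.frame, one row per event x replicate, with `psi_treated`,
#'   `psi_control`, `delta_psi`, `bayes_factor`, `log2_si`.
#' @export
quantify_events <- function(counts, treated = "UV", control = "UN") {
  need <- c("event_id", "type", "replicate", "condition",
            "count_inc", "count_exc", "len_inc", "len_exc")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("count table lacks columns: ",
                         paste(miss, collapse = ", "))
  rows <- list()
  for (ev in unique(counts$event_id)) {
    ce <- counts[counts$event_id == ev, , drop = FALSE]
    for (rep_i in sort(unique(ce$replicate))) {
      tr <- ce[ce$replicate == rep_i & ce$condition == treated, , drop = FALSE]
      cn <- ce[ce$replicate == rep_i & ce$condition == control, , drop = FALSE]
      if (nrow(tr) != 1L || nrow(cn) != 1L)
        stop("event ", ev, " replicate ", rep_i,
             ": need exactly one row per condition")
      est <- estimate_psi(tr$count_inc, tr$count_exc,
                          cn$count_inc, cn$count_exc,
                          tr$len_inc, tr$len_exc)
      si <- if (tr$type[1] %in% c("SE", "RI")) {
        si_single(tr$count_inc, tr$count_gene, cn$count_inc, cn$count_gene)
      } else {
        ## switch form; region 1 = distal/exclusion, region 2 =
        ## proximal/inclusion, so a shift toward the proximal exon is
        ## positive
        si_switch(tr$count_exc, cn$count_exc, tr$count_inc, cn$count_inc)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = ev, type = tr$type[1], replicate = rep_i,
        count_inc_treated = tr$count_inc, count_exc_treated = tr$count_exc,
        count_inc_control = cn$count_inc, count_exc_control = cn$count_exc,
        psi_treated = est$psi_treated, psi_control = est$psi_control,
        delta_psi = est$delta_psi, bayes_factor = est$bayes_factor,
        log2_si = si, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Filter quantified events across replicates
#'
#' Retains events that pass, in every replicate: inclusion and exclusion
#' reads above `min_reads` in both conditions; non-zero delta-PSI with a
#' sign consistent across replicates; Bayes factor above `min_bf`;
#' `|log2 SI| >= min_si` with a consistent sign. An audit trail records
#' the first failed filter per event.
#'
#' @param quantified data.frame from [quantify_events()].
#' @param min_reads read-count threshold (exclusive; default 10).
#' @param min_bf Bayes-factor threshold (exclusive; default 10).
#' @param min_si `|log2 SI|` threshold (inclusive; default 0.25).
#' @param n_replicates replicates required per event (default 2).
#' @return list with `retained` (event ids) and `audit` (data.frame
#'   `event_id`, `pass`, `fail_reason`).
#' @export
filter_events <- function(quantified, min_reads = 10, min_bf = 10,
                          min_si = 0.25, n_replicates = 2) {
  out <- list()
  for (ev in unique(quantified$event_id)) {
    q <- quantified[quantified$event_id == ev, , drop = FALSE]
    if (nrow(q) != n_replicates)
      stop("event ", ev, ": expected ", n_replicates,
           " replicates, got ", nrow(q))
    reason <- NULL
    reads_ok <- all(q$count_inc_treated > min_reads &
                      q$count_exc_treated > min_reads &
                      q$count_inc_control > min_reads &
                      q$count_exc_control > min_reads)
    if (anyNA(q$delta_psi) || anyNA(q$log2_si)) reason <- "undefined"
    else if (!reads_ok) reason <- "min_reads"
    else if (any(q$delta_psi == 0) ||
             length(unique(sign(q$delta_psi))) > 1L) reason <- "delta_psi"
    else if (any(q$bayes_factor <= min_bf)) reason <- "bayes_factor"
    else if (any(abs(q$log2_si) < min_si) ||
             length(unique(sign(q$log2_si))) > 1L) reason <- "log2_si"
    out[[length(out) + 1L]] <- data.frame(
      event_id = ev, pass = is.null(reason),
      fail_reason = if (is.null(reason)) "" else reason,
      stringsAsFactors = FALSE)
  }
  audit <- do.call(rbind, out)
  list(retained = audit$event_id[audit$pass], audit = audit)
}

#' Classify an ALE event as "short" or "long"
#'
#' "Short" when the TSS-proximal terminal exon's relative expression
#' increases after treatment (delta-PSI > 0 with PSI defined on the
#' proximal exon), "long" when it decreases; no change yields a flagged
#' no-call.
#'
#' @param quantified_event data.frame rows for one ALE event (all
#'   replicates) from [quantify_events()].
#' @return `"short"`, `"long"` or `"no_call"`.
#' @export
classify_ale <- function(quantified_event) {
  if (!all(quantified_event$type == "ALE"))
    stop("classify_ale expects an ALE event")
  d <- quantified_event$delta_psi
  if (anyNA(d)) stop("event has undefined delta-PSI")
  if (all(d > 0)) "short"
  else if (all(d < 0)) "long"
  else "no_call"
}

#' Relative change in isoform length
#'
#' `(b - a) / b` for a short pre-mRNA of length `a` and a long pre-mRNA
#' of length `b`.
#'
#' @param a short-isoform pre-mRNA length (bp).
#' @param b long-isoform pre-mRNA length (bp, > 0).
#' @return fraction in (-Inf, 1].
#' @export
relative_length_change <- function(a, b) {
  if (any(b <= 0)) stop("long-isoform length must be > 0")
  (b - a) / b
}

#' Terminal-exon nascent-synthesis ratio
#'
#' Normalizes treated terminal-exon RPKM to untreated and log2-transforms
#' it, for the TSS-proximal (short-isoform) and TSS-distal (long-isoform)
#' terminal exons; the short/long ratio statistic is the difference of the
#' two log2 fold-changes (the log2 of the fold-change ratio).
#'
#' @param rpkm_prox_treated,rpkm_prox_untreated proximal terminal-exon
#'   RPKM in the two conditions.
#' @param rpkm_dist_treated,rpkm_dist_untreated distal terminal-exon RPKM.
#' @return list with `log2fc_proximal`, `log2fc_distal`, `ratio_statistic`,
#'   `undefined`.
#' @export
terminal_exon_ratio <- function(rpkm_prox_treated, rpkm_prox_untreated,
                                rpkm_dist_treated, rpkm_dist_untreated) {
  if (rpkm_prox_untreated <= 0 || rpkm_dist_untreated <= 0)
    return(list(log2fc_proximal = NA_real_, log2fc_distal = NA_real_,
                ratio_statistic = NA_real_, undefined = TRUE))
  lp <- log2(rpkm_prox_treated / rpkm_prox_untreated)
  ld <- log2(rpkm_dist_treated / rpkm_dist_untreated)
  list(log2fc_proximal = lp, log2fc_distal = ld,
       ratio_statistic = lp - ld, undefined = FALSE)
}
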