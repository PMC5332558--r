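## Two-isoform ALE read-count simulator and small assay-table fixtures.

#' Isoform-mixing configuration for the ALE count simulator
#'
#' @param psi_true named numeric vector, per-condition short-isoform
#'   (TSS-proximal terminal exon) fraction in \[0, 1\].
#' @param library_size expected reads per event per replicate.
#' @param n_replicates biological replicates per condition (default 2).
#' @param len_shared,len_proximal,len_distal effective lengths (bp) of the
#'   shared region and the proximal/distal terminal exons.
#' @param seed integer seed.
#' @return object of class `IsoformMixConfig`.
#' @export
isoform_mix_config <- function(psi_true = c(UN = 0.3, UV = 0.8),
                               library_size = 1e4, n_replicates = 2,
                               len_shared = 2000, len_proximal = 1000,
                               len_distal = 1000, seed = 1) {
  if (any(psi_true < 0 | psi_true > 1)) stop("psi_true must be in [0, 1]")
  if (is.null(names(psi_true))) stop("psi_true must be named by condition")
  if (library_size < 0) stop("library_size must be >= 0")
  structure(list(psi_true = psi_true, library_size = library_size,
                 n_replicates = n_replicates, len_shared = len_shared,
                 len_proximal = len_proximal, len_distal = len_distal,
                 seed = as.integer(seed)),
            class = "IsoformMixConfig")
}

#' Simulate ALE event read counts
#'
#' For each event, condition and replicate, draws Poisson counts for the
#' proximal terminal exon (rate proportional to `psi_true * len_proximal`),
#' the distal terminal exon (`(1 - psi_true) * len_distal`) and the shared
#' gene-body region (`len_shared`, traversed by both isoforms), scaled so
#' the expected total per event is `library_size`.
#'
#' @param n_events number of ALE events to simulate.
#' @param mix an `IsoformMixConfig`.
#' @return data.frame in the [quantify_events()] input layout: `event_id`,
#'   `gene_id`, `type`, `replicate`, `condition`, `count_inc` (proximal),
#'   `count_exc` (distal), `count_gene`, `len_inc`, `len_exc`.
#' @export
simulate_rnaseq_counts <- function(n_events, mix) {
  stopifnot(inherits(mix, "IsoformMixConfig"))
  conds <- names(mix$psi_true)
  with_seed(mix$seed, {
    rows <- list()
    for (ev in seq_len(n_events)) {
      for (cond in conds) {
        psi <- mix$psi_true[[cond]]
        w_prox <- psi * mix$len_proximal
        w_dist <- (1 - psi) * mix$len_distal
        w_gene <- mix$len_shared
        tot <- w_prox + w_dist + w_gene
        for (r in seq_len(mix$n_replicates)) {
          lam <- mix$library_size * c(w_prox, w_dist, w_gene) / tot
          cts <- rpois(3L, lam)
          rows[[length(rows) + 1L]] <- data.frame(
            event_id = sprintf("E%04d", ev),
            gene_id = sprintf("G%04d", ev),
            type = "ALE", replicate = r, condition = cond,
            count_inc = cts[1], count_exc = cts[2], count_gene = cts[3],
            len_inc = mix$len_proximal, len_exc = mix$len_distal,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate qPCR CT and per-nucleus intensity tables
#'
#' Fixtures for the assay statistics: a CT table whose target/reference
#' cycle values encode a configurable true fold change between a variable
#' and a control condition, and a per-nucleus intensity table drawn from a
#' two-component Gaussian mixture (low/high transcription states).
#'
#' @param seed integer seed.
#' @param true_fold_change treatment/control expression ratio encoded in
#'   the CT values.
#' @param ct_sd technical scatter of CT values (cycles).
#' @param n_ct_replicates CT replicates per condition.
#' @param n_nuclei nuclei per intensity sample.
#' @param mean_low,mean_high,sd_intensity mixture component means and
#'   common SD (arbitrary units).
#' @param weight_low mixing weight of the low-transcription component.
#' @return list with data.frames `ct` (`sample`, `replicate`, `ct_target`,
#'   `ct_reference`) and `intensity` (`sample`, `nucleus`, `intensity`,
#'   `component`).
#' @export
simulate_assay_tables <- function(seed = 1, true_fold_change = 4,
                                  ct_sd = 0, n_ct_replicates = 3,
                                  n_nuclei = 2000, mean_low = 100,
                                  mean_high = 1000, sd_intensity = 50,
                                  weight_low = 0.4) {
  if (weight_low < 0 || weight_low > 1) stop("weight_low must be in [0, 1]")
  with_seed(seed, {
    ## control: target 26 cycles, reference 18; treatment shifted by
    ## -log2(fold change) on the target
    ct <- do.call(rbind, lapply(c("control", "treated"), function(s) {
      shift <- if (s == "treated") -log2(true_fold_change) else 0
      data.frame(sample = s, replicate = seq_len(n_ct_replicates),
                 ct_target = 26 + shift + rnorm(n_ct_replicates, 0, ct_sd),
                 ct_reference = 18 + rnorm(n_ct_replicates, 0, ct_sd),
                 stringsAsFactors = FALSE)
    }))
    comp <- ifelse(runif(n_nuclei) < weight_low, "low", "high")
    mu <- ifelse(comp == "low", mean_low, mean_high)
    intensity <- data.frame(sample = "S1", nucleus = seq_len(n_nuclei),
                            intensity = rnorm(n_nuclei, mu, sd_intensity),
                            component = comp, stringsAsFactors = FALSE)
    list(ct = ct, intensity = intensity)
  })
}
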