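# polwave

Analysis of RNA polymerase II transcription-elongation kinetics and
alternative last exon (ALE) isoform switching from nascent-RNA
sequencing (GRO-seq) coverage.

## Who this is for

After UV-induced DNA damage, transcript elongation slows dramatically
while initiation continues, confining productive transcription to the
promoter-proximal region of genes and shifting expression toward short
mRNA isoforms that end in TSS-proximal alternative last exons. `polwave`
is for researchers quantifying either read-out from sequencing data:

- **Elongation rates from DRB-release GRO-seq.** Cells synchronized with
  the elongation inhibitor DRB and then released show a wave of engaged
  polymerase advancing into gene bodies. The package builds normalized
  strand-specific coverage, extracts TSS-anchored gene windows
  (−2 kb..+120 kb), calls the per-gene *wave-front* — the transition
  point where islands of depth ≥ 3 reads/bp give way to ≥ 5,000
  consecutive sub-threshold base pairs (internal exons masked) — filters
  the cohort (monotone progression, fronts within the TTS, expression
  and sustained-signal rules for recovery time courses), and converts
  median fronts into rates:

  pairwise: `rate = Δ(median front) / Δt` (kb/min)
  best fit: `rate = OLS slope of median front vs time`

- **Mathematically determined cohort fronts.** For slow kinetics the
  treated-minus-untreated meta-profile (per-bp 5% trimmed mean across
  genes) is loess-smoothed; the first downward zero crossing past the
  promoter is the front estimate, refined to the first point where the
  fitted derivative halves.

- **ALE isoform switching from count tables.** PSI (length-normalized
  inclusion fraction), a conjugate two-proportion Bayes factor for the
  sign of ΔPSI, and splicing-index effect sizes
  `log2((Exon_t/Gene_t)/(Exon_c/Gene_c))` (single-region events) and
  `log2((Exon2_t/Exon2_c)/(Exon1_t/Exon1_c))` (switch events), filtered
  across two biological replicates (reads > 10, BF > 10,
  |log2 SI| ≥ 0.25, consistent signs), with "short"/"long" direction
  calls and the isoform-length statistic `(b − a)/b`.

- **Small assay statistics.** Livak ΔΔCT fold changes, subcellular
  fraction enrichment `2^-(CT_f − CT_ref)`, and the EU-assay low/high
  transcription ratio.

A seeded synthetic-data generator (annotations, wave coverage with
configurable speeds, ALE count tables, assay tables) provides ground
truth for every stage, so the whole pipeline is testable without any
external sequencing data.

## Worked example

Simulate a DRB-release time course (untreated waves at 1.77 then
1.72 kb/min; UV-treated at 0.47 then 0.25 kb/min), call fronts and
estimate rates:

```r
library(polwave)

ann <- make_annotation(n_genes = 12, length_range = c(90000, 119000), seed = 42)
tx  <- select_transcripts(ann)              # longest transcript, >= 30 kb
kin <- wave_kinetics_config(seed = 42)      # default UV slow-down kinetics
reads <- simulate_groseq(ann, kin)

wbs <- list()
for (s in unique(as.character(S4Vectors::mcols(reads)$sample))) {
  rr  <- reads[S4Vectors::mcols(reads)$sample == s]
  trk <- build_coverage(rr, extension = 250, target_depth = length(rr))
  wbs[[s]] <- gene_windows(trk, tx, sample = s)
}
calls <- call_wavefronts(wbs, analysis_config())
filt  <- filter_gene_set(calls, tx)
keep  <- calls[calls$gene_id %in% filt$retained, ]
(med  <- tapply(keep$position, keep$sample, median_wavefront))
#> UN_t10 UN_t25 UN_t40 UV_t10 UV_t25 UV_t40
#>  17802  43632  69372   4813   8588  12314
round(pairwise_rate(med[["UN_t10"]], med[["UN_t25"]], 15), 2)  # 1.72 kb/min
round(pairwise_rate(med[["UV_t25"]], med[["UV_t40"]], 15), 2)  # 0.25 kb/min
```

The median fronts advance ~26 kb per 15 min untreated but only ~3.8 kb
after UV; the pairwise rates recover the configured interval speeds
(1.72 kb/min over 10–25 min untreated, 0.25 kb/min after UV) to within
the cohort sampling error.

An end-to-end run (simulation → coverage → fronts → rates → splicing →
assay, with a reproducibility manifest) is one call:

```r
demo_config("config.yaml", seed = 1)
run_pipeline("config.yaml", "results")
```

or from a shell via the thin wrapper `inst/scripts/polwave`:

```sh
Rscript inst/scripts/polwave run --config config.yaml --out results
```

## Layout

- `R/` — implementation: simulators (`synthetic-*.R`), coverage
  (`coverage.R`), wave-front caller and rates (`wavefront.R`),
  meta-profile fronts (`math-wavefront.R`), splicing (`splicing.R`),
  assay statistics (`assay-stats.R`), orchestration (`pipeline.R`).
- `tests/testthat/` — unit, property and cohort-level tests with
  independent oracles (naive pileup, gap enumeration, closed-form Beta
  comparison).
- `vignettes/polwave-methods.Rmd` — the model, its assumptions, tunable
  parameters, numerical choices and limitations.
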