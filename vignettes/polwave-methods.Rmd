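---
title: "Methods: wave-front calling, elongation rates and ALE quantification"
author: "polwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wave-front calling, elongation rates and ALE quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polwave)
```

## The scientific problem

After UV irradiation, RNA polymerase II continues to initiate but
elongates dramatically more slowly, restricting productive transcription
to the promoter-proximal tens of kilobases. Two genome-wide consequences
are measurable with nascent-RNA sequencing (GRO-seq):

1. **Elongation slow-down.** When cells are synchronized with the
   reversible elongation inhibitor DRB and then released, a "wave" of
   engaged polymerase sweeps into gene bodies. The furthest downstream
   position with sustained nascent signal — the *wave-front* — advances
   at the elongation rate. Comparing front positions across time points
   (with and without UV) turns coverage tracks into rates in kb/min.
2. **Isoform shortening.** Slow elongation favours usage of TSS-proximal
   alternative last exons (ALEs), shifting expression from long mRNAs to
   short isoforms terminating early in the gene.

`polwave` implements the full desk-side analysis for both read-outs,
plus a seeded synthetic-data generator so that every stage can be tested
against known ground truth without any external sequencing data.

## Coverage model

Aligned reads enter as stranded 1-bp 5' positions (BED6). Each read is
extended 250 bp in its 3' direction (`build_coverage()`, configurable)
and piled up per strand; depth is scaled to a common library size of
20 million reads (`target_depth / total mapped reads`). Duplicate reads
are kept and the denominator is the post-filter mapped-read count.
Analyses are restricted to genes with a transcript of at least 30 kb
(longest transcript per gene, ties broken by the lexicographically
smallest transcript id), a length at which a wave travelling ~1.8 kb/min
remains inside the gene for the whole 40-minute time course.

Per gene, a strand-oriented window from 2 kb upstream to 120 kb
downstream of the TSS (122,001 bp) is sliced out of the sense-strand
track; minus-strand genes are reversed so increasing offset always means
sense-direction travel. Cohort profiles are per-offset trimmed means
(`metagene()`, default trim 0.05, dropping `floor(n * trim)` genes from
each tail — with small cohorts this reduces to the plain mean).
Single-gene displays use `log2(1 + depth)` averaged in 500-bp bins with
a GCV-chosen smoothing spline. RPKM over an interval is
`reads * 1e9 / (width * total mapped reads)` with strand-matched
counting of the extended reads.

## Wave-front calling

`call_wavefront()` scans a gene window downstream from the TSS.
Positions with normalized depth ≥ 3 reads/bp form *islands* of
elongation evidence; we read the threshold's unit as normalized reads
per base pair. Once at least one island exists, the first run of 5,000
consecutive sub-threshold base pairs marks halted elongation, and the
front is the *transition point*: the last above-threshold position
before that gap (under this reading, gap start and island end coincide).
The 5-kb gap requirement filters background noise and signal from
downstream transcripts.

Internal exons are masked: mature-mRNA contamination produces sharp
exonic spikes that would otherwise seed false islands, and — equally
wrong — exonic bases could break a genuine gap. Masked bases therefore
neither extend islands nor count toward the gap. "Internal" means all
exons except the first and last in transcription order, capped at a
configurable 5 kb width (typical internal exons are far smaller than the
halt gap).

If signal runs to the window end without a qualifying gap, the front is
called at the last covered position and flagged `window_end`; the
cohort filter then removes fronts beyond the annotated TTS. Cohort
filters (`filter_gene_set()`) require fronts in every sample, strictly
increasing front positions over time within each condition
(configurable to non-strict), and no front beyond the TTS. In recovery
mode three further rules apply: expression (RPKM ≥ 0.3 over
TSS..+250 bp), sustained signal from +30 kb to 1 kb past the TTS
(operationalized as RPKM ≥ the same 0.3 threshold — no separate value
is standard for this filter), and a UV front upstream of the untreated
reference front. Manual curation of antisense/convergent interference
is replaced by an automated rule: `overlapping_genes()` flags genes
whose analysis window overlaps any other annotated gene body on either
strand, and flagged genes are dropped from wave-front cohorts. The
synthetic annotation spaces genes so windows never collide, so the rule
only bites on real annotations.

Rates come in two forms: `pairwise_rate()` divides the difference of
median front positions by the time interval (15 min between the
10/25/40-min points), and `fit_rate()` reports the ordinary
least-squares slope of median front against time.

## Mathematically determined fronts

For slow recovery kinetics (hours rather than minutes) per-gene islands
become noisy, so fronts are estimated at the cohort level. The treated
meta-profile minus the untreated meta-profile is positive near the TSS
(elevated proximal activity after UV) and negative downstream (deficit
beyond the stalled front). `loess_wavefront()` fits a degree-1 loess
curve, takes the first downward zero crossing past +1 kb (skipping the
promoter-peak sign flip) as the initial estimate, and refines it to the
first downstream position where the absolute derivative (central finite
differences at 100-bp resolution) has fallen to half its value at the
crossing; if it never halves, the refined estimate equals the initial
one and is flagged.

Open choices, decided here: the subtraction direction is
treated − untreated (both conventions locate the same crossing); the
derivative-half rule uses absolute values; the loess span defaults to
0.2 of the window but must be matched to the width of the proximal
excess region — for simulated recovery profiles whose excess spans only
a few kb we use span 0.05, since a 24-kb smoothing neighbourhood would
average away a 5-kb feature entirely. The crossing estimate carries a
constant geometry-dependent offset (smoothing an asymmetric step shifts
the zero), which cancels in the slope of front against time; recovery
of a 0.04 kb/min slope is accurate to a few percent even though
individual fronts are biased by ~1 kb.

## Splicing quantification

Events arrive as per-replicate, per-condition count tables (proximal
region, distal region, shared gene body, with effective lengths). PSI is
the length-normalized inclusion fraction. Evidence for a condition
effect uses a conjugate two-proportion model: each condition's
inclusion/exclusion read split receives an independent Beta(1,1)
posterior on the read-level inclusion probability, and the Bayes factor
is the posterior odds that ΔPSI has the observed sign (prior odds 1,
numeric quadrature between posterior quantile bounds). With effective
lengths shared across conditions the read-level probability is a
monotone transform of PSI, so the sign event coincides on both scales.
This is a deliberately simple, fully reproducible evidence measure with
the same decision surface (thresholds on reads, ΔPSI, Bayes factor) as
the original isoform-level Bayesian machinery it stands in for; it does
not model read assignment ambiguity.

Effect sizes are splicing indices: for single-region events (SE/RI),
`log2((exon_t/gene_t) / (exon_c/gene_c))`; for switch events
(AFE/ALE, and A5SS/A3SS restricted to variant-unique reads),
`log2((region2_t/region2_c) / (region1_t/region1_c))` with region 2 the
proximal/inclusion region, so a shift toward the short isoform is
positive. `filter_events()` retains events passing, in **both**
replicates: inclusion and exclusion reads > 10 (applied per replicate
in each condition), ΔPSI ≠ 0 with consistent sign, Bayes factor > 10,
and |log2 SI| ≥ 0.25 with consistent sign. ALE direction is "short"
when the proximal terminal exon's relative expression rises under
treatment. The isoform-length statistic is `(b − a)/b` for short/long
pre-mRNA lengths `a < b`; nascent-synthesis validation uses the
difference of terminal-exon log2 fold-changes (the log2 of the
fold-change ratio — a literal ratio of signed log values is ill-defined
near zero, so the difference form is used and documented as such).

## Assay statistics

Livak quantification: fold change `2^-ΔΔCT` with
`ΔΔCT = (CT_target − CT_ref)_variable − (CT_target − CT_ref)_control`;
replicates are averaged on the linear scale with SEM (geometric mean
optional). Fraction enrichment compares raw CTs between subcellular
fractions without reference-gene normalization. The EU (nascent RNA
labeling) low/high transcription ratio is the fraction of nuclei below
a low-intensity threshold divided by the fraction above a high
threshold, normalized to the control sample; thresholds are explicit
arguments because in practice they are set manually per experiment —
`suggest_thresholds()` proposes density valleys but never applies them.

## What the simulator does and does not emulate

`simulate_groseq()` emits 1-bp 5' read starts whose *extended* expected
depth is: a promoter-proximal peak (default 10 reads/bp over 600 bp,
matching DRB's restriction of polymerase to the first ~600 bp), a wave
plateau (default 5 reads/bp) from the TSS to `v·t`, uniform background,
and optional exonic contamination to exercise the caller's mask. Heights
are defined after the consumer's 250-bp extension, the same units as
the caller's threshold; with `extension = 1` and `noise = "none"` the
generator is exact per base pair, which the exactness tests use. Wave
speeds default to the characteristic values of this system: 1.77 and
1.72 kb/min untreated, 0.47 then 0.25 kb/min after UV. Poisson noise is
drawn per base pair; the deterministic mode emits cumulative-floor
counts so totals are preserved.

The wave is a step plateau, not the empirically decaying profile — the
simplest geometry with an unambiguous front. The generator does not
model sequencing error, mappability, antisense transcription, or
polymerase pausing beyond the promoter peak; passing the recovery tests
therefore demonstrates correctness of the *calling and rate machinery*,
not robustness to every artefact of real GRO-seq libraries. Gene
spacing (132 kb) keeps analysis windows disjoint, so the
antisense-interference filter is never triggered in simulation.

`simulate_rnaseq_counts()` draws Poisson counts per replicate with
expected proportions `ψ·len_prox : (1−ψ)·len_dist : len_shared` scaled
to a 10^4-read library — two biological replicates by default. The
filter-recovery tests use ψ = 0.3 untreated versus 0.8 after UV (a
strong ALE switch) against a ψ-equal null; at this depth the survival
criteria are ≥95% sensitivity and ≤5% null survivors, both met with
margin.

## Numerical choices and problem sizes

Quadrature for the Bayes factor integrates between the 1e-12 and
1−1e-12 posterior quantiles (`stats::integrate`, rel.tol 1e-10) and the
sign probability is capped at 1−1e-12, bounding reported Bayes factors
at ~1e12. Wave-speed recovery simulations use 50 genes of 90–119 kb and
six samples; slow-recovery simulations use 20 genes and five time
points (2–12 hr) — cohort sizes at which median fronts are stable to a
few hundred bp and a full run completes in about a minute on a laptop
core. The island caller is validated against an independent
gap-enumeration oracle on 1,000 random 20-kb windows, and the pileup,
trimmed mean and RPKM against naive reimplementations on 10^4-read
fixtures.

## Known limitations

- Real-data gene lists depend on genome build, annotation version and
  manual curation and are not reproduced here; cohort-level parameter
  recovery on simulations substitutes for them.
- The Bayes factor stand-in ignores read-assignment uncertainty and
  junction-read structure.
- The sustained-signal filter threshold reuses the expression RPKM
  cutoff (0.3) in the absence of a published value.
- Loess span must be chosen commensurate with the width of the
  proximal-excess region; no automatic span selection is attempted.
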