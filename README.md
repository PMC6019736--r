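# mpiseq

Quantify Microprocessor (Drosha/DGCR8) activity at pri-miRNA loci from
chromatin-associated RNA-seq.

When Drosha excises a pre-miRNA hairpin co-transcriptionally, the hairpin
leaves the chromatin-bound RNA fraction while the flanking host-transcript
sequence lingers, so read coverage dips over the precursor relative to its
flanks. `mpiseq` measures that dip as the **Microprocessor processing
index**: with `n1`, `n`, `n2` the maximum read depths in the transcript-5′
shoulder, the trimmed precursor, and the transcript-3′ shoulder (shoulders
are fixed 100-base intervals abutting the Drosha cleavage sites), and a
pseudocount `c = 1`,

    MPI = log2( (n + c) / (((n1 + c) + (n2 + c)) / 2) )

Cleaved loci have negative MPI; values near zero mean no processing.
Between a treated and a mock condition,

    log2FC MPI = MPI(treated) − MPI(mock)

is positive when processing is lost. Loci passing three filters (shoulder
maximum ≥ 30 reads on each side in mock; not on the mirtron/non-DGCR8
exclusion list; MPI(mock) < 0) are classified *less processed*
(log2FC ≥ 0.5), *more processed* (≤ −0.5) or *equally processed*. The
package also scans the classic Microprocessor determinants (UG at −14/−13
of the 5′ cleavage site, CNNC at +16/+18 of the 3′ site, UGU at the
5p/loop boundary) as cleavage-site-anchored frequency profiles with Fisher
enrichment between classes, tests host-transcript expression (scale to
lowest total → log2 → quantile normalize → Welch + BH) as a transcription
control, and ships a seeded read simulator with known processing
efficiencies so the whole chain is verifiable end to end.

It is written for transcriptomics analysts who have aligned
chromatin-associated libraries (per-sample BED/bedGraph evidence plus a
miRBase-like annotation) and want a tested, reusable implementation of
the index, its filters, and the surrounding analyses.

## Worked example

The numbered scripts under `analysis/` run the full study on a simulated
cohort: 200 loci whose true log2FC MPI is +1 / 0 / −1 for 60 / 120 / 20
loci (plus 5 exclusion-list loci), 4 replicates per condition, flank depth
~200, and a basal UG planted at −14 in 60% of the "less processed" class
versus 8% of the "equally processed" class.

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_processing_index.R
Rscript analysis/03_motif_analysis.R
Rscript analysis/04_host_expression.R
```

Stage 2 prints:

```
loci analysed: 205, surviving all filters: 200
   less_processed equally_processed    more_processed          excluded
               60               120                20                 5
mock MPI means: less -0.931 vs equal -0.935 (t = 0.39, p = 0.696)
label recovery on filtered loci: 100.0% (n = 200)
```

All 200 filtered loci recover their true class under the ±0.5 rule; the
5 exclusion-list loci are removed by filter 2; mock MPI ≈ −0.93 per group
matches the simulated mock efficiency p = 0.5 (log2(1 − p) = −1, shifted
slightly by the maximum-depth statistic and the pseudocount). Stage 3
prints, per motif, group frequencies in the canonical window and Fisher
enrichment:

```
TG   @ cut5   [-14..-13]: freq 0.667 vs 0.167, OR 10.00, Fisher p 3.94e-11
CNNC @ cut3   [+16..+18]: freq 0.217 vs 0.125, OR 1.94, Fisher p 0.129
TGT  @ loop5p [-2..+2]: freq 0.083 vs 0.133, OR 0.59, Fisher p 0.461
```

— the planted UG is strongly enriched in the less-processed class while
the unplanted motifs show only background. Stage 4 confirms the control:
host transcripts were simulated with constant transcription and the
expression test rejects at ~0.034 (nominal 0.05), with 0 BH-significant
transcripts, even though 80 of those loci changed processing.

The same machinery is callable directly:

```r
library(mpiseq)
b <- simulate_cohort(cohort_design(), n_replicates = 4, seed = 1)
out <- run_mpi_pipeline(b, out_dir = "results/pipeline")
out$mpi$summary$class_counts
```

On real data, point `run_mpi_pipeline()` at a directory holding
`annotation.tsv`, `reads_<sample>.bed`, `conditions.tsv`, `exclusion.txt`
and optionally `sequences.fa` + `anchors.tsv` and `host_counts.tsv`
(see `?load_cohort` for the layout).

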