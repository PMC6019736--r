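---
title: "Quantifying Microprocessor activity from chromatin-associated RNA-seq"
author: "mpiseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Microprocessor activity from chromatin-associated RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpiseq)
```

## The measurement problem

The Microprocessor (the Drosha/DGCR8 complex) excises pre-miRNA hairpins
from primary miRNA transcripts co-transcriptionally. In RNA that is still
associated with chromatin, a locus whose hairpin is being cleaved shows a
characteristic coverage footprint: read depth over the hairpin (precursor)
region is depleted relative to the host-transcript sequence immediately
flanking it, because the excised hairpin leaves the chromatin fraction
while the flanking cleavage products linger. `mpiseq` turns that footprint
into a per-locus index, compares it between two conditions (a mock and a
treated library set), and asks which sequence determinants distinguish the
loci that respond.

## The Microprocessor processing index

For each locus we take the trimmed precursor region $N$ and two fixed
100-base shoulder regions $N_1$ (transcript-5′) and $N_2$ (transcript-3′)
that abut it. With $n_1, n, n_2$ the **maximum** per-base read depth in
each region and pseudocount $c = 1$,

$$\mathrm{MPI} \;=\; \log_2 \frac{n + c}{\big((n_1 + c) + (n_2 + c)\big)/2}.$$

Processing depletes the precursor, so cleaved loci have negative MPI and
values near zero indicate no processing. The differential index is

$$\log_2\mathrm{FC\ MPI} \;=\; \mathrm{MPI}_{\mathrm{treated}} - \mathrm{MPI}_{\mathrm{mock}},$$

positive when processing is lost under treatment. Loci are classified with
a half-width of 0.5 log2 units: $\ge +0.5$ *less processed*, $\le -0.5$
*more processed*, the open band between *equally processed* (both extreme
thresholds inclusive).

Three selection filters precede classification:

1. **expression** — the mock shoulder maximum must reach 30 reads on each
   side of the hairpin (by default the mean across mock replicates of each
   shoulder maximum; a stricter every-replicate mode is available);
2. **exclusion list** — annotated mirtrons and miRNAs that do not bind
   DGCR8 are removed by name;
3. **processed in mock** — the locus must actually be cleaved at baseline,
   $\mathrm{MPI}_{\mathrm{mock}} < 0$ (strict).

Precursor boundaries come from trimming each hairpin to its mature-arm
annotation: everything transcript-upstream of the 5′ end of the 5p mature
arm and transcript-downstream of the 3′ end of the 3p arm is removed;
when an arm is unannotated the corresponding hairpin end is kept. The
trimmed ends are the Drosha cleavage sites, which also anchor the motif
analysis. All coordinates are 0-based half-open internally and in BED
output; the annotation reader converts 1-based inclusive input on request.

### Design choices worth knowing

* **Sign convention.** The index is precursor-over-shoulder, so that
  cleavage gives negative values; the alternative (inverted) ratio only
  flips signs and the classification map.
* **Flank combiner.** The two shoulder maxima are combined by their mean;
  `min` and `max` are available. The mean is symmetric and robust to one
  noisy shoulder without discarding it.
* **Replicate aggregation.** Each replicate yields its own MPI and the
  condition value is their arithmetic mean. Pooling depths first
  (`replicate_mode = "pooled_depth"`) weights replicates by depth instead;
  both are exposed because neither is canonical.
* **Pseudocount.** $c = 1$ read keeps the index finite when the precursor
  drops to zero depth. At shoulder depths around 200 it perturbs the index
  by ~0.02; it is configurable.
* **Group comparison.** Mock MPI distributions of the less- and
  equally-processed classes are compared with a two-sided pooled-variance
  Student's t-test. Zero pooled variance with equal means returns
  $t = 0, p = 1$; with unequal means it returns $p = 0$ with a warning
  rather than dividing by zero.

## Motif conventions

The scanner reports IUPAC matches (U and T equivalent, `N` any base) by
the offset of the match **start** relative to an anchor, with the anchor
base at offset 0 and the base immediately 5′ of it at −1. Anchors are the
5′ cleavage site (`cut5`, first precursor base), the 3′ cleavage site
(`cut3`, first base after the precursor) and the 5p/terminal-loop boundary
(`loop5p`). Under this convention the canonical determinants sit at their
familiar positions: the basal UG at −14/−13 from `cut5`, CNNC at +16/+18
from `cut3`, and UGU within ±2 of `loop5p` (the UGU window is
configurable; the boundary position is annotation-dependent).

Group profiles are per-offset match fractions smoothed with a centered
sliding window of 3 (edges average the neighbors actually available, so a
constant profile is unchanged). The published "weighted frequency" track
this emulates is not fully specified by its source; the moving-average
reading is documented here as the package's interpretation. Group
enrichment uses the sample (cross-product) odds ratio on the 2×2
match/no-match table over a motif's canonical window and a two-sided
Fisher exact p-value.

## Host-transcript control

An apparent processing change could instead be a transcription change of
the host gene. The control chain normalizes per-transcript counts —
scaling every sample to the lowest library total, $\log_2(x+1)$, then
classic quantile normalization — and tests treated vs mock per transcript
with an ordinary Welch test, BH-adjusted. A moderated linear-model test
would also fit here; the plain two-sample test keeps the chain fully
self-contained and is slightly conservative at $n = 4$ per group
(empirical type-I error ≈ 0.04 at $\alpha = 0.05$ in the suite's null
simulations). Quantile normalization follows the textbook definition
(rank-r values replaced by the mean r-th order statistic): it is exactly
idempotent and equalizes sorted columns on tie-free data; tied values
receive the mean of the reference over their rank range, which is why
those two properties hold only approximately on heavily tied integer
matrices.

## What the simulator emulates

`simulate_cohort()` generates the complete input bundle — annotation,
per-sample read BEDs, transcript-oriented sequences with cleavage-site
anchors, an exclusion list, a host count matrix and a truth table — from a
generative model with one parameter of interest per condition: the
processing efficiency $p$, the fraction of transcripts whose hairpin has
been excised.

* Unprocessed molecules (probability $1 - p$) contribute reads uniformly
  across the locus window; processed molecules contribute reads only to
  the flanks, never crossing a cleavage site (both cleavage products are
  retained on chromatin — a modeling choice, not a biological claim).
* Molecule counts are Poisson and placement is uniform over a window
  padded by one read length, so expected depth is $\lambda$ (default 200)
  in the shoulders and $(1-p)\lambda$ in the precursor, and the pipeline's
  index estimates $\log_2(1-p)$.
* Defaults mirror the analysis conditions: read length 50, 100-base
  shoulders, 70-base precursors, 4 replicates per condition, and a
  three-class cohort (60 loci with true $\log_2$FC MPI $+1$, 120 with 0,
  20 with $-1$; $p_{\mathrm{mock}} = 0.5$ throughout, so every locus is
  cleaved at baseline). Truth MPIs use $\log_2(1 - p + 2^{-10})$ so the
  $p = 1$ limit stays finite.
* Motif plants place a motif at an exact offset in a chosen fraction of a
  class and scrub it at that offset elsewhere, so group frequencies equal
  the instructed rates at the planted position (background occurrences at
  *other* offsets remain).
* Host counts are drawn Poisson with condition-invariant means: the
  hairpin is a negligible fraction of a host transcript's footprint, so
  constant transcription is modeled directly rather than re-derived from
  the locus reads.

The simulator does **not** emulate mappability, GC or fragmentation
biases, overdispersion beyond Poisson (a negative-binomial stress mode is
the natural extension), spliced reads, overlapping loci, or annotation
errors. Passing tests therefore demonstrate that the pipeline's
arithmetic, conventions and decision rules are correct under a faithful
coverage model — not that real chromatin libraries are free of those
complications.

## Numerical behavior and known limitations

* **Extreme-value bias of the maximum.** Using the regional *maximum*
  depth makes each region's statistic sit a little above its mean depth
  (roughly $+b\sqrt{\mu}$ with $b \approx 0.8$–$1.2$ for these region
  sizes). The excess is relatively larger in the depleted precursor
  ($\mu = (1-p)\lambda$) than in the shoulders ($\mu = \lambda$), so the
  estimated index is slightly compressed toward zero at strong
  processing: at $\lambda = 200$ and $p = 0.75$ the mean estimate is
  about $-1.87$ against the ideal $-2.0$. In efficiency units the error
  stays small ($\hat p = 1 - 2^{\mathrm{MPI}}$ is within ~0.03 of truth),
  and the mock-vs-treated *difference* cancels most of the bias when
  depths are comparable — which is why classification recovery is
  unaffected. The acceptance suite records this arm honestly rather than
  masking it.
* **Ties at the class boundaries** go to the extreme classes (thresholds
  inclusive).
* **Degenerate inputs.** Loci whose shoulders would cross coordinate 0
  are rejected, not truncated; malformed annotation rows are skipped and
  reported with line numbers; regions outside a coverage track raise an
  error rather than clipping.
* **Problem sizes.** The suite and the acceptance script run cohorts of
  200–205 loci with 4 replicates per condition (~0.2 M reads per sample),
  50-seed closed-form checks, and 1,000-transcript null calibrations —
  sizes chosen so the full analysis reruns from scratch in about a
  minute on a laptop while keeping Monte-Carlo error well inside the
  asserted bands.

## Reading the pipeline output

`run_mpi_pipeline()` returns (and optionally writes) the regions BED, the
depth-triple table, the per-locus MPI records with filter flags and
labels, per-motif profiles and enrichment for the less- vs
equally-processed groups, the host-transcript test table, and a JSON
manifest whose every number is recomputable from the stage tables it
cites. The numbered scripts under `analysis/` run exactly this sequence
on a seeded simulated cohort and narrate what they find.
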