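#!/usr/bin/env Rscript

# Stage 1: generate the study cohort.
#
# 200 pri-miRNA loci with known Drosha processing efficiencies under two
# conditions (60 lose processing after treatment, 120 unchanged, 20 gain),
# 4 replicates per condition at flank depth ~200 reads, plus a basal UG
# planted at -14 of the 5' cleavage site in 60% of the "less processed"
# group versus 8% of the "equally processed" group. The full read bundle
# (BED per sample, annotation, sequences, anchors, exclusion list, host
# counts, truth table) lands under scratch/sim/ in exactly the formats the
# real-data pipeline consumes.

suppressPackageStartupMessages(library(mpiseq))

seed <- 20240917
out_dir <- "scratch/sim"

specs <- cohort_design(n_less = 60, n_equal = 120, n_more = 20,
                       n_excluded = 5, lambda = 200)
plant <- data.frame(motif = "TG", anchor = "cut5", offset = -14,
                    rate = c(0.60, 0.08),
                    class = c("less_processed", "equally_processed"),
                    stringsAsFactors = FALSE)
bundle <- simulate_cohort(specs, n_replicates = 4, seed = seed,
                          plant = plant)
paths <- write_cohort(bundle, out_dir)

n_reads <- vapply(bundle$reads, nrow, integer(1))
cat(sprintf("cohort: %d loci (%d on the exclusion list), %d samples\n",
            nrow(specs), length(bundle$exclusion_list),
            length(bundle$reads)))
cat(sprintf("reads per sample: %d-%d (median %d)\n",
            min(n_reads), max(n_reads), as.integer(median(n_reads))))
cat(sprintf("truth: %s\n",
            paste(names(table(bundle$truth$true_label)),
                  table(bundle$truth$true_label), collapse = ", ")))
cat("wrote", length(paths), "files under", out_dir, "\n")
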