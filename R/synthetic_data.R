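# Seeded simulator of chromatin-associated reads over pri-miRNA loci.
#
# Generative model: a locus transcribes molecules at a rate set by `lambda`
# (expected flank read depth). With probability 1 - p the molecule is still
# unprocessed and contributes reads uniformly across the whole locus window;
# with probability p the Microprocessor has excised the hairpin, the two
# cleavage products remain on chromatin, and reads fall only in the flanks,
# never crossing a cleavage site. Expected interior depths are therefore
# lambda in the shoulders and (1 - p) * lambda in the precursor, so the
# pipeline's MPI estimates log2(1 - p). Reads are drawn over a window padded
# by one read length on each side so coverage is stationary across the
# analysed regions; molecule counts are Poisson and read placement uniform.

#' Specification of one simulated pri-miRNA locus
#'
#' @param name locus name (also used as its contig name).
#' @param p_mock,p_treated Microprocessor processing efficiency in the two
#'   conditions: the fraction of transcripts whose hairpin has been excised.
#' @param lambda expected flank read depth (reads), default 200.
#' @param precursor_len trimmed precursor length in bases (default 70).
#' @param shoulder_len shoulder length (default 100).
#' @param strand locus strand.
#' @param excluded marks a simulated mirtron/non-DGCR8 locus that belongs on
#'   the exclusion list.
#' @return one-row data.frame.
#' @export
locus_spec <- function(name, p_mock, p_treated, lambda = 200,
                       precursor_len = 70, shoulder_len = 100,
                       strand = "+", excluded = FALSE) {
  stopifnot(p_mock >= 0, p_mock <= 1, p_treated >= 0, p_treated <= 1,
            lambda > 0, precursor_len > 0, shoulder_len >= 1)
  data.frame(name = name, p_mock = p_mock, p_treated = p_treated,
             lambda = lambda, precursor_len = precursor_len,
             shoulder_len = shoulder_len, strand = strand,
             excluded = excluded, stringsAsFactors = FALSE)
}

#' Default cohort design
#'
#' Loci in three differential-processing classes with true log2FC MPI +1
#' (less processed after treatment), 0 and -1, all cleaved in mock
#' (p_mock = 0.5 so true mock MPI = -1), plus optional excluded
#' (mirtron-like) loci.
#'
#' @param n_less,n_equal,n_more class sizes (default 60/120/20).
#' @param n_excluded loci flagged for the exclusion list (default 0).
#' @param lambda expected flank depth (default 200).
#' @return specs data.frame (rbind of [locus_spec()] rows) with a
#'   `true_class` column.
#' @export
cohort_design <- function(n_less = 60, n_equal = 120, n_more = 20,
                          n_excluded = 0, lambda = 200) {
  n <- n_less + n_equal + n_more + n_excluded
  p_treated <- c(rep(0, n_less), rep(0.5, n_equal), rep(0.75, n_more),
                 rep(0.5, n_excluded))
  cls <- c(rep("less_processed", n_less), rep("equally_processed", n_equal),
           rep("more_processed", n_more), rep("equally_processed", n_excluded))
  specs <- do.call(rbind, lapply(seq_len(n), function(i) {
    locus_spec(sprintf("sim-mir-%03d", i), p_mock = 0.5,
               p_treated = p_treated[i], lambda = lambda,
               strand = if (i %% 2 == 0) "-" else "+",
               excluded = i > n_less + n_equal + n_more)
  }))
  specs$true_class <- cls
  specs
}

.locus_geometry <- function(spec, read_len) {
  p_start <- 1000
  p_end <- p_start + spec$precursor_len
  w1 <- p_start - spec$shoulder_len
  w2 <- p_end + spec$shoulder_len
  list(precursor_start = p_start, precursor_end = p_end,
       window = c(w1, w2), pad = read_len)
}

#' Simulate chromatin-associated reads for one locus and one sample
#'
#' @param spec one-row specs data.frame ([locus_spec()]).
#' @param p processing efficiency for this sample's condition.
#' @param read_len read length (default 50); must not exceed the shoulder
#'   length.
#' @return data.frame of read intervals (`chrom`, `start`, `end`, `strand`),
#'   0-based half-open, on the locus contig. Uses the current RNG state;
#'   seed via `set.seed()` or [simulate_cohort()].
#' @export
simulate_locus_reads <- function(spec, p, read_len = 50) {
  stopifnot(p >= 0, p <= 1)
  if (read_len > spec$shoulder_len) {
    stop("read_len exceeds shoulder length; flank-only reads cannot fit")
  }
  g <- .locus_geometry(spec, read_len)
  w1 <- g$window[1]; w2 <- g$window[2]
  # full-length molecules: uniform starts over the padded window
  lo_full <- w1 - read_len; hi_full <- w2 + read_len - read_len  # last start
  n_starts_full <- hi_full - lo_full + 1
  n_full <- stats::rpois(1, (1 - p) * spec$lambda * n_starts_full / read_len)
  starts <- if (n_full > 0) {
    sample.int(n_starts_full, n_full, replace = TRUE) + lo_full - 1L
  } else integer(0)
  # processed molecules: cleavage products end exactly at the cut sites, so
  # reads fit entirely 5' of precursor_start or 3' of precursor_end
  lo_l <- w1 - read_len; hi_l <- g$precursor_start - read_len
  lo_r <- g$precursor_end; hi_r <- w2 + read_len - read_len
  for (side in list(c(lo_l, hi_l), c(lo_r, hi_r))) {
    ns <- side[2] - side[1] + 1
    k <- stats::rpois(1, p * spec$lambda * ns / read_len)
    if (k > 0) {
      starts <- c(starts,
                  sample.int(ns, k, replace = TRUE) + side[1] - 1L)
    }
  }
  data.frame(chrom = rep(spec$name, length(starts)),
             start = as.numeric(starts), end = as.numeric(starts) + read_len,
             strand = rep(spec$strand, length(starts)),
             stringsAsFactors = FALSE)
}

.realize_iupac <- function(pattern) {
  pat <- strsplit(toupper(.norm_seq(pattern)), "")[[1]]
  paste(vapply(pat, function(p) {
    opts <- IUPAC_SETS[[p]]
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

#' Plant a concrete motif instance into a sequence
#'
#' Overwrites the bases starting at `anchor_index + offset` (0-based,
#' match-start offset convention) with a realization of the IUPAC pattern.
#'
#' @param sequence nucleotide string.
#' @param motif IUPAC pattern.
#' @param anchor_index 0-based anchor position in the sequence.
#' @param offset match-start offset relative to the anchor.
#' @return modified sequence.
#' @export
plant_motif <- function(sequence, motif, anchor_index, offset) {
  start <- anchor_index + offset  # 0-based
  k <- nchar(motif)
  if (start < 0 || start + k > nchar(sequence)) {
    stop("motif plant window outside sequence")
  }
  inst <- .realize_iupac(motif)
  paste0(substr(sequence, 1, start), inst,
         substr(sequence, start + k + 1, nchar(sequence)))
}

# Ensure the motif does NOT match at the given offset (so plant rates are
# exact): mutate the first matching base to one outside its IUPAC set.
.scrub_motif <- function(sequence, motif, anchor_index, offset) {
  start <- anchor_index + offset
  if (!match_iupac(motif, sequence, start)) return(sequence)
  pat <- strsplit(toupper(.norm_seq(motif)), "")[[1]]
  allowed <- IUPAC_SETS[[pat[1]]]
  repl <- setdiff(c("A", "C", "G", "T"), allowed)[1]
  paste0(substr(sequence, 1, start), repl,
         substr(sequence, start + 2, nchar(sequence)))
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
        collapse = "")
}

#' Simulate a full pri-miRNA cohort
#'
#' Generates, for every locus in `specs` and every replicate of the mock and
#' treated conditions, chromatin-associated reads plus the matching
#' annotation, transcript-oriented sequences with cleavage-site anchors, an
#' exclusion list, a condition-invariant host-transcript count matrix, and
#' the truth table of expected MPIs and class labels.
#'
#' @param specs specs data.frame ([cohort_design()] or rbind of
#'   [locus_spec()] rows); names must be unique.
#' @param n_replicates replicates per condition (default 4).
#' @param read_len read length (default 50).
#' @param seed optional integer seed; with a seed the bundle is fully
#'   deterministic.
#' @param plant optional data.frame of plant instructions with columns
#'   `motif`, `anchor` (cut5/cut3/loop5p), `offset`, `rate`, and optional
#'   `class` (restrict to one true class). At each instructed position the
#'   motif is planted in exactly `round(rate * n)` of the eligible loci and
#'   scrubbed from the rest, so group frequencies equal the rates.
#' @param host_mean expected host-transcript count per sample (default 1000);
#'   identical in both conditions (constant transcription).
#' @return list: `specs`, `annotation` (hairpin records), `regions`,
#'   `sequences` (named character, transcript orientation), `anchors`
#'   (data.frame locus/cut5/cut3/loop5p, 0-based), `reads` (named list of
#'   per-sample read data.frames), `conditions` (named vector),
#'   `exclusion_list`, `host_counts` (loci x samples), `truth`.
#' @export
simulate_cohort <- function(specs, n_replicates = 4, read_len = 50,
                            seed = NULL, plant = NULL, host_mean = 1000) {
  if (anyDuplicated(specs$name)) stop("duplicate locus names in specs")
  if (!is.null(seed)) set.seed(seed)
  mature_len <- 22
  samples <- c(sprintf("mock_%d", seq_len(n_replicates)),
               sprintf("treated_%d", seq_len(n_replicates)))
  conditions <- stats::setNames(rep(c("mock", "treated"),
                                    each = n_replicates), samples)

  ann <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    g <- .locus_geometry(s, read_len)
    ps <- g$precursor_start; pe <- g$precursor_end
    plus <- s$strand == "+"
    data.frame(name = s$name, chrom = s$name,
               hairpin_start = ps - 8, hairpin_end = pe + 8,
               strand = s$strand,
               mature5p_start = if (plus) ps else pe - mature_len,
               mature5p_end = if (plus) ps + mature_len else pe,
               mature3p_start = if (plus) pe - mature_len else ps,
               mature3p_end = if (plus) pe else ps + mature_len,
               stringsAsFactors = FALSE)
  })
  annotation <- do.call(rbind, ann)
  regions <- build_regions(trim_hairpin(annotation),
                           shoulder_len = specs$shoulder_len[1])

  # transcript-oriented sequences spanning the padded window, with anchors
  seqs <- character(nrow(specs))
  anchors <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    g <- .locus_geometry(s, read_len)
    g1 <- g$window[1] - read_len; g2 <- g$window[2] + read_len
    genomic <- .random_seq(g2 - g1)
    tx <- if (s$strand == "+") genomic else .revcomp(genomic)
    cut5 <- if (s$strand == "+") g$precursor_start - g1
            else g2 - g$precursor_end
    anchors[[i]] <- data.frame(locus = s$name, cut5 = cut5,
                               cut3 = cut5 + s$precursor_len,
                               loop5p = cut5 + mature_len,
                               stringsAsFactors = FALSE)
    seqs[i] <- tx
  }
  names(seqs) <- specs$name
  anchors <- do.call(rbind, anchors)

  if (!is.null(plant)) {
    for (j in seq_len(nrow(plant))) {
      pl <- plant[j, ]
      eligible <- if (!is.null(pl$class) && !is.na(pl$class) &&
                      !is.null(specs$true_class)) {
        which(specs$true_class == pl$class)
      } else seq_len(nrow(specs))
      k <- round(pl$rate * length(eligible))
      chosen <- sample(eligible, k)
      for (i in eligible) {
        a <- anchors[i, ][[pl$anchor]]
        seqs[i] <- if (i %in% chosen) {
          plant_motif(seqs[i], pl$motif, a, pl$offset)
        } else {
          .scrub_motif(seqs[i], pl$motif, a, pl$offset)
        }
      }
    }
  }

  reads <- lapply(samples, function(smp) {
    p_col <- if (conditions[smp] == "mock") "p_mock" else "p_treated"
    do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
      simulate_locus_reads(specs[i, ], specs[[p_col]][i], read_len)
    }))
  })
  names(reads) <- samples

  host_counts <- matrix(stats::rpois(nrow(specs) * length(samples),
                                     host_mean),
                        nrow = nrow(specs),
                        dimnames = list(specs$name, samples))

  list(specs = specs, annotation = annotation, regions = regions,
       sequences = seqs, anchors = anchors, reads = reads,
       conditions = conditions,
       exclusion_list = specs$name[specs$excluded],
       host_counts = host_counts,
       truth = truth_table(specs))
}

#' Expected MPIs and class labels of a cohort design
#'
#' Deterministic truth for a specs table: expected mock/treated MPI is
#' log2(1 - p + eps) with a small eps keeping the p = 1 limit finite;
#' labels follow the same +/-0.5 rule as [classify_mpi()].
#'
#' @param specs specs data.frame.
#' @param eps floor inside the log (default 2^-10).
#' @param class_threshold classification half-width (default 0.5).
#' @return data.frame: `locus`, `expected_mpi_mock`, `expected_mpi_treated`,
#'   `expected_log2fc`, `true_label`.
#' @export
truth_table <- function(specs, eps = 2^-10, class_threshold = 0.5) {
  em <- log2(1 - specs$p_mock + eps)
  et <- log2(1 - specs$p_treated + eps)
  data.frame(locus = specs$name,
             expected_mpi_mock = em, expected_mpi_treated = et,
             expected_log2fc = et - em,
             true_label = as.character(classify_mpi(et - em,
                                                    class_threshold)),
             stringsAsFactors = FALSE)
}

#' Write a simulated cohort bundle to disk
#'
#' Emits exactly the plain-text formats the real-input pipeline consumes:
#' annotation TSV, per-sample read BEDs, hairpin+flank FASTA, anchors TSV,
#' exclusion list, host-count TSV, condition map and truth table.
#'
#' @param bundle output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(annotation = file.path(dir, "annotation.tsv"),
             fasta = file.path(dir, "sequences.fa"),
             anchors = file.path(dir, "anchors.tsv"),
             exclusion = file.path(dir, "exclusion.txt"),
             host_counts = file.path(dir, "host_counts.tsv"),
             conditions = file.path(dir, "conditions.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_mirna_annotation(bundle$annotation, paths["annotation"])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bundle$sequences), paths["fasta"])
  utils::write.table(bundle$anchors, paths["anchors"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(bundle$exclusion_list, paths["exclusion"])
  utils::write.table(data.frame(locus = rownames(bundle$host_counts),
                                bundle$host_counts, check.names = FALSE),
                     paths["host_counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = names(bundle$conditions),
                                condition = unname(bundle$conditions)),
                     paths["conditions"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (smp in names(bundle$reads)) {
    p <- file.path(dir, sprintf("reads_%s.bed", smp))
    write_bed_reads(bundle$reads[[smp]], p)
    paths[paste0("reads_", smp)] <- p
  }
  invisible(paths)
}
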