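# End-to-end orchestration: regions -> depth triples -> MPI/classification
# -> motif profiles -> host-transcript differential test, with a
# machine-readable JSON manifest. Works on an in-memory cohort bundle
# (simulate_cohort) or a directory holding the same files (write_cohort
# layout, which mirrors the real-input formats).

#' Load a cohort directory into a bundle
#'
#' Reads the file layout written by [write_cohort()]: `annotation.tsv`,
#' `reads_<sample>.bed`, `conditions.tsv`, `exclusion.txt`, and, when
#' present, `sequences.fa` + `anchors.tsv` and `host_counts.tsv`.
#'
#' @param dir directory path.
#' @return bundle list as from [simulate_cohort()] (without `specs`/`truth`
#'   unless a `truth.tsv` is present).
#' @export
load_cohort <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input file: ", p)
    p
  }
  annotation <- read_mirna_annotation(need("annotation.tsv"))
  cond_tab <- utils::read.table(need("conditions.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  conditions <- stats::setNames(cond_tab$condition, cond_tab$sample)
  reads <- lapply(cond_tab$sample, function(s) {
    read_bed_reads(need(sprintf("reads_%s.bed", s)))
  })
  names(reads) <- cond_tab$sample
  excl_path <- file.path(dir, "exclusion.txt")
  exclusion <- if (file.exists(excl_path)) readLines(excl_path) else character()
  bundle <- list(annotation = annotation, reads = reads,
                 conditions = conditions,
                 exclusion_list = exclusion[nzchar(exclusion)])
  fa <- file.path(dir, "sequences.fa")
  anc <- file.path(dir, "anchors.tsv")
  if (file.exists(fa) && file.exists(anc)) {
    ss <- Biostrings::readDNAStringSet(fa)
    bundle$sequences <- stats::setNames(as.character(ss), names(ss))
    bundle$anchors <- utils::read.table(anc, header = TRUE, sep = "\t",
                                        stringsAsFactors = FALSE)
  }
  hc <- file.path(dir, "host_counts.tsv")
  if (file.exists(hc)) {
    tab <- utils::read.table(hc, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    bundle$host_counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(bundle$host_counts) <- tab[[1]]
  }
  truth <- file.path(dir, "truth.tsv")
  if (file.exists(truth)) {
    bundle$truth <- utils::read.table(truth, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE)
  }
  bundle
}

#' Anchored sequences for a set of loci
#'
#' Joins a named sequence vector with an anchors table into the list
#' structure the motif scanner consumes.
#'
#' @param sequences named character vector (transcript orientation).
#' @param anchors data.frame: `locus`, `cut5`, `cut3`, `loop5p` (0-based).
#' @param loci optional subset of locus names.
#' @return list of anchored sequences.
#' @export
anchored_sequences <- function(sequences, anchors, loci = NULL) {
  if (is.null(loci)) loci <- anchors$locus
  loci <- intersect(loci, intersect(anchors$locus, names(sequences)))
  lapply(loci, function(l) {
    a <- anchors[anchors$locus == l, ]
    anchored_sequence(list(locus = l, sequence = unname(sequences[l]),
                           cut5 = a$cut5, cut3 = a$cut3, loop5p = a$loop5p))
  })
}

#' Run the full processing-index pipeline
#'
#' Builds regions from the annotation, extracts maximum regional depth
#' triples for every sample, computes MPI / log2FC MPI with the three
#' selection filters and the class rule, compares mock MPIs between the
#' less- and equally-processed classes, profiles the default motif set
#' between those classes (when sequences are available), and tests
#' host-transcript expression changes (when counts are available). All stage
#' tables and a JSON manifest are written under `out_dir` when given.
#'
#' @param input cohort bundle (list) or directory path for [load_cohort()].
#' @param out_dir optional output directory.
#' @param shoulder_len shoulder length in bases (default 100).
#' @param min_shoulder_depth expression filter threshold (default 30 reads).
#' @param class_threshold log2FC MPI classification half-width (default 0.5).
#' @param pseudocount depth pseudocount (default 1).
#' @param motifs motif set data.frame (default [default_motifs()]).
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return list: `regions`, `depths`, `mpi` (records + summary), `motifs`
#'   (profiles and group comparison per motif), `expression` (normalized
#'   matrix + test table), `manifest`.
#' @export
run_mpi_pipeline <- function(input, out_dir = NULL, shoulder_len = 100,
                             min_shoulder_depth = 30, class_threshold = 0.5,
                             pseudocount = 1, motifs = default_motifs(),
                             seed = NULL) {
  bundle <- if (is.character(input)) load_cohort(input) else input
  stopifnot(min_shoulder_depth > 0, class_threshold > 0, pseudocount > 0)

  regions <- build_regions(trim_hairpin(bundle$annotation), shoulder_len)
  depths <- region_depths(regions, bundle$reads, bundle$conditions)
  res <- mpi_analysis(depths, exclusion_list = bundle$exclusion_list,
                      pseudocount = pseudocount,
                      min_shoulder_depth = min_shoulder_depth,
                      class_threshold = class_threshold)

  motif_out <- NULL
  if (!is.null(bundle$sequences) && !is.null(bundle$anchors)) {
    rec <- res$records
    less <- rec$locus[rec$label == "less_processed"]
    equal <- rec$locus[rec$label == "equally_processed"]
    if (length(less) > 0 && length(equal) > 0) {
      sa <- anchored_sequences(bundle$sequences, bundle$anchors, less)
      sb <- anchored_sequences(bundle$sequences, bundle$anchors, equal)
      motif_out <- lapply(seq_len(nrow(motifs)), function(i) {
        m <- motifs[i, ]
        list(motif = m$motif, anchor = m$anchor,
             window = c(m$window_lo, m$window_hi),
             profile_less = group_profile(sa, m$motif, m$anchor,
                                          c(m$scan_lo, m$scan_hi)),
             profile_equal = group_profile(sb, m$motif, m$anchor,
                                           c(m$scan_lo, m$scan_hi)),
             comparison = compare_profiles(sa, sb, m$motif, m$anchor,
                                           c(m$window_lo, m$window_hi)))
      })
      names(motif_out) <- motifs$motif
    }
  }

  expr_out <- NULL
  if (!is.null(bundle$host_counts)) {
    normalized <- normalize_counts(bundle$host_counts, pseudocount)
    expr_out <- list(normalized = normalized,
                     test = groupwise_test(normalized, bundle$conditions))
  }

  manifest <- list(
    package = "mpiseq",
    version = as.character(utils::packageVersion("mpiseq")),
    seed = seed,
    thresholds = list(shoulder_len = shoulder_len,
                      min_shoulder_depth = min_shoulder_depth,
                      class_threshold = class_threshold,
                      pseudocount = pseudocount),
    n_loci = res$summary$n_total,
    n_filtered = res$summary$n_filtered,
    class_counts = as.list(res$summary$class_counts),
    mock_mpi_group_comparison = list(
      mean_less = res$summary$mock_mpi_less,
      mean_equal = res$summary$mock_mpi_equal,
      t = res$summary$t, p = res$summary$p),
    motif_enrichment = lapply(motif_out, function(m) {
      c(list(motif = m$motif, anchor = m$anchor,
             window = paste(m$window, collapse = "..")),
        m$comparison[c("freq_a", "freq_b", "odds_ratio", "p")])
    }))

  out <- list(regions = regions, depths = depths, mpi = res,
              motifs = motif_out, expression = expr_out, manifest = manifest)
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir)
  out
}

.write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_regions_bed(out$regions, file.path(out_dir, "regions.bed"))
  tsv(out$depths, "depths.tsv")
  tsv(out$mpi$records, "mpi.tsv")
  if (!is.null(out$motifs)) {
    prof <- do.call(rbind, lapply(out$motifs, function(m) {
      rbind(cbind(motif = m$motif, anchor = m$anchor, group = "less_processed",
                  m$profile_less),
            cbind(motif = m$motif, anchor = m$anchor,
                  group = "equally_processed", m$profile_equal))
    }))
    tsv(prof, "motif_profiles.tsv")
    cmp <- do.call(rbind, lapply(out$motifs, function(m) {
      data.frame(motif = m$motif, anchor = m$anchor,
                 window_lo = m$window[1], window_hi = m$window[2],
                 freq_less = m$comparison$freq_a,
                 freq_equal = m$comparison$freq_b,
                 odds_ratio = m$comparison$odds_ratio,
                 p = m$comparison$p, stringsAsFactors = FALSE)
    }))
    tsv(cmp, "motif_comparison.tsv")
  }
  if (!is.null(out$expression)) {
    tsv(data.frame(transcript = rownames(out$expression$normalized),
                   out$expression$normalized, check.names = FALSE),
        "expression_normalized.tsv")
    tsv(out$expression$test, "expression_test.tsv")
  }
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
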