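# Per-base depth over locus windows and the (N1, N, N2) maximum regional
# depth triple. Reads are ungapped intervals, 0-based half-open; spliced
# alignments must be pre-split into blocks upstream. Depth counts every
# overlapping read base (standard pileup semantics).

#' Per-base pileup of read intervals over a window
#'
#' @param reads data.frame with numeric `start`, `end` columns (0-based
#'   half-open), optionally `chrom` and `strand`.
#' @param window length-2 numeric `c(start, end)`, 0-based half-open.
#' @param chrom optional chromosome name recorded on the track (and used to
#'   subset `reads` when they carry a `chrom` column).
#' @param strand optional strand filter: only reads whose `strand` matches
#'   are counted (reads without strand information always count).
#' @return a coverage track: list with `chrom`, `start` (window start) and
#'   integer vector `depth`, one entry per base of the window.
#' @export
pileup <- function(reads, window, chrom = NA_character_, strand = NULL) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (!is.na(chrom) && !is.null(reads$chrom)) {
    reads <- reads[reads$chrom == chrom, , drop = FALSE]
  }
  if (!is.null(strand) && !is.null(reads$strand)) {
    reads <- reads[is.na(reads$strand) | reads$strand == strand, , drop = FALSE]
  }
  width <- as.integer(window[2] - window[1])
  if (nrow(reads) == 0) {
    return(list(chrom = chrom, start = window[1], depth = integer(width)))
  }
  stopifnot(all(reads$end > reads$start))
  ir <- IRanges::IRanges(start = as.integer(reads$start) + 1L,
                         end = as.integer(reads$end))
  ir <- IRanges::restrict(ir, start = as.integer(window[1]) + 1L,
                          end = as.integer(window[2]))
  cov <- IRanges::coverage(ir, width = as.integer(window[2]))
  depth <- as.integer(S4Vectors::window(cov, start = window[1] + 1L,
                                        end = window[2]))
  list(chrom = chrom, start = window[1], depth = depth)
}

.track_slice <- function(track, start, end) {
  i0 <- start - track$start
  i1 <- end - track$start
  if (i0 < 0 || i1 > length(track$depth)) {
    stop(sprintf("region [%d,%d) outside track window [%d,%d)",
                 start, end, track$start, track$start + length(track$depth)))
  }
  track$depth[seq.int(i0 + 1, i1)]
}

#' Maximum regional read depth triple (N1, N, N2)
#'
#' Extracts the maximum per-base depth over the transcript-5' shoulder (N1),
#' the precursor (N) and the transcript-3' shoulder (N2) of one locus. These
#' maxima are the regional depth measures the downstream MPI uses.
#'
#' @param track coverage track from [pileup()] or [read_bedgraph()]; must
#'   span all three regions.
#' @param region one row of a regions data.frame ([build_regions()]).
#' @return list with `n1`, `n`, `n2`.
#' @export
max_regional_depth <- function(track, region) {
  list(
    n1 = max(.track_slice(track, region$shoulder5_start, region$shoulder5_end)),
    n = max(.track_slice(track, region$precursor_start, region$precursor_end)),
    n2 = max(.track_slice(track, region$shoulder3_start, region$shoulder3_end)))
}

#' Read a bedGraph into a coverage track
#'
#' Gaps in the bedGraph are depth 0; overlapping intervals are rejected (the
#' format forbids them).
#'
#' @param path bedGraph file (chrom start end value, 0-based half-open).
#' @param window length-2 `c(start, end)` to materialize.
#' @param chrom chromosome to extract (defaults to the file's only one).
#' @return coverage track as from [pileup()].
#' @export
read_bedgraph <- function(path, window, chrom = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (is.null(chrom)) {
    chr <- unique(as.character(GenomicRanges::seqnames(gr)))
    if (length(chr) > 1) stop("multiple chromosomes in bedGraph; give `chrom`")
    chrom <- chr
  }
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  if (length(gr) > 1 &&
      !IRanges::isDisjoint(GenomicRanges::ranges(gr))) {
    stop("overlapping intervals in bedGraph: ", path)
  }
  width <- as.integer(window[2] - window[1])
  depth <- integer(width)
  st <- GenomicRanges::start(gr) - 1  # back to 0-based
  en <- GenomicRanges::end(gr)
  val <- gr$score
  for (i in seq_along(gr)) {
    a <- max(st[i], window[1]); b <- min(en[i], window[2])
    if (a < b) depth[(a - window[1] + 1):(b - window[1])] <- val[i]
  }
  list(chrom = chrom, start = window[1], depth = depth)
}

#' Write a coverage track as bedGraph
#'
#' Zero-depth runs are omitted (bedGraph gaps).
#'
#' @param track coverage track.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values > 0
  if (!any(keep)) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + starts[keep] + 1,
                              end = track$start + ends[keep]),
    score = r$values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read aligned-read intervals from a BED file
#'
#' @param path BED file of read intervals.
#' @return data.frame with `chrom`, `start`, `end`, `strand` (0-based
#'   half-open).
#' @export
read_bed_reads <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write read intervals as BED
#'
#' @param reads data.frame with `chrom`, `start`, `end` and optional `strand`.
#' @param path output path.
#' @export
write_bed_reads <- function(reads, path) {
  if (nrow(reads) == 0) {
    file.create(path)
    return(invisible(path))
  }
  strand <- if (is.null(reads$strand)) "*" else reads$strand
  gr <- GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$start + 1, end = reads$end),
    strand = strand,
    name = sprintf("read%d", seq_len(nrow(reads))), score = 0L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read aligned reads from a BAM file (optional adapter)
#'
#' Spliced alignments are split into their aligned blocks so every returned
#' interval is ungapped.
#'
#' @param path indexed BAM file.
#' @param region optional list/row with `chrom` and a window to restrict to.
#' @return data.frame as from [read_bed_reads()].
#' @export
read_bam_reads <- function(path, region = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE)) {
    stop("the BAM adapter requires Rsamtools and GenomicAlignments")
  }
  param <- Rsamtools::ScanBamParam()
  if (!is.null(region)) {
    w <- region_window(region)
    param <- Rsamtools::ScanBamParam(which = GenomicRanges::GRanges(
      region$chrom, IRanges::IRanges(w[1] + 1, w[2])))
  }
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  blocks <- unlist(GenomicAlignments::grglist(ga))
  data.frame(chrom = as.character(GenomicRanges::seqnames(blocks)),
             start = GenomicRanges::start(blocks) - 1,
             end = GenomicRanges::end(blocks),
             strand = as.character(GenomicRanges::strand(blocks)),
             stringsAsFactors = FALSE)
}

#' Depth triples for every locus in every sample
#'
#' Runs [pileup()] and [max_regional_depth()] over a table of regions and a
#' set of per-sample read evidence, producing the long-format depth table the
#' MPI stage consumes.
#'
#' @param regions regions data.frame from [build_regions()].
#' @param samples named list: one entry per sample, each either a read
#'   data.frame (`chrom`,`start`,`end`[,`strand`]) or a function
#'   `(region, window)` returning a coverage track (for bedGraph-backed
#'   samples).
#' @param conditions named character vector mapping sample name to
#'   `"mock"` / `"treated"`.
#' @param strand_specific count only reads matching the locus strand when
#'   strand information is present (default TRUE).
#' @return data.frame: `locus`, `sample`, `condition`, `n1`, `n`, `n2`.
#' @export
region_depths <- function(regions, samples, conditions,
                          strand_specific = TRUE) {
  stopifnot(all(names(samples) %in% names(conditions)))
  out <- vector("list", length(samples) * nrow(regions))
  k <- 0
  for (s in names(samples)) {
    ev <- samples[[s]]
    for (i in seq_len(nrow(regions))) {
      reg <- regions[i, ]
      w <- region_window(reg)
      track <- if (is.function(ev)) {
        ev(reg, w)
      } else {
        pileup(ev, w, chrom = reg$chrom,
               strand = if (strand_specific) reg$strand else NULL)
      }
      d <- max_regional_depth(track, reg)
      k <- k + 1
      out[[k]] <- data.frame(locus = reg$name, sample = s,
                             condition = unname(conditions[s]),
                             n1 = d$n1, n = d$n, n2 = d$n2,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
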