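# All genomic intervals in this package are 0-based, half-open ([start, end)),
# the BED convention. The annotation reader can convert from 1-based inclusive
# (miRBase convention) on ingest. "5p"/"3p" and "shoulder5"/"shoulder3" always
# refer to the transcript orientation: on the minus strand the 5p arm is the
# genomically rightmost mature interval and shoulder5 lies genomically
# downstream of the precursor.

HAIRPIN_COLUMNS <- c("name", "chrom", "hairpin_start", "hairpin_end", "strand",
                     "mature5p_start", "mature5p_end",
                     "mature3p_start", "mature3p_end")

#' Validate a table of hairpin records
#'
#' Checks each row of a hairpin annotation table against the structural
#' invariants: `hairpin_start < hairpin_end`; mature-arm sub-intervals, when
#' present, lie inside the hairpin and do not overlap each other; strand is
#' `+` or `-`; coordinates are non-negative. Duplicated names keep their
#' first occurrence (first-listed isoform wins).
#'
#' @param records data.frame with columns `name`, `chrom`, `hairpin_start`,
#'   `hairpin_end`, `strand`, and optional `mature5p_start`, `mature5p_end`,
#'   `mature3p_start`, `mature3p_end` (NA when an arm is unannotated).
#'   Coordinates 0-based half-open.
#' @return The valid rows, with a `"rejected"` attribute: a data.frame of
#'   row numbers and reasons for every row that failed validation.
#' @export
validate_hairpins <- function(records) {
  required <- c("name", "chrom", "hairpin_start", "hairpin_end", "strand")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("annotation is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in setdiff(HAIRPIN_COLUMNS, names(records))) records[[col]] <- NA_real_

  reason <- rep(NA_character_, nrow(records))
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- why
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  hs <- num(records$hairpin_start); he <- num(records$hairpin_end)
  m5s <- num(records$mature5p_start); m5e <- num(records$mature5p_end)
  m3s <- num(records$mature3p_start); m3e <- num(records$mature3p_end)

  flag(is.na(records$name) | records$name == "", "missing name")
  flag(!(records$strand %in% c("+", "-")), "strand must be + or -")
  flag(is.na(hs) | is.na(he), "non-numeric hairpin interval")
  flag(!is.na(hs) & hs < 0, "negative coordinate")
  flag(!is.na(hs) & !is.na(he) & hs >= he, "hairpin_start must be < hairpin_end")
  flag(xor(is.na(m5s), is.na(m5e)) | xor(is.na(m3s), is.na(m3e)),
       "half-specified mature arm")
  in5 <- !is.na(m5s)
  flag(in5 & (m5s >= m5e | m5s < hs | m5e > he), "5p arm outside hairpin")
  in3 <- !is.na(m3s)
  flag(in3 & (m3s >= m3e | m3s < hs | m3e > he), "3p arm outside hairpin")
  flag(in5 & in3 & is.na(reason) & pmax(m5s, m3s) < pmin(m5e, m3e),
       "mature arms overlap")
  # transcript order: the 5p arm precedes the 3p arm in transcript direction
  plus <- records$strand == "+"
  flag(in5 & in3 & is.na(reason) & plus & m5e > m3s,
       "5p arm not transcript-upstream of 3p arm")
  flag(in5 & in3 & is.na(reason) & !plus & m3e > m5s,
       "5p arm not transcript-upstream of 3p arm")
  flag(is.na(reason) & duplicated(records$name), "duplicate name (first kept)")

  ok <- is.na(reason)
  out <- records[ok, HAIRPIN_COLUMNS, drop = FALSE]
  out$hairpin_start <- hs[ok]; out$hairpin_end <- he[ok]
  out$mature5p_start <- m5s[ok]; out$mature5p_end <- m5e[ok]
  out$mature3p_start <- m3s[ok]; out$mature3p_end <- m3e[ok]
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(
    row = which(!ok), name = records$name[!ok], reason = reason[!ok],
    stringsAsFactors = FALSE)
  out
}

#' Read a miRBase-like hairpin annotation table
#'
#' Parses a TSV with one row per hairpin: genomic interval, strand, and
#' optional 5p/3p mature-arm sub-intervals. Malformed rows are dropped and
#' reported (with their line numbers) in the `"rejected"` attribute.
#'
#' @param path TSV file with a header naming the columns of
#'   [validate_hairpins()].
#' @param one_based if `TRUE`, input coordinates are 1-based inclusive
#'   (miRBase convention) and are converted to 0-based half-open on ingest.
#' @return data.frame of valid hairpin records (0-based half-open).
#' @export
read_mirna_annotation <- function(path, one_based = FALSE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#", na.strings = c("NA", "", "."))
  if (one_based) {
    for (col in c("hairpin_start", "mature5p_start", "mature3p_start")) {
      if (col %in% names(tab)) tab[[col]] <- tab[[col]] - 1
    }
  }
  out <- validate_hairpins(tab)
  rej <- attr(out, "rejected")
  if (nrow(rej) > 0) {
    rej$line <- rej$row + 1L  # header occupies line 1
    attr(out, "rejected") <- rej
    warning(sprintf("%d annotation row(s) rejected; see attr(,'rejected')",
                    nrow(rej)))
  }
  out
}

#' Write a hairpin annotation table
#'
#' Inverse of [read_mirna_annotation()] (with `one_based = FALSE`).
#'
#' @param records hairpin data.frame.
#' @param path output TSV path.
#' @export
write_mirna_annotation <- function(records, path) {
  utils::write.table(records[, HAIRPIN_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trim hairpins to the mature-arm boundaries
#'
#' Removes, where possible, all sequence transcript-upstream of the 5' end of
#' the 5p mature arm and all sequence transcript-downstream of the 3' end of
#' the 3p mature arm, yielding the precursor interval whose ends are the
#' Drosha cleavage sites. When an arm is unannotated the corresponding
#' hairpin end is kept untrimmed.
#'
#' @param records validated hairpin data.frame.
#' @return the same data.frame with `precursor_start` / `precursor_end`
#'   columns added (0-based half-open, genomic).
#' @export
trim_hairpin <- function(records) {
  n <- nrow(records)
  ps <- records$hairpin_start
  pe <- records$hairpin_end
  plus <- records$strand == "+"
  has5 <- !is.na(records$mature5p_start)
  has3 <- !is.na(records$mature3p_start)
  # transcript-5' boundary comes from the 5p arm, transcript-3' from the 3p arm
  ps[plus & has5] <- records$mature5p_start[plus & has5]
  pe[plus & has3] <- records$mature3p_end[plus & has3]
  pe[!plus & has5] <- records$mature5p_end[!plus & has5]
  ps[!plus & has3] <- records$mature3p_start[!plus & has3]
  records$precursor_start <- ps
  records$precursor_end <- pe
  records
}

#' Attach fixed-length shoulder regions to trimmed precursors
#'
#' Builds, for each locus, the precursor interval plus two abutting shoulder
#' intervals of exactly `shoulder_len` bases in transcript orientation
#' (shoulder5 at the transcript-5' end; on the minus strand this is
#' genomically downstream). Loci whose shoulders would run past coordinate 0
#' are rejected, not truncated.
#'
#' @param records output of [trim_hairpin()].
#' @param shoulder_len shoulder length in bases (default 100, fixed in the
#'   analysis this package implements).
#' @return data.frame with one row per accepted locus: `name`, `chrom`,
#'   `strand`, `precursor_start/end`, `shoulder5_start/end`,
#'   `shoulder3_start/end`; rejected loci reported in attr `"rejected"`.
#' @export
build_regions <- function(records, shoulder_len = 100) {
  stopifnot(shoulder_len > 0)
  if (is.null(records$precursor_start)) records <- trim_hairpin(records)
  plus <- records$strand == "+"
  left_start <- records$precursor_start - shoulder_len
  left_end <- records$precursor_start
  right_start <- records$precursor_end
  right_end <- records$precursor_end + shoulder_len
  out <- data.frame(
    name = records$name, chrom = records$chrom, strand = records$strand,
    precursor_start = records$precursor_start,
    precursor_end = records$precursor_end,
    shoulder5_start = ifelse(plus, left_start, right_start),
    shoulder5_end = ifelse(plus, left_end, right_end),
    shoulder3_start = ifelse(plus, right_start, left_start),
    shoulder3_end = ifelse(plus, right_end, left_end),
    stringsAsFactors = FALSE)
  bad <- left_start < 0
  attr(out, "rejected") <- data.frame(
    name = records$name[bad],
    reason = rep("shoulder extends past contig start", sum(bad)),
    stringsAsFactors = FALSE)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.regions_to_granges <- function(regions) {
  roles <- c("shoulder5", "precursor", "shoulder3")
  starts <- cbind(regions$shoulder5_start, regions$precursor_start,
                  regions$shoulder3_start)
  ends <- cbind(regions$shoulder5_end, regions$precursor_end,
                regions$shoulder3_end)
  n <- nrow(regions)
  GenomicRanges::GRanges(
    seqnames = rep(regions$chrom, each = 3),
    ranges = IRanges::IRanges(start = as.vector(t(starts)) + 1,
                              end = as.vector(t(ends))),
    strand = rep(regions$strand, each = 3),
    name = paste(rep(regions$name, each = 3), rep(roles, n), sep = "."),
    score = 0L)
}

#' Write region sets as BED6
#'
#' Each locus contributes three lines named `<name>.shoulder5`,
#' `<name>.precursor`, `<name>.shoulder3` (0-based half-open on disk).
#'
#' @param regions output of [build_regions()].
#' @param path output BED path.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- .regions_to_granges(regions)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a region-set BED6 back into a regions table
#'
#' Inverse of [write_regions_bed()]; expects the three-role naming scheme.
#'
#' @param path BED file written by [write_regions_bed()].
#' @return regions data.frame as from [build_regions()].
#' @export
read_regions_bed <- function(path) {
  empty <- data.frame(name = character(), chrom = character(),
                      strand = character(),
                      precursor_start = numeric(), precursor_end = numeric(),
                      shoulder5_start = numeric(), shoulder5_end = numeric(),
                      shoulder3_start = numeric(), shoulder3_end = numeric(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  role <- sub(".*\\.", "", nm)
  locus <- sub("\\.[^.]*$", "", nm)
  if (!all(role %in% c("shoulder5", "precursor", "shoulder3"))) {
    stop("BED names lack the .shoulder5/.precursor/.shoulder3 role suffix")
  }
  df <- data.frame(locus = locus, role = role,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  pick <- function(r) df[df$role == r, ][match(unique(df$locus),
                                               df$locus[df$role == r]), ]
  pre <- pick("precursor"); s5 <- pick("shoulder5"); s3 <- pick("shoulder3")
  data.frame(name = unique(df$locus), chrom = pre$chrom, strand = pre$strand,
             precursor_start = pre$start, precursor_end = pre$end,
             shoulder5_start = s5$start, shoulder5_end = s5$end,
             shoulder3_start = s3$start, shoulder3_end = s3$end,
             stringsAsFactors = FALSE)
}

#' Full analysis window of a locus
#'
#' The union of shoulder5, precursor and shoulder3 as a single genomic
#' interval `c(start, end)` (0-based half-open).
#'
#' @param region one row of a regions data.frame.
#' @export
region_window <- function(region) {
  c(min(region$shoulder5_start, region$shoulder3_start),
    max(region$shoulder5_end, region$shoulder3_end))
}
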