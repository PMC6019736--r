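# Positional scanning of the sequence determinants of optimal Microprocessor
# substrates -- the basal UG (around -14/-13 of the 5' Drosha cleavage site),
# the apical UGU at the 5p/terminal-loop boundary, and the CNNC downstream
# element (+16/+18 of the 3' cleavage site).
#
# Offset convention: the offset of a motif is the position of its FIRST base
# relative to the anchor, with the anchor base itself at 0 and the base
# immediately 5' of it at -1. Anchors are 0-based indices into the sequence:
# `cut5` = first precursor base, `cut3` = first base after the precursor,
# `loop5p` = first base after the 5p mature arm.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.norm_seq <- function(x) chartr("uU", "tT", x)

#' Match an IUPAC pattern at given positions of a sequence
#'
#' U and T are equivalent in both pattern and sequence; `N` matches any
#' base. Positions where the pattern would run outside the sequence return
#' `FALSE`, not an error.
#'
#' @param pattern IUPAC nucleotide pattern (e.g. `"CNNC"`).
#' @param sequence nucleotide string, RNA or DNA alphabet.
#' @param positions 0-based start position(s) to test; vectorized.
#' @return logical vector, one entry per position.
#' @export
match_iupac <- function(pattern, sequence, positions) {
  pat <- strsplit(toupper(.norm_seq(pattern)), "")[[1]]
  if (!all(pat %in% names(IUPAC_SETS))) {
    stop("pattern contains non-IUPAC characters: ", pattern)
  }
  seqc <- strsplit(toupper(.norm_seq(sequence)), "")[[1]]
  k <- length(pat)
  n <- length(seqc)
  vapply(positions, function(p) {
    if (is.na(p) || p < 0 || p + k > n) return(FALSE)
    all(vapply(seq_len(k), function(i) {
      seqc[p + i] %in% IUPAC_SETS[[pat[i]]]
    }, logical(1)))
  }, logical(1))
}

.anchor_index <- function(seq, anchor = c("cut5", "cut3", "loop5p")) {
  anchor <- match.arg(anchor)
  idx <- switch(anchor, cut5 = seq$cut5, cut3 = seq$cut3,
                loop5p = seq$loop5p)
  if (is.null(idx) || is.na(idx)) stop("anchored sequence lacks anchor ", anchor)
  idx
}

#' Validate an anchored sequence
#'
#' An anchored sequence is a list with `locus`, `sequence` (transcript
#' orientation), and 0-based anchor indices `cut5` (first precursor base),
#' `cut3` (one past the last precursor base) and optionally `loop5p` (one
#' past the 3' end of the 5p mature arm).
#'
#' @param seq list as described.
#' @return the list, invisibly, after checking
#'   `0 <= cut5 < loop5p <= cut3 <= nchar(sequence)`.
#' @export
anchored_sequence <- function(seq) {
  stopifnot(is.character(seq$sequence), length(seq$sequence) == 1)
  n <- nchar(seq$sequence)
  stopifnot(seq$cut5 >= 0, seq$cut5 < seq$cut3, seq$cut3 <= n)
  if (!is.null(seq$loop5p) && !is.na(seq$loop5p)) {
    stopifnot(seq$cut5 < seq$loop5p, seq$loop5p <= seq$cut3)
  }
  invisible(seq)
}

#' Scan a motif around an anchor of one sequence
#'
#' @param seq anchored sequence (see [anchored_sequence()]).
#' @param motif IUPAC pattern.
#' @param anchor `"cut5"`, `"cut3"` or `"loop5p"`.
#' @param offset_range integer `c(lo, hi)`: offsets scanned are
#'   `lo, lo+1, ..., hi` (match-start positions relative to the anchor;
#'   negative = transcript-5' of the anchor). Offsets whose window falls
#'   outside the sequence are silently skipped.
#' @return integer vector of offsets at which the motif matches.
#' @export
scan_anchor <- function(seq, motif, anchor, offset_range) {
  a <- .anchor_index(seq, anchor)
  offs <- seq.int(offset_range[1], offset_range[2])
  hit <- match_iupac(motif, seq$sequence, a + offs)
  offs[hit]
}

#' Sliding-window smoothing of a positional frequency profile
#'
#' Centered moving average; edge positions are averaged over the neighbors
#' actually available, so a constant profile is left unchanged.
#'
#' @param freq numeric vector.
#' @param window odd window size (default 3).
#' @export
smooth_profile <- function(freq, window = 3) {
  stopifnot(window >= 1, window %% 2 == 1)
  h <- (window - 1) / 2
  n <- length(freq)
  vapply(seq_len(n), function(i) {
    mean(freq[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Per-position motif frequency profile of a locus group
#'
#' For every offset in `offset_range`, the fraction of loci whose sequence
#' carries a motif match starting at that offset from the anchor, smoothed
#' with a centered sliding window (width 3 by default).
#'
#' @param seqs list of anchored sequences (>= 1).
#' @inheritParams scan_anchor
#' @param window smoothing window (odd; default 3).
#' @return data.frame: `offset`, `freq`, `freq_smoothed`, with attributes
#'   `motif`, `anchor` and `n_loci`.
#' @export
group_profile <- function(seqs, motif, anchor, offset_range, window = 3) {
  if (length(seqs) == 0) stop("empty locus group")
  offs <- seq.int(offset_range[1], offset_range[2])
  counts <- integer(length(offs))
  for (s in seqs) {
    hit <- scan_anchor(s, motif, anchor, offset_range)
    counts[offs %in% hit] <- counts[offs %in% hit] + 1L
  }
  freq <- counts / length(seqs)
  out <- data.frame(offset = offs, freq = freq,
                    freq_smoothed = smooth_profile(freq, window))
  attr(out, "motif") <- motif
  attr(out, "anchor") <- anchor
  attr(out, "n_loci") <- length(seqs)
  out
}

#' Motif enrichment between two locus groups within an offset window
#'
#' A locus counts as a match if the motif occurs at any offset inside
#' `offset_window`. The two groups form a 2x2 match/no-match contingency
#' table; the odds ratio is the sample (cross-product) odds ratio and the
#' p-value is from the two-sided Fisher exact test.
#'
#' @param seqs_a,seqs_b anchored-sequence lists for the two groups.
#' @inheritParams scan_anchor
#' @param offset_window integer `c(lo, hi)` window of admissible match-start
#'   offsets (e.g. `c(-14, -13)` for the basal UG).
#' @return list: `freq_a`, `freq_b`, `match_a`, `match_b`, `n_a`, `n_b`,
#'   `odds_ratio`, `p`.
#' @export
compare_profiles <- function(seqs_a, seqs_b, motif, anchor, offset_window) {
  if (length(seqs_a) == 0 || length(seqs_b) == 0) stop("empty locus group")
  hits <- function(seqs) {
    sum(vapply(seqs, function(s) {
      length(scan_anchor(s, motif, anchor, offset_window)) > 0
    }, logical(1)))
  }
  ka <- hits(seqs_a); kb <- hits(seqs_b)
  na <- length(seqs_a); nb <- length(seqs_b)
  tab <- matrix(c(ka, na - ka, kb, nb - kb), nrow = 2)
  or <- (ka * (nb - kb)) / ((na - ka) * kb)
  p <- stats::fisher.test(tab)$p.value
  list(freq_a = ka / na, freq_b = kb / nb, match_a = ka, match_b = kb,
       n_a = na, n_b = nb, odds_ratio = or, p = p)
}

#' Default motif set of Microprocessor substrate determinants
#'
#' UG at the basal 5' cleavage site, CNNC downstream of the 3' cleavage
#' site, UGU at the 5p/terminal-loop boundary; GNNU (reported elsewhere as a
#' basal element) ships as optional and is off by default.
#'
#' @param include_optional include the optional GNNU entry.
#' @return data.frame: `motif`, `anchor`, `window_lo`, `window_hi`,
#'   `scan_lo`, `scan_hi` (enrichment window and the wider profile scan
#'   range, as match-start offsets).
#' @export
default_motifs <- function(include_optional = FALSE) {
  m <- data.frame(
    motif = c("TG", "CNNC", "TGT"),
    anchor = c("cut5", "cut3", "loop5p"),
    window_lo = c(-14L, 16L, -2L),
    window_hi = c(-13L, 18L, 2L),
    scan_lo = c(-30L, 0L, -10L),
    scan_hi = c(-1L, 30L, 10L),
    stringsAsFactors = FALSE)
  if (include_optional) {
    m <- rbind(m, data.frame(motif = "GNNT", anchor = "cut5",
                             window_lo = -14L, window_hi = -11L,
                             scan_lo = -30L, scan_hi = -1L))
  }
  m
}
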