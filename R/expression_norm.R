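# Host-transcript count normalization and differential testing: counts are
# scaled to the lowest sample total, log2-transformed, quantile-normalized,
# then tested per transcript between conditions with BH adjustment across
# transcripts. This is the control analysis asking whether apparent
# processing changes could instead be transcription changes of the host.

.check_counts <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("count matrix has negative entries")
  m
}

#' Scale every sample to the lowest library total
#'
#' Each column is multiplied by (min column total / its column total), so
#' all column totals equal the smallest one afterwards.
#'
#' @param m transcripts x samples matrix of non-negative counts.
#' @return rescaled real-valued matrix.
#' @export
scale_to_lowest_total <- function(m) {
  m <- .check_counts(m)
  totals <- colSums(m)
  if (any(totals == 0)) stop("sample(s) with zero total count: ",
                             paste(colnames(m)[totals == 0], collapse = ", "))
  sweep(m, 2, min(totals) / totals, `*`)
}

#' Elementwise log2 with pseudocount
#'
#' @param m non-negative matrix.
#' @param pseudocount added before the log (default 1, so a 0 maps to 0).
#' @export
log2_transform <- function(m, pseudocount = 1) {
  m <- .check_counts(m)
  log2(m + pseudocount)
}

#' Quantile-normalize a matrix of expression values
#'
#' Classic quantile normalization: within each column the rank-r value is
#' replaced by the mean of the r-th order statistics across columns; tied
#' values receive the mean of the reference distribution over their rank
#' range, so the operation is exactly idempotent and every column has the
#' same sorted values afterwards.
#'
#' @param m matrix with >= 2 columns.
#' @return matrix with identical sorted columns.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("quantile normalization needs >= 2 samples")
  reference <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")  # fractional at tie midpoints
    (reference[floor(r)] + reference[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Full normalization chain
#'
#' Scale to lowest total, log2-transform, quantile-normalize.
#'
#' @inheritParams scale_to_lowest_total
#' @inheritParams log2_transform
#' @export
normalize_counts <- function(m, pseudocount = 1) {
  quantile_normalize(log2_transform(scale_to_lowest_total(m), pseudocount))
}

#' Per-transcript differential test between conditions
#'
#' Ordinary two-sample t-test (Welch by default) on normalized log2 values,
#' treated relative to mock, with Benjamini-Hochberg adjustment across
#' transcripts. Transcripts with zero variance in both groups and equal
#' means get t = 0, p = 1.
#'
#' @param m_normalized transcripts x samples matrix of normalized log2
#'   values (e.g. from [normalize_counts()]).
#' @param conditions character vector (length = ncol) of `"mock"` /
#'   `"treated"`, or a named vector matched against column names.
#' @param method `"welch"` (default) or `"student"` (pooled variance).
#' @return data.frame: `transcript`, `log2fc` (treated - mock mean), `t`,
#'   `p`, `padj`.
#' @export
groupwise_test <- function(m_normalized, conditions,
                           method = c("welch", "student")) {
  method <- match.arg(method)
  m <- as.matrix(m_normalized)
  if (!is.null(names(conditions)) && !is.null(colnames(m))) {
    conditions <- conditions[colnames(m)]
  }
  stopifnot(length(conditions) == ncol(m),
            all(conditions %in% c("mock", "treated")))
  a <- m[, conditions == "treated", drop = FALSE]
  b <- m[, conditions == "mock", drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2 || nb < 2) stop("need >= 2 samples per condition")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  if (method == "welch") {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, nrow(m))
  }
  t <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  t[degen & ma == mb] <- 0
  p[degen & ma == mb] <- 1
  p[degen & ma != mb] <- 0
  t[degen & ma != mb] <- sign(ma - mb)[degen & ma != mb] * Inf
  data.frame(
    transcript = if (is.null(rownames(m))) as.character(seq_len(nrow(m)))
                 else rownames(m),
    log2fc = ma - mb, t = t, p = p,
    padj = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL)
}
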