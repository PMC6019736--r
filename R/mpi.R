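# The Microprocessor processing index. For a locus with maximum regional
# read depths N1 (5' shoulder), N (precursor) and N2 (3' shoulder),
#
#   MPI = log2( (N + c) / ((N1 + c + N2 + c) / 2) ),    c = pseudocount
#
# so that Drosha excision of the hairpin (precursor depleted relative to its
# flanks) gives a negative MPI and absence of processing gives MPI near 0.
# The differential index is log2FC MPI = MPI(treated) - MPI(mock); positive
# values mean loss of processing under treatment.

#' Microprocessor processing index of a depth triple
#'
#' @param n1,n,n2 non-negative maximum regional depths: transcript-5'
#'   shoulder, precursor, transcript-3' shoulder. Vectorized.
#' @param pseudocount added to every depth before the ratio so the index is
#'   finite at zero precursor depth (default 1).
#' @param flank_combiner how the two shoulder depths are combined:
#'   `"mean"` (default), `"min"` or `"max"`.
#' @return MPI in log2 units; negative when the precursor is depleted
#'   relative to the combined shoulders.
#' @export
mpi <- function(n1, n, n2, pseudocount = 1,
                flank_combiner = c("mean", "min", "max")) {
  flank_combiner <- match.arg(flank_combiner)
  stopifnot(pseudocount > 0, all(n1 >= 0), all(n >= 0), all(n2 >= 0))
  flank <- switch(flank_combiner,
                  mean = ((n1 + pseudocount) + (n2 + pseudocount)) / 2,
                  min = pmin(n1, n2) + pseudocount,
                  max = pmax(n1, n2) + pseudocount)
  log2((n + pseudocount) / flank)
}

#' Combine per-replicate MPI values for one locus and condition
#'
#' Arithmetic mean of the per-replicate indices.
#'
#' @param values numeric vector of per-sample MPIs, length >= 1.
#' @export
aggregate_condition <- function(values) {
  if (length(values) == 0) stop("no replicate MPI values to aggregate")
  mean(values)
}

#' Differential processing index between conditions
#'
#' @param mpi_mock,mpi_treated per-condition MPIs (log2 units).
#' @return `mpi_treated - mpi_mock`; positive = less processed under
#'   treatment.
#' @export
log2fc_mpi <- function(mpi_mock, mpi_treated) {
  stopifnot(all(is.finite(mpi_mock)), all(is.finite(mpi_treated)))
  mpi_treated - mpi_mock
}

#' Per-locus MPI table from a depth-triple table
#'
#' Computes a per-replicate MPI for every (locus, sample), averages
#' replicates within each condition, and takes the treated-minus-mock
#' difference. Replicates are aggregated at the MPI level, not the depth
#' level (`replicate_mode = "pooled_depth"` instead averages the depth
#' triples across replicates before one MPI per condition).
#'
#' @param depths data.frame from [region_depths()]: `locus`, `sample`,
#'   `condition` (mock/treated), `n1`, `n`, `n2`.
#' @param pseudocount,flank_combiner passed to [mpi()].
#' @param replicate_mode `"mpi_mean"` (default) or `"pooled_depth"`.
#' @return data.frame: `locus`, `mpi_mock`, `mpi_treated`, `log2fc_mpi`.
#' @export
mpi_table <- function(depths, pseudocount = 1, flank_combiner = "mean",
                      replicate_mode = c("mpi_mean", "pooled_depth")) {
  replicate_mode <- match.arg(replicate_mode)
  stopifnot(all(c("locus", "condition", "n1", "n", "n2") %in% names(depths)))
  stopifnot(all(depths$condition %in% c("mock", "treated")))
  if (replicate_mode == "mpi_mean") {
    depths$value <- mpi(depths$n1, depths$n, depths$n2, pseudocount,
                        flank_combiner)
    agg <- stats::aggregate(value ~ locus + condition, depths, mean)
  } else {
    pooled <- stats::aggregate(cbind(n1, n, n2) ~ locus + condition, depths,
                               mean)
    pooled$value <- mpi(pooled$n1, pooled$n, pooled$n2, pseudocount,
                        flank_combiner)
    agg <- pooled[, c("locus", "condition", "value")]
  }
  wide <- stats::reshape(agg, idvar = "locus", timevar = "condition",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "mpi_", names(wide))
  if (is.null(wide$mpi_mock) || is.null(wide$mpi_treated)) {
    stop("depth table must contain both mock and treated samples")
  }
  wide$log2fc_mpi <- log2fc_mpi(wide$mpi_mock, wide$mpi_treated)
  rownames(wide) <- NULL
  wide[order(wide$locus), c("locus", "mpi_mock", "mpi_treated", "log2fc_mpi")]
}

#' Apply the three pri-miRNA selection filters
#'
#' A locus is kept only if (1) it is sufficiently expressed: in the mock
#' condition the shoulder maximum depth reaches `min_shoulder_depth` on each
#' side of the hairpin; (2) it is not on the exclusion list (annotated
#' mirtrons and miRNAs that do not bind DGCR8); (3) it is actually cleaved by
#' the Microprocessor in mock conditions (`mpi_mock < 0`, strict).
#'
#' @param mpi_tbl output of [mpi_table()].
#' @param depths the depth-triple table the MPIs came from.
#' @param exclusion_list character vector of locus names to exclude.
#' @param min_shoulder_depth expression threshold on each shoulder
#'   (default 30 reads).
#' @param expression_mode `"replicate_mean"` (default: the mean across mock
#'   replicates of each shoulder maximum must reach the threshold) or
#'   `"per_replicate"` (every mock replicate must reach it on both sides).
#' @return `mpi_tbl` with logical columns `filter_expression`,
#'   `filter_exclusionlist`, `filter_processed_in_mock` (TRUE = passes) and
#'   `keep` (all three pass).
#' @export
apply_filters <- function(mpi_tbl, depths, exclusion_list = character(),
                          min_shoulder_depth = 30,
                          expression_mode = c("replicate_mean",
                                              "per_replicate")) {
  expression_mode <- match.arg(expression_mode)
  mock <- depths[depths$condition == "mock", , drop = FALSE]
  if (expression_mode == "replicate_mean") {
    sh <- stats::aggregate(cbind(n1, n2) ~ locus, mock, mean)
    pass_expr <- sh$n1 >= min_shoulder_depth & sh$n2 >= min_shoulder_depth
  } else {
    sh <- stats::aggregate(cbind(n1, n2) ~ locus, mock, min)
    pass_expr <- sh$n1 >= min_shoulder_depth & sh$n2 >= min_shoulder_depth
  }
  mpi_tbl$filter_expression <- pass_expr[match(mpi_tbl$locus, sh$locus)]
  mpi_tbl$filter_expression[is.na(mpi_tbl$filter_expression)] <- FALSE
  mpi_tbl$filter_exclusionlist <- !(mpi_tbl$locus %in% exclusion_list)
  mpi_tbl$filter_processed_in_mock <- mpi_tbl$mpi_mock < 0
  mpi_tbl$keep <- mpi_tbl$filter_expression & mpi_tbl$filter_exclusionlist &
    mpi_tbl$filter_processed_in_mock
  mpi_tbl
}

#' Classify loci by differential processing
#'
#' `log2fc_mpi >= threshold` is `less_processed` (processing lost under
#' treatment), `<= -threshold` is `more_processed`, the open band in between
#' is `equally_processed`; both extreme thresholds are inclusive.
#'
#' @param log2fc numeric vector of log2FC MPI values.
#' @param threshold classification half-width (default 0.5 log2 units).
#' @return factor with levels `less_processed`, `equally_processed`,
#'   `more_processed`.
#' @export
classify_mpi <- function(log2fc, threshold = 0.5) {
  stopifnot(threshold > 0)
  lab <- ifelse(log2fc >= threshold, "less_processed",
                ifelse(log2fc <= -threshold, "more_processed",
                       "equally_processed"))
  factor(lab, levels = c("less_processed", "equally_processed",
                         "more_processed"))
}

#' Full MPI analysis of a depth table
#'
#' MPI per condition, log2FC, filters, class labels (filtered-out loci are
#' labelled `excluded`), plus a summary with class counts and the mock-MPI
#' group comparison between the less- and equally-processed classes.
#'
#' @inheritParams mpi_table
#' @inheritParams apply_filters
#' @param class_threshold classification half-width (default 0.5).
#' @return list with `records` (per-locus data.frame incl. `label`) and
#'   `summary` (class counts, group means, t, p).
#' @export
mpi_analysis <- function(depths, exclusion_list = character(),
                         pseudocount = 1, min_shoulder_depth = 30,
                         class_threshold = 0.5, flank_combiner = "mean",
                         replicate_mode = "mpi_mean",
                         expression_mode = "replicate_mean") {
  tbl <- mpi_table(depths, pseudocount, flank_combiner, replicate_mode)
  tbl <- apply_filters(tbl, depths, exclusion_list, min_shoulder_depth,
                       expression_mode)
  lab <- as.character(classify_mpi(tbl$log2fc_mpi, class_threshold))
  lab[!tbl$keep] <- "excluded"
  tbl$label <- factor(lab, levels = c("less_processed", "equally_processed",
                                      "more_processed", "excluded"))
  counts <- table(tbl$label)
  less <- tbl$mpi_mock[tbl$label == "less_processed"]
  equal <- tbl$mpi_mock[tbl$label == "equally_processed"]
  grp <- if (length(less) >= 2 && length(equal) >= 2) {
    compare_group_mpi(less, equal)
  } else {
    list(mean_a = mean(less), mean_b = mean(equal), t = NA_real_,
         p = NA_real_)
  }
  list(records = tbl,
       summary = list(
         n_total = nrow(tbl),
         n_filtered = sum(tbl$keep),
         class_counts = counts,
         mock_mpi_less = grp$mean_a, mock_mpi_equal = grp$mean_b,
         t = grp$t, p = grp$p))
}

#' Compare mock MPI distributions between two locus classes
#'
#' Two-sided pooled-variance Student's t-test, as used to ask whether
#' treatment-affected pri-miRNAs were already more processed at baseline.
#' Zero pooled variance with unequal means returns p = 0 with a warning
#' (the groups are perfectly separated); with equal means, t = 0 and p = 1.
#'
#' @param group_a,group_b numeric vectors of mock MPIs, each length >= 2.
#' @return list: `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @export
compare_group_mpi <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  ma <- mean(group_a); mb <- mean(group_b)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  df <- na + nb - 2
  if (sp2 == 0) {
    if (ma == mb) {
      return(list(mean_a = ma, mean_b = mb, t = 0, df = df, p = 1))
    }
    warning("zero pooled variance with unequal means; returning p = 0")
    return(list(mean_a = ma, mean_b = mb, t = sign(ma - mb) * Inf, df = df,
                p = 0))
  }
  t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(t), df)
  list(mean_a = ma, mean_b = mb, t = t, df = df, p = p)
}
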