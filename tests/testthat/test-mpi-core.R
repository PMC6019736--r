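test_that("MPI follows its defining ratio and sign convention", {
  expect_equal(mpi(40, 40, 40), 0)
  expect_equal(mpi(39, 19, 39), -1)
  # hairpin-depleted coverage gives negative values
  expect_lt(mpi(100, 20, 100), 0)
  expect_error(mpi(1, -1, 1))
})

test_that("MPI equals an independent arithmetic recomputation on random triples", {
  set.seed(61)
  for (i in 1:500) {
    tr <- sample(0:500, 3, replace = TRUE)
    got <- mpi(tr[1], tr[2], tr[3])
    # independent route: natural logs and explicit flank average
    flank <- ((tr[1] + 1) + (tr[3] + 1)) / 2
    want <- (log(tr[2] + 1) - log(flank)) / log(2)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("flank combiner and pseudocount options behave as documented", {
  expect_equal(mpi(10, 20, 40, flank_combiner = "min"), log2(21 / 11))
  expect_equal(mpi(10, 20, 40, flank_combiner = "max"), log2(21 / 41))
  expect_equal(mpi(0, 0, 0, pseudocount = 0.5), 0)
  expect_true(is.finite(mpi(1000, 0, 1000)))
})

test_that("condition aggregation is the replicate mean", {
  expect_equal(aggregate_condition(-1), -1)
  expect_equal(aggregate_condition(c(-1, -2)), -1.5)
  set.seed(67)
  x <- rnorm(9)
  expect_equal(aggregate_condition(x), sum(x) / length(x))
  expect_error(aggregate_condition(numeric(0)), "no replicate")
})

test_that("log2FC MPI is the treated-minus-mock difference and antisymmetric", {
  expect_equal(log2fc_mpi(-2, -1), 1)
  expect_equal(log2fc_mpi(-1.3, -1.3), 0)
  set.seed(71)
  for (i in 1:100) {
    a <- rnorm(1); b <- rnorm(1)
    expect_equal(log2fc_mpi(a, b), -log2fc_mpi(b, a))
  }
})

test_that("mpi_table averages replicates within condition before the difference", {
  depths <- rbind(
    data.frame(locus = "x", sample = c("m1", "m2"), condition = "mock",
               n1 = 39, n = c(19, 9), n2 = 39),
    data.frame(locus = "x", sample = c("t1", "t2"), condition = "treated",
               n1 = 39, n = 39, n2 = 39))
  tbl <- mpi_table(depths)
  expect_equal(tbl$mpi_mock, mean(c(-1, -2)))
  expect_equal(tbl$mpi_treated, 0)
  expect_equal(tbl$log2fc_mpi, 1.5)

  pooled <- mpi_table(depths, replicate_mode = "pooled_depth")
  expect_equal(pooled$mpi_mock, log2(15 / 40))
  expect_error(mpi_table(depths[depths$condition == "mock", , drop = FALSE]),
               "mock and treated")
})

test_that("the three selection filters use their documented boundaries", {
  # 10-locus toy: each filter exercised at its boundary
  mk <- function(locus, n1, n, n2, cond, smp) {
    data.frame(locus = locus, sample = smp, condition = cond,
               n1 = n1, n = n, n2 = n2, stringsAsFactors = FALSE)
  }
  loci <- c("ok", "expr29", "expr30", "mirtron", "flat0", "onesided")
  depths <- rbind(
    mk("ok", 40, 10, 40, "mock", "m1"),
    mk("expr29", 29, 5, 500, "mock", "m1"),     # fails: 29 < 30 on one side
    mk("expr30", 30, 10, 30, "mock", "m1"),     # passes: threshold inclusive
    mk("mirtron", 100, 10, 100, "mock", "m1"),  # fails: exclusion list
    mk("flat0", 50, 50, 50, "mock", "m1"),      # fails: MPI mock == 0, strict
    mk("onesided", 500, 5, 29, "mock", "m1"),   # fails: other side below 30
    do.call(rbind, lapply(loci, function(l) mk(l, 40, 20, 40, "treated", "t1"))))
  res <- mpi_analysis(depths, exclusion_list = "mirtron")$records
  expect_equal(sort(res$locus[res$keep]), sort(c("ok", "expr30")))
  expect_false(res$filter_expression[res$locus == "expr29"])
  expect_true(res$filter_expression[res$locus == "expr30"])
  expect_false(res$filter_exclusionlist[res$locus == "mirtron"])
  expect_false(res$filter_processed_in_mock[res$locus == "flat0"])
  expect_true(all(res$label[!res$keep] == "excluded"))
})

test_that("expression filter modes aggregate mock replicates as documented", {
  depths <- rbind(
    data.frame(locus = "x", sample = c("m1", "m2"), condition = "mock",
               n1 = c(25, 45), n = 5, n2 = c(45, 25)),
    data.frame(locus = "x", sample = "t1", condition = "treated",
               n1 = 40, n = 5, n2 = 40))
  tbl <- mpi_table(depths)
  # replicate means are 35 on both sides: passes
  lax <- apply_filters(tbl, depths, expression_mode = "replicate_mean")
  expect_true(lax$filter_expression)
  # but replicate m1 has n1 = 25 < 30: per-replicate mode fails
  strict <- apply_filters(tbl, depths, expression_mode = "per_replicate")
  expect_false(strict$filter_expression)
})

test_that("classification thresholds are inclusive at +/-0.5 and labels partition", {
  expect_equal(as.character(classify_mpi(0.7)), "less_processed")
  expect_equal(as.character(classify_mpi(0)), "equally_processed")
  expect_equal(as.character(classify_mpi(-0.6)), "more_processed")
  expect_equal(as.character(classify_mpi(c(0.5, -0.5))),
               c("less_processed", "more_processed"))
  expect_equal(as.character(classify_mpi(c(0.499, -0.499))),
               rep("equally_processed", 2))

  set.seed(73)
  fc <- rnorm(200)
  lab <- classify_mpi(fc)
  expect_equal(sum(table(lab)), 200)
  # swapping conditions negates the fold change and maps less <-> more
  swapped <- classify_mpi(-fc)
  expect_equal(as.character(swapped[lab == "less_processed"]),
               rep("more_processed", sum(lab == "less_processed")))
  expect_equal(as.character(swapped[lab == "equally_processed"]),
               rep("equally_processed", sum(lab == "equally_processed")))
})

test_that("group MPI comparison matches the textbook pooled t-test", {
  same <- compare_group_mpi(c(-1, -2, -3), c(-3, -2, -1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_warning(deg <- compare_group_mpi(c(-3, -3, -3), c(-1, -1, -1)),
                 "zero pooled variance")
  expect_equal(deg$mean_a, -3)
  expect_equal(deg$p, 0)

  set.seed(79)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), mean = 0.5)
    got <- compare_group_mpi(a, b)
    sp <- sqrt((((length(a) - 1) * var(a)) + ((length(b) - 1) * var(b))) /
                 (length(a) + length(b) - 2))
    t_ref <- (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
    expect_equal(got$t, t_ref, tolerance = 1e-10)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(compare_group_mpi(1, c(1, 2)), "at least 2")
})
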