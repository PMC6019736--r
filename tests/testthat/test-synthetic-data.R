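test_that("simulated reads respect the processing limits", {
  sp <- locus_spec("x", p_mock = 1, p_treated = 1)
  g <- mpiseq:::.locus_geometry(sp, 50)
  set.seed(151)
  for (i in 1:5) {
    reads <- simulate_locus_reads(sp, p = 1)
    tr <- pileup(reads, g$window, chrom = "x")
    prec <- tr$depth[(g$precursor_start - g$window[1] + 1):
                       (g$precursor_end - g$window[1])]
    expect_true(all(prec == 0))  # full processing empties the hairpin
    # and cleavage products never cross a cut site
    expect_true(all(reads$end <= g$precursor_start |
                      reads$start >= g$precursor_end))
  }

  set.seed(157)
  m <- mean(replicate(10, pipeline_mpi_once(0)))
  expect_lt(abs(m), 0.15)  # no processing: precursor ~ flanks
})

test_that("read count scales with lambda and bases are conserved", {
  sp <- locus_spec("x", 0.5, 0.5, lambda = 200)
  set.seed(163)
  reads <- simulate_locus_reads(sp, p = 0.5, read_len = 50)
  expect_equal(sum(reads$end - reads$start), 50 * nrow(reads))
  expect_error(simulate_locus_reads(locus_spec("y", 0, 0, shoulder_len = 40),
                                    p = 0, read_len = 50),
               "read_len exceeds")
})

test_that("estimated MPI decreases with processing efficiency", {
  set.seed(167)
  means <- vapply(c(0, 0.25, 0.5, 0.75), function(p) {
    mean(replicate(12, pipeline_mpi_once(p)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("motif planting is recovered by the scanner", {
  set.seed(173)
  for (i in 1:100) {
    s <- random_anchored()
    anchor <- sample(c("cut5", "cut3", "loop5p"), 1)
    off <- sample(-20:20, 1)
    motif <- sample(c("TG", "TGT", "CNNC"), 1)
    a <- switch(anchor, cut5 = s$cut5, cut3 = s$cut3, loop5p = s$loop5p)
    s$sequence <- plant_motif(s$sequence, motif, a, off)
    expect_true(off %in% scan_anchor(s, motif, anchor, c(off, off)))
  }
  s <- random_anchored()
  expect_error(plant_motif(s$sequence, "TG", s$cut5, -200), "outside")
})

test_that("truth table derives labels deterministically from the efficiencies", {
  specs <- rbind(locus_spec("a", 0.5, 0), locus_spec("b", 0.5, 0.5),
                 locus_spec("c", 0.5, 0.75), locus_spec("d", 1, 1))
  tt <- truth_table(specs)
  expect_equal(tt$expected_mpi_mock[1], log2(0.5 + 2^-10))
  expect_equal(tt$true_label, c("less_processed", "equally_processed",
                                "more_processed", "equally_processed"))
  expect_true(is.finite(tt$expected_mpi_mock[4]))  # eps keeps p = 1 finite
})

test_that("cohort simulation is deterministic given a seed", {
  specs <- cohort_design(n_less = 2, n_equal = 2, n_more = 1, n_excluded = 1)
  b1 <- simulate_cohort(specs, n_replicates = 2, seed = 99)
  b2 <- simulate_cohort(specs, n_replicates = 2, seed = 99)
  expect_identical(b1, b2)
  b3 <- simulate_cohort(specs, n_replicates = 2, seed = 100)
  expect_false(identical(b1$reads, b3$reads))

  expect_error(simulate_cohort(rbind(locus_spec("a", 0, 0),
                                     locus_spec("a", 0, 0))),
               "duplicate")
})

test_that("a minimal cohort bundle is complete and self-consistent", {
  b <- simulate_cohort(locus_spec("solo", 0.5, 0), n_replicates = 1,
                       seed = 5)
  expect_equal(names(b$reads), c("mock_1", "treated_1"))
  expect_equal(nrow(b$annotation), 1)
  expect_equal(nrow(b$truth), 1)
  expect_equal(b$truth$true_label, "less_processed")
  # trimming the emitted annotation recovers the simulated precursor
  tr <- trim_hairpin(b$annotation)
  expect_equal(tr$precursor_end - tr$precursor_start, 70)
  # anchors are consistent with the precursor length
  expect_equal(b$anchors$cut3 - b$anchors$cut5, 70)
  # exclusion flag surfaces on the list
  b2 <- simulate_cohort(locus_spec("m", 0.5, 0.5, excluded = TRUE),
                        n_replicates = 1, seed = 5)
  expect_equal(b2$exclusion_list, "m")
})

test_that("written cohorts reload into an equivalent bundle", {
  specs <- cohort_design(n_less = 2, n_equal = 2, n_more = 0, n_excluded = 1)
  b <- simulate_cohort(specs, n_replicates = 2, seed = 17)
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  back <- load_cohort(dir)
  expect_equal(back$annotation, b$annotation, ignore_attr = TRUE)
  expect_equal(back$conditions, b$conditions)
  expect_equal(back$exclusion_list, b$exclusion_list)
  expect_equal(back$sequences, b$sequences)
  expect_equal(back$anchors, b$anchors, ignore_attr = TRUE)
  expect_equal(back$host_counts, b$host_counts)
  for (s in names(b$reads)) {
    key <- function(df) df[with(df, order(chrom, start, end)),
                           c("chrom", "start", "end")]
    expect_equal(key(back$reads[[s]]), key(b$reads[[s]]), ignore_attr = TRUE)
  }
})

test_that("planted cohort groups carry their motifs at the instructed rates", {
  specs <- cohort_design(n_less = 10, n_equal = 10, n_more = 0)
  plant <- data.frame(motif = "TG", anchor = "cut5", offset = -14,
                      rate = c(0.8, 0.1),
                      class = c("less_processed", "equally_processed"),
                      stringsAsFactors = FALSE)
  b <- simulate_cohort(specs, n_replicates = 1, seed = 21, plant = plant)
  seqs <- anchored_sequences(b$sequences, b$anchors)
  names(seqs) <- vapply(seqs, `[[`, "", "locus")
  hit <- vapply(seqs, function(s) {
    length(scan_anchor(s, "TG", "cut5", c(-14, -14))) > 0
  }, logical(1))
  less <- b$specs$name[b$specs$true_class == "less_processed"]
  equal <- b$specs$name[b$specs$true_class == "equally_processed"]
  expect_equal(sum(hit[less]), 8)
  expect_equal(sum(hit[equal]), 1)
})
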