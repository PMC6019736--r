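test_that("annotation rows map to hairpin records and bad rows are rejected", {
  tab <- data.frame(
    name = c("mir-X", "mir-bad"), chrom = "chr1",
    hairpin_start = c(1000, 1000), hairpin_end = c(1085, 1085),
    strand = "+",
    mature5p_start = c(1000, 900), mature5p_end = c(1022, 930),
    mature3p_start = c(1060, 1060), mature3p_end = c(1082, 1082),
    stringsAsFactors = FALSE)
  out <- validate_hairpins(tab)
  expect_equal(out$name, "mir-X")
  expect_equal(out$mature5p_end, 1022)
  rej <- attr(out, "rejected")
  expect_equal(rej$row, 2L)
  expect_match(rej$reason, "5p arm outside hairpin")

  expect_error(validate_hairpins(tab[, -2]), "missing required column")
})

test_that("rejected rows are reported with their file line numbers", {
  tab <- random_hairpins(5)
  tab$hairpin_end[3] <- tab$hairpin_start[3]  # empty interval
  tab$mature5p_start[3] <- NA; tab$mature5p_end[3] <- NA
  tab$mature3p_start[3] <- NA; tab$mature3p_end[3] <- NA
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mirna_annotation(tab, f)
  expect_warning(out <- read_mirna_annotation(f), "rejected")
  expect_equal(attr(out, "rejected")$line, 4L)  # row 3 + header
  expect_equal(nrow(out), 4)
})

test_that("annotation round-trips through write and parse", {
  set.seed(101)
  recs <- validate_hairpins(random_hairpins(50))
  expect_equal(nrow(recs), 50)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mirna_annotation(recs, f)
  back <- read_mirna_annotation(f)
  expect_equal(back, recs, ignore_attr = TRUE)
})

test_that("one-based input coordinates are shifted on ingest", {
  tab <- data.frame(name = "m", chrom = "c", hairpin_start = 1001,
                    hairpin_end = 1085, strand = "+",
                    mature5p_start = 1001, mature5p_end = 1022,
                    mature3p_start = 1060, mature3p_end = 1082)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mirna_annotation(validate_hairpins(tab), f)
  out <- read_mirna_annotation(f, one_based = TRUE)
  expect_equal(out$hairpin_start, 1000)
  expect_equal(out$mature5p_start, 1000)
  expect_equal(out$hairpin_end, 1085)  # end stays: half-open == inclusive end
})

test_that("hairpin trimming follows the mature arms, keeping untrimmed ends when an arm is absent", {
  plus <- validate_hairpins(data.frame(
    name = "a", chrom = "c", hairpin_start = 1000, hairpin_end = 1085,
    strand = "+", mature5p_start = 1000, mature5p_end = 1022,
    mature3p_start = 1060, mature3p_end = 1082))
  t1 <- trim_hairpin(plus)
  expect_equal(c(t1$precursor_start, t1$precursor_end), c(1000, 1082))

  minus <- validate_hairpins(data.frame(
    name = "b", chrom = "c", hairpin_start = 1000, hairpin_end = 1085,
    strand = "-", mature5p_start = 1063, mature5p_end = 1085,
    mature3p_start = 1000, mature3p_end = 1022))
  t2 <- trim_hairpin(minus)
  expect_equal(c(t2$precursor_start, t2$precursor_end), c(1000, 1085))

  no3p <- validate_hairpins(data.frame(
    name = "d", chrom = "c", hairpin_start = 1000, hairpin_end = 1085,
    strand = "+", mature5p_start = 1005, mature5p_end = 1027,
    mature3p_start = NA, mature3p_end = NA))
  t3 <- trim_hairpin(no3p)
  expect_equal(c(t3$precursor_start, t3$precursor_end), c(1005, 1085))
})

test_that("trimming is idempotent and never enlarges the hairpin", {
  set.seed(7)
  recs <- validate_hairpins(random_hairpins(40))
  t1 <- trim_hairpin(recs)
  expect_true(all(t1$precursor_start >= t1$hairpin_start))
  expect_true(all(t1$precursor_end <= t1$hairpin_end))
  t2 <- trim_hairpin(t1)
  expect_equal(t2$precursor_start, t1$precursor_start)
  expect_equal(t2$precursor_end, t1$precursor_end)
})

test_that("shoulders abut the precursor in transcript orientation, exactly 100 bases", {
  rec <- validate_hairpins(data.frame(
    name = "a", chrom = "c", hairpin_start = 1000, hairpin_end = 1082,
    strand = "+", mature5p_start = NA, mature5p_end = NA,
    mature3p_start = NA, mature3p_end = NA))
  r <- build_regions(trim_hairpin(rec))
  expect_equal(c(r$shoulder5_start, r$shoulder5_end), c(900, 1000))
  expect_equal(c(r$shoulder3_start, r$shoulder3_end), c(1082, 1182))

  rec$strand <- "-"
  r2 <- build_regions(trim_hairpin(rec))
  expect_equal(c(r2$shoulder5_start, r2$shoulder5_end), c(1082, 1182))
  expect_equal(c(r2$shoulder3_start, r2$shoulder3_end), c(900, 1000))

  for (r in list(r, r2)) {
    expect_equal(r$shoulder5_end - r$shoulder5_start, 100)
    expect_equal(r$shoulder3_end - r$shoulder3_start, 100)
  }
})

test_that("loci too close to the contig edge are rejected, not truncated", {
  rec <- validate_hairpins(data.frame(
    name = "edge", chrom = "c", hairpin_start = 40, hairpin_end = 110,
    strand = "+", mature5p_start = NA, mature5p_end = NA,
    mature3p_start = NA, mature3p_end = NA))
  r <- build_regions(trim_hairpin(rec))
  expect_equal(nrow(r), 0)
  expect_equal(attr(r, "rejected")$name, "edge")
})

test_that("mirroring coordinates and flipping strand mirrors the region sets", {
  set.seed(13)
  recs <- validate_hairpins(random_hairpins(20))
  M <- 10000
  mirrored <- recs
  mirrored$hairpin_start <- M - recs$hairpin_end
  mirrored$hairpin_end <- M - recs$hairpin_start
  mirrored$mature5p_start <- M - recs$mature5p_end
  mirrored$mature5p_end <- M - recs$mature5p_start
  mirrored$mature3p_start <- M - recs$mature3p_end
  mirrored$mature3p_end <- M - recs$mature3p_start
  mirrored$strand <- ifelse(recs$strand == "+", "-", "+")
  a <- build_regions(trim_hairpin(recs))
  b <- build_regions(trim_hairpin(mirrored))
  expect_equal(b$precursor_start, M - a$precursor_end)
  expect_equal(b$shoulder5_start, M - a$shoulder5_end)
  expect_equal(b$shoulder3_end, M - a$shoulder3_start)
})

test_that("region sets round-trip through BED6", {
  set.seed(23)
  regions <- build_regions(trim_hairpin(validate_hairpins(random_hairpins(20))))
  f <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(regions, f)
  lines <- readLines(f)
  expect_equal(length(lines), 3 * nrow(regions))
  expect_true(all(grepl("\\.(shoulder5|precursor|shoulder3)\t", lines)))
  back <- read_regions_bed(f)
  back <- back[match(regions$name, back$name), ]
  expect_equal(back, regions, ignore_attr = TRUE)

  write_regions_bed(regions[0, ], f)
  expect_equal(length(readLines(f)), 0)
  expect_equal(nrow(read_regions_bed(f)), 0)
})
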