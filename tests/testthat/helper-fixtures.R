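# Shared fixtures and independent oracles. Oracles are deliberately written
# from first principles (loops, sorting, closed forms), independent of the
# implementation paths they check.

# brute-force per-base membership count
brute_pileup <- function(reads, window) {
  vapply(seq(window[1], window[2] - 1), function(b) {
    sum(reads$start <= b & reads$end > b)
  }, numeric(1))
}

random_reads <- function(n, window, read_len_range = c(1, 60)) {
  start <- sample(seq(window[1] - 60, window[2] + 10), n, replace = TRUE)
  len <- sample(seq(read_len_range[1], read_len_range[2]), n, replace = TRUE)
  data.frame(chrom = "c", start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# a regions row with the given precursor and abutting shoulders
region_row <- function(ps, pe, strand = "+", shoulder_len = 100,
                       name = "x", chrom = "c") {
  left <- c(ps - shoulder_len, ps)
  right <- c(pe, pe + shoulder_len)
  s5 <- if (strand == "+") left else right
  s3 <- if (strand == "+") right else left
  data.frame(name = name, chrom = chrom, strand = strand,
             precursor_start = ps, precursor_end = pe,
             shoulder5_start = s5[1], shoulder5_end = s5[2],
             shoulder3_start = s3[1], shoulder3_end = s3[2],
             stringsAsFactors = FALSE)
}

random_hairpins <- function(n, with_arms = TRUE) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    start <- sample(500:5000, 1)
    len <- sample(60:120, 1)
    arm <- sample(18:25, 2)
    strand <- sample(c("+", "-"), 1)
    has5 <- !with_arms || stats::runif(1) < 0.8
    has3 <- !with_arms || stats::runif(1) < 0.8
    # transcript-5' arm is genomically leftmost on +, rightmost on -
    left <- c(start, start + arm[1])
    right <- c(start + len - arm[2], start + len)
    a5 <- if (strand == "+") left else right
    a3 <- if (strand == "+") right else left
    data.frame(name = sprintf("hp-%03d", i), chrom = "chr1",
               hairpin_start = start, hairpin_end = start + len,
               strand = strand,
               mature5p_start = if (has5) a5[1] else NA,
               mature5p_end = if (has5) a5[2] else NA,
               mature3p_start = if (has3) a3[1] else NA,
               mature3p_end = if (has3) a3[2] else NA,
               stringsAsFactors = FALSE)
  }))
}

# BH adjustment from the definition: p_(i) * n / i, cumulative minimum from
# the largest p down, capped at 1
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# two-sided Fisher exact p by hypergeometric enumeration: sum the
# probabilities of all tables no more likely than the observed one
fisher_oracle <- function(ka, na, kb, nb) {
  k_tot <- ka + kb
  kmin <- max(0, k_tot - nb); kmax <- min(k_tot, na)
  d <- stats::dhyper(kmin:kmax, na, nb, k_tot)
  d_obs <- stats::dhyper(ka, na, nb, k_tot)
  sum(d[d <= d_obs * (1 + 1e-7)])
}

# anchored sequence with random background of length n and anchors at fixed
# interior positions
random_anchored <- function(n = 300, cut5 = 100, precursor_len = 70,
                            mature_len = 22, locus = "x") {
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  anchored_sequence(list(locus = locus, sequence = s, cut5 = cut5,
                         cut3 = cut5 + precursor_len,
                         loop5p = cut5 + mature_len))
}

# group of anchored sequences with a motif present at a given anchor offset
# in exactly round(rate * n) members and absent in the rest
planted_group <- function(n, motif, anchor, offset, rate, prefix = "g") {
  seqs <- lapply(seq_len(n), function(i) {
    random_anchored(locus = sprintf("%s-%03d", prefix, i))
  })
  planted <- sample(n, round(rate * n))
  lapply(seq_len(n), function(i) {
    s <- seqs[[i]]
    a <- switch(anchor, cut5 = s$cut5, cut3 = s$cut3, loop5p = s$loop5p)
    s$sequence <- if (i %in% planted) {
      plant_motif(s$sequence, motif, a, offset)
    } else {
      mpiseq:::.scrub_motif(s$sequence, motif, a, offset)
    }
    s
  })
}

# single-locus MPI through the real coverage path
pipeline_mpi_once <- function(p, lambda = 200, read_len = 50,
                              precursor_len = 70) {
  sp <- locus_spec("x", p, p, lambda = lambda,
                   precursor_len = precursor_len)
  g <- mpiseq:::.locus_geometry(sp, read_len)
  reg <- region_row(g$precursor_start, g$precursor_end, chrom = "x")
  reads <- simulate_locus_reads(sp, p, read_len)
  track <- pileup(reads, g$window, chrom = "x")
  d <- max_regional_depth(track, reg)
  mpi(d$n1, d$n, d$n2)
}
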