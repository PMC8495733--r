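test_that("read_alignments filters unmapped, chrM and unplaced records", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:10000",
    "@SQ\tSN:chrM\tLN:16000",
    "@SQ\tSN:chr1_random\tLN:5000",
    "r1\t0\tchr1\t100\t255\t36M\t*\t0\t0\t*\t*",
    "r2\t16\tchr1\t200\t255\t36M\t*\t0\t0\t*\t*",
    "r3\t0\tchr1\t300\t255\t36M\t*\t0\t0\t*\t*",
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r5\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r6\t0\tchrM\t50\t255\t36M\t*\t0\t0\t*\t*",
    "r7\t0\tchr1_random\t70\t255\t36M\t*\t0\t0\t*\t*"), sam)
  rd <- read_alignments(sam)
  expect_equal(length(rd), 3)
  expect_equal(S4Vectors::metadata(rd)$n_filtered, 2)
  expect_equal(S4Vectors::metadata(rd)$read_length, 36)
  expect_false(any(as.character(GenomicRanges::seqnames(rd)) %in%
                     c("chrM", "chr1_random")))
  rd2 <- read_alignments(sam, drop_chrM = FALSE, drop_unplaced = FALSE)
  expect_equal(length(rd2), 5)
})

test_that("simulator SAM output round-trips through read_alignments", {
  w <- make_world(5e4, n_direct = 10, n_indirect = 5, seed = 61,
                  min_distance = 1200)
  reads <- simulate_chip_reads(w$genome, w$sites, mean_frag_len = 200,
                               n_reads = 500, background_fraction = 0.5,
                               seed = 62)
  sam <- tempfile(fileext = ".sam")
  write_sam(reads, w$genome, sam)
  back <- read_alignments(sam)
  expect_equal(length(back), length(reads))
  expect_equal(sort(GenomicRanges::start(back)),
               sort(GenomicRanges::start(reads)))
  expect_equal(sum(as.character(GenomicRanges::strand(back)) == "-"),
               sum(as.character(GenomicRanges::strand(reads)) == "-"))
})

test_that("strand cross-correlation matches hand Pearson on a toy", {
  # 10 fragments of exact length 100; one read from each end
  set.seed(71)
  frag_start <- sort(sample(100:1800, 10))
  reads <- aligned_reads("chrT",
                         start = c(frag_start, frag_start + 100 - 36),
                         length = 36,
                         strand = rep(c("+", "-"), each = 10))
  prof <- strand_cc_profile(reads, max_shift = 150)
  oracle <- brute_force_cc(reads, 150)
  expect_equal(prof$cc, oracle, tolerance = 1e-12)
  # maximal where reverse 5' ends sit: shift 99
  expect_equal(prof$shift[which.max(prof$cc)], 99)
  expect_true(all(prof$cc <= 1 + 1e-12 & prof$cc >= -1 - 1e-12,
                  na.rm = TRUE))
})

test_that("cross-correlation degenerate inputs behave per contract", {
  # reverse vector an exact copy of forward: cc(0) = 1
  pos <- c(40, 55, 55, 90, 120)
  reads <- aligned_reads("chrT", c(pos, pos - 35), 36,
                         rep(c("+", "-"), each = 5))
  prof <- strand_cc_profile(reads, max_shift = 20)
  expect_equal(prof$cc[1], 1)

  one_strand <- aligned_reads("chrT", c(10, 60, 100), 36, "+")
  expect_error(strand_cc_profile(one_strand), "each strand")
})

test_that("nsc_rsc computes the standard ratios from the profile", {
  cc <- rep(0.01, 101)
  cc[31 + 1] <- 0.03   # phantom peak at the read length
  cc[66 + 1] <- 0.05   # fragment-length peak
  prof <- structure(list(shift = 0:100, cc = cc, read_length = 31,
                         cc_min = 0.01), class = "cc_profile")
  r <- nsc_rsc(prof, exclusion_halfwidth = 10)
  expect_equal(r$nsc, 5)
  expect_equal(r$rsc, 2)
  expect_equal(r$est_fragment_length, 66)
  expect_equal(r$phantom_shift, 31)

  # phantom at background level: RSC undefined with diagnostic
  prof2 <- prof
  prof2$cc[31 + 1] <- 0.01
  r2 <- nsc_rsc(prof2)
  expect_true(is.na(r2$rsc))
  expect_match(r2$diagnostics, "RSC undefined", all = FALSE)
})

test_that("fragment length is recovered from simulated data across seeds", {
  w <- make_world(1.5e5, n_direct = 30, n_indirect = 15, seed = 81)
  for (s in 1:3) {
    reads <- simulate_chip_reads(w$genome, w$sites, ip_profile("none"),
                                 mean_frag_len = 200, frag_sd = 30,
                                 n_reads = 10000, read_len = 36,
                                 background_fraction = 0.3,
                                 seed = 200 + s)
    est <- nsc_rsc(strand_cc_profile(reads, 350))$est_fragment_length
    expect_lt(abs(est - 200), 20)
  }
})

test_that("frip equals the brute-force overlap scan", {
  set.seed(91)
  reads <- uniform_reads(1000, 5e4, seed = 91)
  peaks <- random_intervals(100, 5e4, seed = 92)
  expect_equal(frip(reads, peaks), brute_force_frip(reads, peaks))

  # simple arithmetic case: 40 of 100 reads in a peak
  r2 <- aligned_reads("chrT", c(seq(0, 39) * 10, seq(5000, 5590, 10)),
                      10, "+")
  p2 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 500))
  expect_equal(frip(r2, p2), 0.40)
  expect_equal(frip(r2, GenomicRanges::GRanges()), 0)
  expect_error(frip(GenomicRanges::GRanges(), p2), "empty read set")

  # monotone under peak union; merged peaks never double-count
  p3 <- c(p2, GenomicRanges::GRanges("chrT", IRanges::IRanges(400, 900)))
  expect_gte(frip(r2, p3), frip(r2, p2))
  expect_lte(frip(r2, p3), 1)
})

test_that("frip on uniform reads matches covered genome fraction", {
  reads <- uniform_reads(20000, 1e5, read_len = 1, seed = 93)
  peaks <- GenomicRanges::GRanges("chrS",
    IRanges::IRanges(seq(1, 9.5e4, 5000), width = 500))  # 10% covered
  f <- frip(reads, peaks, rule = "five_prime")
  expect_lt(abs(f - 0.10), 4 * sqrt(0.1 * 0.9 / 20000) + 0.002)
})

test_that("overlap_peaks honours half-open boundaries and the oracle", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))  # [100,200)
  b1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300)) # [199,300)
  b2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 300)) # [200,300)
  expect_length(overlap_peaks(a, b1), 1)   # 1-bp overlap retained
  expect_length(overlap_peaks(a, b2), 0)   # abutting: dropped

  set.seed(94)
  aa <- random_intervals(80, 4e4, seed = 95)
  bb <- random_intervals(60, 4e4, seed = 96)
  got <- overlap_peaks(aa, bb)
  want <- brute_force_overlap(aa, bb)
  expect_equal(GenomicRanges::start(got), GenomicRanges::start(want))
  expect_equal(GenomicRanges::end(got), GenomicRanges::end(want))
  expect_equal(S4Vectors::metadata(got)$overlap_fraction,
               length(want) / length(aa))

  # overlap with self is the identity
  self <- overlap_peaks(aa, aa)
  expect_equal(length(self), length(aa))
})

test_that("frip_hc restricts FRiP to high-confidence-overlapping peaks", {
  set.seed(97)
  reads <- uniform_reads(2000, 5e4, seed = 97)
  peaks <- random_intervals(50, 5e4, seed = 98)
  # peaks subset of hc: identical scores
  expect_equal(frip_hc(reads, peaks, peaks), frip(reads, peaks))
  # disjoint hc: zero
  far <- GenomicRanges::GRanges("chrOther",
                                IRanges::IRanges(1, 1000))
  expect_equal(frip_hc(reads, peaks, far), 0)
  # decoys capture reads: frip_hc <= frip
  hc <- peaks[seq_len(20)]
  expect_lte(frip_hc(reads, peaks, hc), frip(reads, peaks))
})

test_that("poisson peak caller is calibrated on uniform noise", {
  genome_len <- 4e5
  reads <- uniform_reads(20000, genome_len, seed = 99)
  nwin <- ceiling(genome_len / 200)
  # tight threshold: essentially no false windows expected
  pk <- call_peaks_simple(reads, window = 200,
                          fdr_like_threshold = 1e-5,
                          genome_length = c(chrS = genome_len))
  expect_lte(length(pk), 2)
  # looser threshold: expected false windows nwin * 1e-3; stay under
  # the Poisson 99.9% envelope (merging only reduces the count)
  pk2 <- call_peaks_simple(reads, window = 200,
                           fdr_like_threshold = 1e-3,
                           genome_length = c(chrS = genome_len))
  expect_lte(length(pk2), qpois(0.999, nwin * 1e-3))
})

test_that("poisson peak caller finds an enriched site exactly", {
  g_len <- 2e5
  set.seed(100)
  bg <- uniform_reads(5000, g_len, seed = 100)
  # 100x local enrichment at one site
  sig_pos <- 100000L
  sig <- aligned_reads("chrS",
                       start = round(rnorm(1000, sig_pos, 60)),
                       length = 36,
                       strand = sample(c("+", "-"), 1000, TRUE))
  reads <- suppressWarnings(c(bg, sig))
  S4Vectors::metadata(reads) <- list(read_length = 36L,
                                     total_mapped = length(reads))
  pk <- call_peaks_simple(reads, window = 200, frag_len = 100,
                          fdr_like_threshold = 1e-5,
                          genome_length = c(chrS = g_len))
  expect_gte(length(pk), 1)
  hit <- overlap_peaks(pk, GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(sig_pos - 300, sig_pos + 300)))
  expect_equal(length(hit), length(pk))  # only windows at the site

  # empty control falls back to the genome-wide rate
  pk_ctl <- call_peaks_simple(reads, control = NULL, window = 200,
                              frag_len = 100,
                              fdr_like_threshold = 1e-5,
                              genome_length = c(chrS = g_len))
  expect_equal(GenomicRanges::start(pk_ctl), GenomicRanges::start(pk))
  expect_error(call_peaks_simple(reads, window = 1e6), "larger than")
})
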