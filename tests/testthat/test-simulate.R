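test_that("simulate_genome honours composition, determinism and errors", {
  g <- simulate_genome(10, gc_fraction = 0, seed = 1)
  expect_true(grepl("^[AT]+$", g$sequence))

  g1 <- simulate_genome(5000, 0.5, seed = 7)
  g2 <- simulate_genome(5000, 0.5, seed = 7)
  expect_identical(g1$sequence, g2$sequence)

  # observed GC within 3 sigma of Binomial(n, 0.5)
  n <- 1e5
  gbig <- simulate_genome(n, 0.5, seed = 7)
  gc_obs <- genome_gc_count(gbig)
  expect_lt(abs(gc_obs - n * 0.5), 3 * sqrt(n * 0.25))

  expect_error(simulate_genome(0, 0.5), "positive")
  expect_error(simulate_genome(10, 1.5), "\\[0, 1\\]")
})

test_that("place_sites embeds motifs only at direct sites", {
  g <- simulate_genome(50000, 0.5, seed = 3)
  mo <- example_motif()

  ps0 <- place_sites(g, mo, n_direct = 0, n_indirect = 5, seed = 4)
  expect_identical(ps0$genome$sequence, g$sequence)
  expect_equal(nrow(ps0$sites), 5)
  expect_true(all(is.na(ps0$sites$motif)))

  # degenerate consensus-only PWM: every direct center carries the word
  cons <- matrix(0, 6, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  word <- c("G", "A", "T", "T", "A", "C")
  for (i in 1:6) cons[i, word[i]] <- 1
  mo_cons <- pw_motif(cons)
  ps1 <- place_sites(g, mo_cons, n_direct = 20, n_indirect = 0, seed = 5)
  for (i in which(ps1$sites$kind == "direct")) {
    at <- ps1$sites$center[i] - 3L
    expect_identical(substr(ps1$genome$sequence, at + 1, at + 6),
                     "GATTAC")
  }

  expect_error(place_sites(g, mo, 1000, 1000, seed = 1), "too short")
})

test_that("direct/indirect truth windows are recovered by the scanner", {
  w <- make_world(2e5, n_direct = 100, n_indirect = 100, seed = 42,
                  min_distance = 900)
  mo <- example_motif()
  direct <- truth_intervals(w$sites, kind = "direct")
  indirect <- truth_intervals(w$sites, kind = "indirect")
  res_d <- peak_motif_fraction(direct, w$genome, mo, alpha = 1e-4)
  expect_gte(res_d$fraction, 0.95)
  # indirect windows: false-positive rate bounded by 2 * window * alpha
  res_i <- peak_motif_fraction(indirect, w$genome, mo, alpha = 1e-4)
  peak_len <- 200
  fp_bound <- 2 * (peak_len - 15 + 1) * 1e-4
  expect_lte(res_i$fraction, fp_bound + 3 * sqrt(fp_bound / 100))
})

test_that("predict_fragment_length has the right boundaries and ordering", {
  m <- sonication_model(L0 = 1500, Linf = 150, k = 0.15,
                        cell_factor = 0.35, n_ref = 2e7)
  expect_equal(predict_fragment_length(m, 0, 2e7), 1500)
  g5 <- (5e7 / 2e7)^0.35
  expect_equal(predict_fragment_length(m, 0, 5e7), 1500 * g5)
  expect_lt(abs(predict_fragment_length(m, 1e4, 2e7) - 150), 1)
  # strictly decreasing in cycles
  cyc <- 0:60
  pred <- predict_fragment_length(m, cyc, 2e7)
  expect_true(all(diff(pred) < 0))
  # more cells -> longer chromatin at equal cycles
  expect_true(all(predict_fragment_length(m, cyc, 5e7) >=
                    predict_fragment_length(m, cyc, 2e7)))
  expect_error(predict_fragment_length(m, -1), ">= 0")
})

test_that("simulated reads are strand-balanced with correct 5'-end geometry", {
  w <- make_world(seed = 7)
  reads <- simulate_chip_reads(w$genome, w$sites, ip_profile("none"),
                               mean_frag_len = 200, frag_sd = 40,
                               n_reads = 10000, read_len = 36,
                               background_fraction = 0, seed = 8)
  n_fwd <- sum(as.character(GenomicRanges::strand(reads)) == "+")
  expect_lt(abs(n_fwd - 5000), 4 * sqrt(10000 * 0.25))

  # determinism
  reads2 <- simulate_chip_reads(w$genome, w$sites, ip_profile("none"),
                                mean_frag_len = 200, frag_sd = 40,
                                n_reads = 10000, read_len = 36,
                                background_fraction = 0, seed = 8)
  expect_identical(GenomicRanges::start(reads),
                   GenomicRanges::start(reads2))

  # single strong site, occlusion off: strand 5'-end modes differ by
  # about the mean fragment length
  g <- simulate_genome(50000, 0.5, seed = 9)
  one <- data.frame(chrom = g$name, center = 25000L, kind = "indirect",
                    motif = NA, strength = 1)
  r1 <- simulate_chip_reads(g, one, ip_profile("none"),
                            mean_frag_len = 200, frag_sd = 30,
                            n_reads = 10000, read_len = 36,
                            background_fraction = 0, seed = 10)
  p5 <- five_prime_pos(r1)
  fwd <- as.character(GenomicRanges::strand(r1)) == "+"
  # all reads straddle the site: 5'-end distributions sit on opposite
  # sides of it, separated by about the mean fragment length
  expect_lt(max(abs(p5 - 25000)), 1000)  # every fragment covers the site
  expect_lt(abs((median(p5[!fwd]) - median(p5[fwd])) - 200), 20)

  expect_error(simulate_chip_reads(g, NULL, background_fraction = 0.5,
                                   seed = 1),
               "background_fraction = 1")
})

test_that("pure background reads give FRiP near the covered fraction", {
  g <- simulate_genome(1e5, 0.5, seed = 11)
  reads <- simulate_chip_reads(g, NULL, ip_profile("none"),
                               mean_frag_len = 200, frag_sd = 40,
                               n_reads = 20000, read_len = 36,
                               background_fraction = 1, seed = 12)
  # fixed peak set covering 1% of the genome
  peaks <- GenomicRanges::GRanges(g$name,
    IRanges::IRanges(start = seq(1, 9e4, by = 1e4), width = 100))
  f <- frip(reads, peaks)
  # read intervals + fragment spillover widen the effective target a bit:
  # p in [0.01, 0.01 + (read_len)/1e4 * 10 peaks /...]; use generous band
  expect_gt(f, 0.005)
  expect_lt(f, 0.025)
})

test_that("occlusion lowers FRiP for long fragments (TAL1-like)", {
  w <- make_world(seed = 21)
  frips <- vapply(c(225, 400), function(mfl) {
    r <- simulate_chip_reads(w$genome, w$sites, ip_profile("TAL1-like"),
                             mean_frag_len = mfl, frag_sd = 50,
                             n_reads = 8000, read_len = 36,
                             background_fraction = 0.7, seed = 22)
    frip(r, w$truth)
  }, 0)
  expect_gt(frips[1], frips[2])

  # monotone non-increasing beyond the occlusion midpoint over 5 seeds
  for (s in 1:5) {
    fr <- vapply(c(320, 400, 500), function(mfl) {
      r <- simulate_chip_reads(w$genome, w$sites, ip_profile("TAL1-like"),
                               mean_frag_len = mfl, frag_sd = 40,
                               n_reads = 5000, read_len = 36,
                               background_fraction = 0.5, seed = 100 + s)
      frip(r, w$truth)
    }, 0)
    expect_true(all(diff(fr) < 0.02))  # non-increasing up to noise
  }
})

test_that("electropherogram simulation conserves mass and round-trips", {
  tr <- simulate_electropherogram(rep(200, 50), bin_width = 10,
                                  noise_sd = 0)
  expect_equal(sum(tr$intensity > 0), 1)
  expect_equal(tr$size_bp[which.max(tr$intensity)], 205)

  # mass weighting: equal counts at 150 and 450 give intensity ratio 1:3
  tr2 <- simulate_electropherogram(c(rep(150, 40), rep(450, 40)),
                                   bin_width = 10, noise_sd = 0)
  nz <- tr2$intensity[tr2$intensity > 0]
  expect_equal(nz[2] / nz[1], 455 / 155, tolerance = 1e-10)

  # total intensity equals sum of bin-center masses
  set.seed(31)
  lens <- round(rlnorm(5000, log(250), 0.3))
  tr3 <- simulate_electropherogram(lens, bin_width = 5, noise_sd = 0)
  expect_equal(sum(tr3$intensity), sum(lens), tolerance = 0.02)

  expect_error(simulate_electropherogram(numeric(0)), "at least one")
})

test_that("experiment grid carries metadata and matches its config", {
  cfg <- data.frame(factor_profile = "CTCF-like", mean_frag_len = 225)
  grid <- simulate_experiment_grid(cfg, seed = 5, n_reads = 2000,
                                   genome_length = 1e5, n_direct = 20,
                                   n_indirect = 10)
  expect_length(grid$datasets, 1)
  d <- grid$datasets[[1]]
  expect_equal(d$meta$mean_frag_len, 225)
  expect_equal(length(d$reads), 2000)
  expect_s4_class(d$truth, "GRanges")
  expect_s3_class(d$trace, "electropherogram")

  cfg2 <- data.frame(factor_profile = "CTCF-like", cycles = 10)
  grid2 <- simulate_experiment_grid(cfg2, seed = 5, n_reads = 500,
                                    genome_length = 1e5, n_direct = 20,
                                    n_indirect = 10)
  expect_equal(grid2$datasets[[1]]$meta$mean_frag_len,
               predict_fragment_length(sonication_model(), 10))
  expect_error(simulate_experiment_grid(data.frame(x = 1)),
               "factor_profile")
})
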