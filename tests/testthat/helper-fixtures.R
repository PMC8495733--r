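# Shared fixture builders and independent brute-force oracles.

# Small world: genome with embedded sites, reused across tests.
make_world <- function(genome_len = 2e5, n_direct = 40, n_indirect = 20,
                       seed = 101, min_distance = 1500, margin = 2000) {
  g <- simulate_genome(genome_len, 0.45, seed = seed)
  ps <- place_sites(g, example_motif(), n_direct, n_indirect,
                    min_distance = min_distance, margin = margin,
                    seed = seed + 1)
  ps$truth <- truth_intervals(ps$sites)
  ps
}

genome_gc_count <- function(g) {
  sum(strsplit(g$sequence, "")[[1]] %in% c("G", "C"))
}

# Quadratic any-overlap oracle between read intervals (0-based half-open
# given as 1-based closed GRanges) and a peak list.
brute_force_frip <- function(reads, peaks) {
  if (length(peaks) == 0) return(0)
  rs <- GenomicRanges::start(reads); re <- GenomicRanges::end(reads)
  ps <- GenomicRanges::start(peaks); pe <- GenomicRanges::end(peaks)
  rc <- as.character(GenomicRanges::seqnames(reads))
  pc <- as.character(GenomicRanges::seqnames(peaks))
  n_in <- 0L
  for (i in seq_along(reads)) {
    hit <- FALSE
    for (j in seq_along(peaks)) {
      if (rc[i] == pc[j] && rs[i] <= pe[j] && ps[j] <= re[i]) {
        hit <- TRUE
        break
      }
    }
    n_in <- n_in + hit
  }
  n_in / length(reads)
}

brute_force_overlap <- function(a, b) {
  as_ <- GenomicRanges::start(a); ae <- GenomicRanges::end(a)
  bs <- GenomicRanges::start(b); be <- GenomicRanges::end(b)
  ac <- as.character(GenomicRanges::seqnames(a))
  bc <- as.character(GenomicRanges::seqnames(b))
  keep <- vapply(seq_along(a), function(i)
    any(ac[i] == bc & as_[i] <= be & bs <= ae[i]), TRUE)
  a[keep]
}

# Dense hand-Pearson strand cross-correlation over one chromosome.
brute_force_cc <- function(reads, max_shift) {
  p5 <- sonichip::five_prime_pos(reads)
  fwd <- as.character(GenomicRanges::strand(reads)) == "+"
  L <- max(p5)
  f <- tabulate(p5[fwd], nbins = L)
  r <- tabulate(p5[!fwd], nbins = L)
  vapply(0:max_shift, function(d) {
    m <- L - d
    if (m < 2) return(NA_real_)
    suppressWarnings(stats::cor(f[1:m], r[(d + 1):L]))
  }, 0)
}

# Exhaustive PWM null distribution for small widths.
enumerate_scores <- function(S, bg) {
  w <- nrow(S)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  score <- vapply(seq_len(nrow(grid)), function(r)
    sum(S[cbind(seq_len(w), grid[r, ])]), 0)
  prob <- vapply(seq_len(nrow(grid)), function(r)
    prod(bg[grid[r, ]]), 0)
  data.frame(score = score, prob = prob)
}

random_pwm <- function(w, seed) {
  set.seed(seed)
  m <- matrix(stats::rgamma(w * 4, shape = 0.8) + 0.02, nrow = w)
  pw_motif(m / rowSums(m))
}

uniform_reads <- function(n, genome_len, read_len = 36, seed = 1,
                          chrom = "chrS") {
  set.seed(seed)
  start0 <- floor(runif(n) * (genome_len - read_len))
  aligned_reads(chrom, start0, read_len,
                sample(c("+", "-"), n, replace = TRUE))
}

random_intervals <- function(n, genome_len, min_w = 50, max_w = 400,
                             seed = 1, chrom = "chrS") {
  set.seed(seed)
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- sample.int(genome_len - max_w, n)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, width = w),
                         name = sprintf("iv%03d", seq_len(n)))
}
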