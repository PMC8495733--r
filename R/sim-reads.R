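#' Construct an aligned read set
#'
#' The in-memory representation of mapped single-end reads is a `GRanges`
#' whose ranges are the read intervals (0-based half-open converted to the
#' 1-based closed GRanges convention), with strand and per-set metadata
#' `read_length` (modal) and `total_mapped`.
#'
#' @param chrom Chromosome name(s).
#' @param start 0-based read start positions (5' end for + reads).
#' @param length Read length(s) in bp.
#' @param strand "+" or "-".
#' @return A `GRanges` read set.
#' @export
aligned_reads <- function(chrom, start, length, strand) {
  stopifnot(all(start >= 0), all(length > 0))
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start + 1L, width = length),
    strand = strand)
  rl <- as.integer(names(sort(table(length), decreasing = TRUE))[1])
  S4Vectors::metadata(gr) <- list(read_length = rl,
                                  total_mapped = base::length(gr))
  gr
}

read_length_of <- function(reads) {
  S4Vectors::metadata(reads)$read_length %||%
    as.integer(stats::median(GenomicRanges::width(reads)))
}

#' 5'-end positions of reads
#'
#' @param reads Read `GRanges`.
#' @return Integer vector of 1-based 5'-end positions (start for +,
#'   end for -).
#' @export
five_prime_pos <- function(reads) {
  ifelse(as.character(GenomicRanges::strand(reads)) == "-",
         GenomicRanges::end(reads), GenomicRanges::start(reads))
}

#' Simulate a ChIP-seq read set
#'
#' Generative model: each sequenced read comes either from background
#' (uniformly placed fragment) or from signal (a fragment covering a
#' binding site).  Signal fragments are accepted with probability
#' `pulldown_prob(ip_model, length)`; a rejected signal fragment is
#' replaced by a background fragment, so sequencing depth is fixed and
#' length-dependent IP efficiency translates into a lower fraction of
#' reads at sites.  Fragment lengths are log-normal with the requested
#' mean and sd, truncated below at `read_len`.  Each fragment emits one
#' read from a uniformly chosen end: a forward read whose 5' end is the
#' fragment start, or a reverse read whose 5' end is the fragment end.
#'
#' @param genome A `sim_genome` (defines coordinate bounds).
#' @param sites Site data.frame from [place_sites()]; may be `NULL` /
#'   empty only when `background_fraction = 1`.
#' @param ip_model An [ip_profile()] model.
#' @param mean_frag_len,frag_sd Mean and sd (bp) of the fragment-length
#'   distribution (the sheared chromatin).
#' @param n_reads Number of reads to emit.
#' @param read_len Read length in bp.
#' @param background_fraction Fraction of fragments drawn from background
#'   before IP selection.
#' @param seed Integer seed.
#' @return Read set `GRanges` (see [aligned_reads()]) with metadata
#'   `fragment_lengths` (the pre-IP chromatin lengths drawn, for
#'   electropherogram construction) and `n_signal` (reads accepted as
#'   signal).
#' @export
simulate_chip_reads <- function(genome, sites, ip_model = ip_profile("none"),
                                mean_frag_len = 225, frag_sd = 50,
                                n_reads = 10000, read_len = 36,
                                background_fraction = 0.7, seed = NULL) {
  stopifnot(inherits(genome, "sim_genome"),
            background_fraction >= 0, background_fraction <= 1)
  n_sites <- if (is.null(sites)) 0L else nrow(sites)
  if (n_sites == 0L && background_fraction < 1)
    stop("empty site list requires background_fraction = 1")
  if (mean_frag_len <= read_len)
    stop("mean_frag_len must exceed read_len")
  L <- genome$length
  with_seed(seed, {
    sdlog <- sqrt(log(1 + (frag_sd / mean_frag_len)^2))
    meanlog <- log(mean_frag_len) - sdlog^2 / 2
    frag_len <- pmin(pmax(round(rlnorm(n_reads, meanlog, sdlog)),
                          read_len), L - 1L)
    is_bg <- runif(n_reads) < background_fraction
    if (!all(is_bg)) {
      idx_sig <- which(!is_bg)
      site_i <- sample.int(n_sites, length(idx_sig), replace = TRUE,
                           prob = sites$strength)
      keep <- runif(length(idx_sig)) <
        pulldown_prob(ip_model, frag_len[idx_sig])
      is_bg[idx_sig[!keep]] <- TRUE        # failed pulldown -> background
      idx_sig <- idx_sig[keep]
      site_i <- site_i[keep]
    } else {
      idx_sig <- integer(0)
    }
    frag_start <- integer(n_reads)
    # background: uniform fragment placement
    bg <- which(is_bg)
    frag_start[bg] <- floor(runif(length(bg)) * (L - frag_len[bg]))
    # signal: the site center falls uniformly within the fragment
    if (length(idx_sig)) {
      centers <- sites$center[site_i]
      offset <- floor(runif(length(idx_sig)) * frag_len[idx_sig])
      frag_start[idx_sig] <- pmin(pmax(centers - offset, 0L),
                                  L - frag_len[idx_sig])
    }
    fwd <- runif(n_reads) < 0.5
    start0 <- ifelse(fwd, frag_start,
                     frag_start + frag_len - read_len)
    reads <- aligned_reads(genome$name, start0, read_len,
                           ifelse(fwd, "+", "-"))
    md <- S4Vectors::metadata(reads)
    md$fragment_lengths <- frag_len
    md$n_signal <- length(idx_sig)
    md$read_length <- as.integer(read_len)
    S4Vectors::metadata(reads) <- md
    reads
  })
}

#' Simulate an electropherogram trace from fragment lengths
#'
#' Bins fragment lengths and reports per-bin fluorescence intensity
#' proportional to DNA mass (bin midpoint length times fragment count),
#' optionally with additive Gaussian noise clipped at zero — the shape a
#' Bioanalyzer reports for the same material.
#'
#' @param fragment_lengths Vector of fragment lengths in bp (>= 1 value).
#' @param bin_width Histogram bin width in bp.
#' @param noise_sd Sd of additive Gaussian intensity noise (0 = none).
#' @return An [electropherogram] object.
#' @export
simulate_electropherogram <- function(fragment_lengths, bin_width = 10,
                                      noise_sd = 0) {
  if (length(fragment_lengths) < 1L) stop("need at least one fragment")
  lo <- floor(min(fragment_lengths) / bin_width) * bin_width
  hi <- ceiling((max(fragment_lengths) + 1) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- tabulate(findInterval(fragment_lengths, breaks),
                     nbins = length(breaks) - 1L)
  centers <- breaks[-length(breaks)] + bin_width / 2
  intensity <- centers * counts
  if (noise_sd > 0)
    intensity <- pmax(0, intensity + rnorm(length(intensity), 0, noise_sd))
  if (length(centers) < 2L) {            # single bin: pad a zero neighbour
    centers <- c(centers, centers + bin_width)
    intensity <- c(intensity, 0)
  }
  electropherogram(centers, intensity)
}

#' Write reads as a SAM file
#'
#' Minimal single-end SAM: header with the genome's sequence line, one
#' alignment record per read (flag 16 for minus-strand), `*` sequence and
#' quality.  Readable back with [read_alignments()].
#'
#' @param reads Read set `GRanges`.
#' @param genome_lengths Named integer vector of chromosome lengths, or a
#'   `sim_genome`.
#' @param path Output path (".sam").
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome_lengths, path) {
  if (inherits(genome_lengths, "sim_genome"))
    genome_lengths <- setNames(genome_lengths$length, genome_lengths$name)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(genome_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm,
                       as.integer(genome_lengths[[nm]])), con)
  n <- length(reads)
  if (n) {
    flag <- ifelse(as.character(GenomicRanges::strand(reads)) == "-",
                   16L, 0L)
    recs <- sprintf("r%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                    seq_len(n), flag,
                    as.character(GenomicRanges::seqnames(reads)),
                    GenomicRanges::start(reads),
                    GenomicRanges::width(reads))
    writeLines(recs, con)
  }
  invisible(path)
}

#' Simulate a grid of sonication scenarios
#'
#' Produces one complete synthetic dataset (reads, input-chromatin
#' electropherogram, truth intervals, metadata) per scenario row,
#' emulating a sonication-cycles-by-cell-number experiment.  Each row may
#' give the achieved `mean_frag_len` directly, or `cycles` (+ optionally
#' `n_cells`) from which it is predicted with `sonication`.
#'
#' A genome with embedded truth sites is built once per factor profile and
#' shared across that profile's scenarios, so datasets differ only in
#' sonication degree and sampling noise.
#'
#' @param config Data frame; recognized columns: `factor_profile`
#'   ("TAL1-like"/"CTCF-like"/"POL2-like"/"none"), `mean_frag_len` or
#'   `cycles` (+ `n_cells`), and optional per-row overrides `n_reads`,
#'   `read_len`, `frag_sd`, `background_fraction`.
#' @param seed Integer master seed; row r uses `seed + r`.
#' @param sonication A `sonication_model` used when rows give `cycles`.
#' @param genome_length,gc_fraction,n_direct,n_indirect,site_strength
#'   Shared genome/truth-set parameters.
#' @param motif PWM for direct sites; default [example_motif()].
#' @param n_reads,read_len,frag_sd,background_fraction Defaults for rows
#'   that do not override them.
#' @param trace_fragments Number of input-chromatin fragments drawn for
#'   each electropherogram.
#' @return An `experiment_grid`: list of datasets, each a list with
#'   `reads`, `trace`, `truth` (GRanges), and `meta` (row parameters plus
#'   `mean_frag_len` actually used).
#' @export
simulate_experiment_grid <- function(config, seed = 1,
                                     sonication = sonication_model(),
                                     genome_length = 3e5,
                                     gc_fraction = 0.45,
                                     n_direct = 90, n_indirect = 60,
                                     site_strength = 1,
                                     motif = example_motif(),
                                     n_reads = 20000, read_len = 36,
                                     frag_sd = 50,
                                     background_fraction = 0.7,
                                     trace_fragments = 10000) {
  stopifnot(is.data.frame(config), nrow(config) >= 1L)
  if (is.null(config$factor_profile))
    stop("config must have a 'factor_profile' column")
  if (is.null(config$mean_frag_len) && is.null(config$cycles))
    stop("config needs 'mean_frag_len' or 'cycles'")
  profiles <- unique(config$factor_profile)
  worlds <- lapply(setNames(profiles, profiles), function(p) {
    g <- simulate_genome(genome_length, gc_fraction,
                         seed = seed + 10000L + match(p, profiles),
                         name = paste0("chr_", gsub("-like", "", p)))
    place_sites(g, motif, n_direct, n_indirect,
                strengths = site_strength,
                seed = seed + 20000L + match(p, profiles))
  })
  datasets <- lapply(seq_len(nrow(config)), function(r) {
    row <- config[r, , drop = FALSE]
    world <- worlds[[row$factor_profile]]
    mfl <- row$mean_frag_len
    if (is.null(mfl) || is.na(mfl)) {
      mfl <- predict_fragment_length(sonication, row$cycles,
                                     row$n_cells %||% NULL)
    }
    get_par <- function(nm, default) {
      v <- row[[nm]]
      if (is.null(v) || is.na(v)) default else v
    }
    nr <- get_par("n_reads", n_reads)
    rl <- get_par("read_len", read_len)
    fsd <- get_par("frag_sd", frag_sd)
    bgf <- get_par("background_fraction", background_fraction)
    reads <- simulate_chip_reads(
      world$genome, world$sites, ip_profile(row$factor_profile),
      mean_frag_len = mfl, frag_sd = fsd, n_reads = nr, read_len = rl,
      background_fraction = bgf, seed = seed + r)
    trace <- with_seed(seed + 30000L + r, {
      sdlog <- sqrt(log(1 + (fsd / mfl)^2))
      lens <- pmax(round(rlnorm(trace_fragments,
                                log(mfl) - sdlog^2 / 2, sdlog)), 1)
      simulate_electropherogram(lens, bin_width = 10)
    })
    meta <- as.list(row)
    meta$mean_frag_len <- mfl
    meta$id <- meta$id %||% sprintf("scenario_%02d", r)
    list(reads = reads, trace = trace,
         truth = truth_intervals(world$sites), meta = meta)
  })
  structure(list(datasets = datasets, config = config, seed = seed),
            class = "experiment_grid")
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat(sprintf("<experiment_grid> %d synthetic datasets (seed %d)\n",
              length(x$datasets), x$seed))
  meta <- do.call(rbind, lapply(x$datasets, function(d)
    data.frame(id = d$meta$id, factor = d$meta$factor_profile,
               mean_frag_len = round(d$meta$mean_frag_len, 1),
               n_reads = length(d$reads))))
  print(meta, row.names = FALSE)
  invisible(x)
}

#' A compact example transcription-factor motif
#'
#' A 15-position PWM with a strong 12-bp core, with width and information
#' content comparable to HOCOMOCO models for CTCF-class zinc-finger
#' factors; used as the default motif in simulations and examples.  At
#' the conventional 1e-4 scanning cutoff, well over 95% of instances
#' sampled from the PWM itself are recovered.
#'
#' @return A [pw_motif].
#' @export
example_motif <- function() {
  core <- c("C", "A", "C", "G", "T", "G", "G", "T", "G", "C", "A", "G")
  w <- length(core) + 3L
  probs <- matrix(0.25, nrow = w, ncol = 4,
                  dimnames = list(NULL, DNA_BASES))
  for (i in seq_along(core)) {
    probs[i + 1L, ] <- 0.02
    probs[i + 1L, core[i]] <- 0.94
  }
  pw_motif(probs, name = "EXAMPLE_TF")
}
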