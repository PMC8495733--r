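#' Simulate a toy genome sequence
#'
#' Draws an i.i.d. nucleotide sequence with a specified GC content, as a
#' stand-in for a reference assembly when exercising the pipeline offline.
#'
#' @param length Genome length in bp (>= 1).
#' @param gc_fraction Target P(G) + P(C), in \[0, 1\].
#' @param seed Integer seed; the same (length, gc_fraction, seed) triple
#'   always yields the same sequence.  `NULL` uses the current RNG stream.
#' @param name Chromosome name used in all downstream coordinates.
#' @return A `sim_genome` object: list with `name`, `sequence` (single
#'   character string over A/C/G/T) and `length`.
#' @examples
#' g <- simulate_genome(1000, 0.5, seed = 1)
#' substr(g$sequence, 1, 20)
#' @export
simulate_genome <- function(length, gc_fraction = 0.5, seed = NULL,
                            name = "chrS") {
  if (!is.numeric(length) || length < 1)
    stop("'length' must be a positive number of bp")
  if (!is.numeric(gc_fraction) || gc_fraction < 0 || gc_fraction > 1)
    stop("'gc_fraction' must lie in [0, 1]")
  length <- as.integer(length)
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
         gc_fraction / 2, (1 - gc_fraction) / 2)
  bases <- with_seed(seed,
    sample(DNA_BASES, length, replace = TRUE, prob = p))
  structure(
    list(name = name, sequence = paste(bases, collapse = ""),
         length = length),
    class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %s: %d bp, GC %.3f\n", x$name, x$length,
              genome_gc(x)))
  invisible(x)
}

genome_gc <- function(genome) {
  counts <- table(strsplit(genome$sequence, "")[[1]])
  sum(counts[c("G", "C")], na.rm = TRUE) / genome$length
}

#' Write a simulated genome as FASTA
#'
#' @param genome A `sim_genome`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$name))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Place direct and indirect binding sites on a simulated genome
#'
#' Direct sites have a motif instance sampled from the PWM written into the
#' genome sequence at the site center; indirect sites (tethered binding)
#' leave the sequence untouched.  Sites are laid out on a jittered grid so
#' they can never overlap.
#'
#' @param genome A `sim_genome`.
#' @param motif A [pw_motif] used to sample direct-site motif instances.
#' @param n_direct,n_indirect Numbers of sites of each kind.
#' @param strengths Relative enrichment per site; recycled to
#'   `n_direct + n_indirect`.  Default 1 for all sites.
#' @param min_distance Minimum center-to-center distance in bp.
#' @param margin Distance kept clear of the genome ends.
#' @param seed Integer seed for site placement and motif sampling.
#' @return List with components `genome` (the possibly modified
#'   `sim_genome`) and `sites`, a data.frame with columns `chrom`,
#'   `center` (0-based), `kind` ("direct"/"indirect"), `motif` (instance
#'   string or NA) and `strength`.
#' @export
place_sites <- function(genome, motif, n_direct, n_indirect,
                        strengths = 1, min_distance = 1000L,
                        margin = 2000L, seed = NULL) {
  stopifnot(inherits(genome, "sim_genome"))
  n <- n_direct + n_indirect
  if (n < 1) stop("need at least one site")
  grid <- seq.int(margin, genome$length - margin, by = min_distance)
  if (length(grid) < n)
    stop(sprintf(
      "genome too short: %d grid slots for %d sites (min_distance=%d)",
      length(grid), n, min_distance))
  w <- if (n_direct > 0) motif_width(motif) else 0L
  sites <- with_seed(seed, {
    centers <- sort(sample(grid, n)) +
      sample.int(max(1L, min_distance %/% 4L), n, replace = TRUE) - 1L
    kind <- sample(rep(c("direct", "indirect"), c(n_direct, n_indirect)))
    inst <- rep(NA_character_, n)
    if (n_direct > 0) {
      for (i in which(kind == "direct"))
        inst[i] <- sample_motif_instance(motif)
    }
    data.frame(chrom = genome$name, center = centers, kind = kind,
               motif = inst,
               strength = rep_len(strengths, n),
               stringsAsFactors = FALSE)
  })
  seqc <- genome$sequence
  for (i in which(sites$kind == "direct")) {
    at <- sites$center[i] - w %/% 2L          # 0-based start of instance
    substr(seqc, at + 1L, at + w) <- sites$motif[i]
  }
  genome$sequence <- seqc
  list(genome = genome, sites = sites)
}

sample_motif_instance <- function(motif) {
  p <- motif$probs
  paste(vapply(seq_len(nrow(p)), function(i)
    sample(DNA_BASES, 1L, prob = p[i, ]), ""), collapse = "")
}

#' Truth-site intervals as a GRanges
#'
#' Converts a `place_sites()` site table to peak-like intervals of fixed
#' half-width around each site center, for FRiP/overlap computations.
#'
#' @param sites Site data.frame from [place_sites()].
#' @param flank Half-width in bp around the site center.
#' @param kind Optional subset: "direct", "indirect" or both (default).
#' @return A `GRanges` with `name`, `kind` and `strength` columns.
#' @export
truth_intervals <- function(sites, flank = 100L,
                            kind = c("direct", "indirect")) {
  kind <- match.arg(kind, several.ok = TRUE)
  s <- sites[sites$kind %in% kind, , drop = FALSE]
  ids <- sprintf("site_%05d", match(s$center, sort(sites$center)))
  gr <- GenomicRanges::GRanges(
    s$chrom,
    IRanges::IRanges(start = pmax(1L, s$center - flank + 1L),
                     end = s$center + flank),
    name = ids, kind = s$kind, strength = s$strength)
  names(gr) <- ids
  gr
}
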