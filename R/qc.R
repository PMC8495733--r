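#' Read and filter a SAM/BAM alignment file
#'
#' Loads mapped single-end reads, dropping unmapped records and — per the
#' standard ChIP-seq hygiene — mitochondrial and unplaced-contig reads.
#' SAM input is converted on the fly.
#'
#' @param path SAM or BAM file.
#' @param drop_chrM Drop chrM/MT reads.
#' @param drop_unplaced Drop reads on contigs matching `unplaced_regex`.
#' @param unplaced_regex Pattern identifying unplaced/alternate contigs.
#' @return Read set `GRanges` with metadata `read_length`, `total_mapped`
#'   and `n_filtered` (records removed by the chromosome filters).
#' @export
read_alignments <- function(path, drop_chrM = TRUE, drop_unplaced = TRUE,
                            unplaced_regex = "_random$|^chrUn|_alt$|_hap") {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (tolower(tools::file_ext(path)) == "sam") {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))
  if (length(ga) == 0L) stop("no mapped reads in ", path)
  gr <- GenomicRanges::granges(ga)
  rlens <- GenomicAlignments::qwidth(ga)
  keep <- rep(TRUE, length(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (drop_chrM) keep <- keep & !(chrom %in% c("chrM", "chrMT", "MT", "M"))
  if (drop_unplaced) keep <- keep & !grepl(unplaced_regex, chrom)
  n_filtered <- sum(!keep)
  gr <- gr[keep]
  if (length(gr) == 0L) stop("no reads left after chromosome filtering")
  rl <- as.integer(names(sort(table(rlens[keep]), decreasing = TRUE))[1])
  S4Vectors::metadata(gr) <- list(read_length = rl,
                                  total_mapped = length(gr),
                                  n_filtered = n_filtered)
  gr
}

#' Strand cross-correlation profile
#'
#' In a successful ChIP-seq experiment, reads pile up on the forward and
#' reverse strands on either side of each binding site, offset by roughly
#' the fragment length.  This computes, for every shift d in
#' `0:max_shift`, the Pearson correlation between the per-position
#' forward-strand 5'-end counts and the reverse-strand 5'-end counts
#' shifted left by d.  Chromosomes are processed independently and pooled
#' by summing per-shift sufficient statistics, so no cross-chromosome
#' position pairs are formed.
#'
#' @param reads Read set `GRanges` (see [aligned_reads()]).
#' @param max_shift Largest shift examined, bp.
#' @return A `cc_profile`: list with `shift`, `cc`, `read_length`,
#'   `cc_min`.
#' @export
strand_cc_profile <- function(reads, max_shift = 400) {
  str <- as.character(GenomicRanges::strand(reads))
  pos5 <- five_prime_pos(reads)
  chrom <- as.character(GenomicRanges::seqnames(reads))
  fwd_all <- str == "+"
  if (length(unique(pos5[fwd_all])) < 2L ||
      length(unique(pos5[!fwd_all])) < 2L)
    stop("need >= 2 distinct 5'-end positions on each strand")
  shifts <- 0:max_shift
  stats_acc <- matrix(0, nrow = length(shifts), ncol = 6,
                      dimnames = list(NULL,
                        c("n", "sf", "sf2", "sr", "sr2", "sfr")))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    p <- pos5[sel]; f_ <- fwd_all[sel]
    L <- max(p)
    f <- tabulate(p[f_], nbins = L)
    r <- tabulate(p[!f_], nbins = L)
    cf <- cumsum(f); cf2 <- cumsum(f^2)
    cr <- c(0, cumsum(r)); cr2 <- c(0, cumsum(r^2))
    for (j in seq_along(shifts)) {
      d <- shifts[j]
      m <- L - d
      if (m < 2L) next
      stats_acc[j, "n"] <- stats_acc[j, "n"] + m
      stats_acc[j, "sf"] <- stats_acc[j, "sf"] + cf[m]
      stats_acc[j, "sf2"] <- stats_acc[j, "sf2"] + cf2[m]
      stats_acc[j, "sr"] <- stats_acc[j, "sr"] + cr[L + 1L] - cr[d + 1L]
      stats_acc[j, "sr2"] <- stats_acc[j, "sr2"] + cr2[L + 1L] - cr2[d + 1L]
      stats_acc[j, "sfr"] <- stats_acc[j, "sfr"] +
        sum(f[1:m] * r[(d + 1L):L])
    }
  }
  n <- stats_acc[, "n"]
  vf <- stats_acc[, "sf2"] - stats_acc[, "sf"]^2 / n
  vr <- stats_acc[, "sr2"] - stats_acc[, "sr"]^2 / n
  if (!is.finite(vf[1]) || vf[1] <= 0 || vr[1] <= 0)
    stop("zero-variance strand count vector; cannot correlate")
  ok <- is.finite(vf) & is.finite(vr) & vf > 0 & vr > 0 & n >= 2
  cc <- rep(NA_real_, length(shifts))
  cc[ok] <- (stats_acc[ok, "sfr"] -
               stats_acc[ok, "sf"] * stats_acc[ok, "sr"] / n[ok]) /
    sqrt(vf[ok] * vr[ok])
  structure(list(shift = shifts, cc = cc,
                 read_length = read_length_of(reads),
                 cc_min = min(cc, na.rm = TRUE)),
            class = "cc_profile")
}

#' @export
print.cc_profile <- function(x, ...) {
  cat(sprintf(
    "<cc_profile> shifts 0-%d bp, read length %d, cc in [%.4f, %.4f]\n",
    max(x$shift), x$read_length, min(x$cc, na.rm = TRUE),
    max(x$cc, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.cc_profile <- function(x, ...) {
  plot(x$shift, x$cc, type = "l", xlab = "strand shift (bp)",
       ylab = "cross-correlation", ...)
  abline(v = x$read_length, lty = 3)
  invisible(x)
}

#' NSC, RSC and fragment-length estimate from a cross-correlation profile
#'
#' The fragment-length peak is the correlation maximum outside an
#' exclusion zone of `exclusion_halfwidth` bp around the read length,
#' where the "phantom" read-length peak lives.  With `ccmin` the profile
#' minimum (background correlation), `ccfrag` the fragment-peak value and
#' `ccphantom` the phantom-peak value:
#' \deqn{NSC = ccfrag / ccmin, \quad
#'       RSC = (ccfrag - ccmin) / (ccphantom - ccmin).}
#' RSC > 0.8 is the conventional threshold for a successful experiment;
#' values between roughly 1.5 and 2.5 typify clean transcription-factor
#' datasets.
#'
#' Peak locations are taken from a lightly smoothed copy of the profile
#' (running mean of half-width `smooth_halfwidth`), which stabilizes the
#' argmax of the broad fragment-length peak against sampling noise; the
#' reported correlation values come from the raw profile.
#'
#' @param profile A `cc_profile` from [strand_cc_profile()].
#' @param exclusion_halfwidth Half-width (bp) of the phantom exclusion
#'   zone around the read length.
#' @param smooth_halfwidth Half-width (bp) of the running-mean window
#'   used only to locate the peaks; 0 disables smoothing.
#' @return List with `nsc`, `rsc`, `est_fragment_length`,
#'   `phantom_shift`, and `diagnostics` (character, non-empty when RSC is
#'   undefined).
#' @export
nsc_rsc <- function(profile, exclusion_halfwidth = 10,
                    smooth_halfwidth = 15) {
  stopifnot(inherits(profile, "cc_profile"))
  rl <- profile$read_length
  zone <- abs(profile$shift - rl) <= exclusion_halfwidth
  if (all(zone)) stop("exclusion zone covers the whole profile")
  cc <- profile$cc
  ccmin <- min(cc, na.rm = TRUE)
  cc[is.na(cc)] <- -Inf
  cc_loc <- cc
  if (smooth_halfwidth > 0) {
    k <- 2L * as.integer(smooth_halfwidth) + 1L
    if (length(cc) > k) {
      sm <- stats::filter(profile$cc, rep(1 / k, k), sides = 2)
      cc_loc <- ifelse(is.na(sm), cc, as.numeric(sm))
    }
  }
  # argmax of the smoothed profile; plateaus (e.g. around a sharp spike)
  # are resolved by the raw correlation
  out_idx <- which(!zone)
  cand <- out_idx[cc_loc[out_idx] >= max(cc_loc[out_idx]) - 1e-12]
  i_frag <- cand[which.max(cc[cand])]
  frag_shift <- profile$shift[i_frag]
  cc_frag <- cc[i_frag]
  if (any(zone)) {
    i_ph <- which(zone)[which.max(cc[zone])]
    phantom_shift <- profile$shift[i_ph]
    cc_phantom <- cc[i_ph]
  } else {
    phantom_shift <- NA_integer_; cc_phantom <- NA_real_
  }
  nsc <- cc_frag / ccmin
  diagnostics <- character(0)
  denom <- cc_phantom - ccmin
  if (!is.finite(denom) || denom <= 0) {
    rsc <- NA_real_
    diagnostics <- c(diagnostics,
      "phantom peak does not exceed background; RSC undefined")
  } else {
    rsc <- (cc_frag - ccmin) / denom
  }
  if (ccmin <= 0)
    diagnostics <- c(diagnostics,
      "non-positive minimum correlation; NSC not interpretable")
  list(nsc = nsc, rsc = rsc, est_fragment_length = frag_shift,
       phantom_shift = phantom_shift, cc_frag = cc_frag,
       cc_phantom = cc_phantom, cc_min = ccmin,
       diagnostics = diagnostics)
}

#' Fraction of reads in peaks (FRiP)
#'
#' The share of mapped reads whose interval overlaps any peak by at least
#' `min_overlap` bp.  Peaks are merged first, so overlapping peak calls
#' never double-count a read.  With `rule = "five_prime"` a read counts
#' only if its 5'-end position falls inside a peak.
#'
#' @param reads Read set `GRanges`.
#' @param peaks Peak `GRanges` (empty set gives FRiP 0).
#' @param rule Read-in-peak rule: any-overlap of the full read interval
#'   (default) or 5'-end containment.
#' @param min_overlap Minimum overlap in bp for the `"overlap"` rule.
#' @return FRiP as a fraction in \[0, 1\].
#' @export
frip <- function(reads, peaks, rule = c("overlap", "five_prime"),
                 min_overlap = 1L) {
  rule <- match.arg(rule)
  if (length(reads) == 0L) stop("empty read set")
  if (is.null(peaks) || length(peaks) == 0L) return(0)
  merged <- GenomicRanges::reduce(peaks)
  q <- if (rule == "five_prime") {
    GenomicRanges::GRanges(GenomicRanges::seqnames(reads),
                           IRanges::IRanges(five_prime_pos(reads),
                                            width = 1L))
  } else reads
  # reads and peaks may carry disjoint chromosome universes (e.g. a
  # reference set from another assembly build); that is not an error
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(q, merged, minoverlap = min_overlap,
                                 ignore.strand = TRUE))
  sum(hits > 0) / length(reads)
}

#' Peaks overlapping a reference set
#'
#' Returns the subset of `a` whose intervals overlap any interval of `b`
#' by at least 1 bp (half-open/closed conventions respected by GRanges),
#' e.g. the "overlapped-hc" peaks when `b` is a high-confidence reference
#' set.  The overlap fraction |result| / |a| is attached as
#' `metadata(result)$overlap_fraction` (NA when `a` is empty).
#'
#' @param a,b Peak `GRanges` in the same coordinate system.
#' @return Subset of `a`, with the overlap fraction in its metadata.
#' @export
overlap_peaks <- function(a, b) {
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(a, b, ignore.strand = TRUE))
  out <- a[hits > 0]
  S4Vectors::metadata(out)$overlap_fraction <-
    if (length(a)) length(out) / length(a) else NA_real_
  out
}

#' FRiP over the high-confidence-overlapping peak subset
#'
#' `frip_hc(reads, peaks, hc)` equals
#' `frip(reads, overlap_peaks(peaks, hc))`: the fraction of reads in the
#' dataset's peaks that overlap a high-confidence reference set.
#'
#' @inheritParams frip
#' @param hc High-confidence reference peak `GRanges`.
#' @return FRiP-hc as a fraction.
#' @export
frip_hc <- function(reads, peaks, hc, rule = c("overlap", "five_prime")) {
  frip(reads, overlap_peaks(peaks, hc), rule = match.arg(rule))
}

#' Minimal Poisson sliding-window peak caller
#'
#' A deliberately simple caller for synthetic end-to-end runs (it makes no
#' attempt to match production callers): reads are reduced to estimated
#' fragment centers (5' end shifted by `frag_len/2` along the strand),
#' counted in non-overlapping windows, and each window is tested against
#' Poisson(lambda_local), where lambda_local is the larger of the
#' genome-wide rate and the (depth-scaled) control rate in the same
#' window.  Adjacent significant windows are merged.
#'
#' @param reads Read set `GRanges`.
#' @param control Optional control read set; `NULL` falls back to the
#'   genome-wide rate alone.
#' @param window Window size in bp.
#' @param fdr_like_threshold Per-window Poisson tail probability cutoff.
#' @param frag_len Fragment length used to shift 5' ends; default twice
#'   the read length.
#' @param genome_length Optional named vector of chromosome lengths;
#'   defaults to the maximum read end per chromosome.
#' @return Peak `GRanges` with `score` (-log10 of the smallest window
#'   p-value in the peak).
#' @export
call_peaks_simple <- function(reads, control = NULL, window = 200L,
                              fdr_like_threshold = 1e-5, frag_len = NULL,
                              genome_length = NULL) {
  if (length(reads) == 0L) stop("empty read set")
  frag_len <- frag_len %||% (2L * read_length_of(reads))
  shift <- as.integer(round(frag_len / 2))
  centers_of <- function(rs) {
    p <- five_prime_pos(rs)
    ifelse(as.character(GenomicRanges::strand(rs)) == "-",
           p - shift, p + shift)
  }
  chrom <- as.character(GenomicRanges::seqnames(reads))
  centers <- centers_of(reads)
  ctl_chrom <- if (!is.null(control))
    as.character(GenomicRanges::seqnames(control))
  ctl_centers <- if (!is.null(control)) centers_of(control)
  chrom_levels <- unique(chrom)
  lens <- vapply(chrom_levels, function(ch) {
    if (!is.null(genome_length) && ch %in% names(genome_length))
      as.integer(genome_length[[ch]])
    else max(GenomicRanges::end(reads[chrom == ch]))
  }, 0L)
  if (any(window > lens)) stop("window larger than a chromosome")
  total_len <- sum(as.numeric(lens))
  lambda_bg <- length(reads) * window / total_len
  ctl_scale <- if (!is.null(control) && length(control) > 0)
    length(reads) / length(control) else NA_real_
  out <- list()
  for (ch in chrom_levels) {
    L <- lens[[ch]]
    nwin <- ceiling(L / window)
    cen <- centers[chrom == ch]
    cen <- cen[cen >= 1 & cen <= L]
    counts <- tabulate(pmin((cen - 1L) %/% window + 1L, nwin),
                       nbins = nwin)
    lambda <- rep(lambda_bg, nwin)
    if (!is.null(control) && length(control) > 0) {
      ctl <- ctl_centers[ctl_chrom == ch]
      ctl <- ctl[ctl >= 1 & ctl <= L]
      ctl_counts <- tabulate(pmin((ctl - 1L) %/% window + 1L, nwin),
                             nbins = nwin)
      lambda <- pmax(lambda, ctl_counts * ctl_scale)
    }
    pvals <- stats::ppois(counts - 1L, lambda, lower.tail = FALSE)
    sig <- pvals <= fdr_like_threshold
    if (!any(sig)) next
    runs <- rle(sig)
    ends_i <- cumsum(runs$lengths)
    starts_i <- ends_i - runs$lengths + 1L
    keep <- which(runs$values)
    gr <- GenomicRanges::GRanges(
      ch,
      IRanges::IRanges(start = (starts_i[keep] - 1L) * window + 1L,
                       end = pmin(ends_i[keep] * window, L)),
      score = vapply(keep, function(i)
        -log10(max(min(pvals[starts_i[i]:ends_i[i]]), 1e-300)), 0))
    out[[ch]] <- gr
  }
  if (!length(out))
    return(GenomicRanges::GRanges(score = numeric(0)))
  unname(do.call(c, unname(out)))
}

#' Read a BED or ENCODE narrowPeak interval file
#'
#' @param path BED3+/BED6 or narrowPeak file.
#' @return Peak `GRanges` (narrowPeak extra columns, including the summit
#'   offset `peak`, become metadata columns).
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  if (grepl("narrowpeak(\\.gz)?$", tolower(path))) {
    extra <- c(signalValue = "numeric", pValue = "numeric",
               qValue = "numeric", peak = "integer")
    rtracklayer::import(path, format = "BED", extraCols = extra)
  } else {
    rtracklayer::import(path, format = "BED")
  }
}

#' Write intervals as BED6
#'
#' @param gr Interval `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
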