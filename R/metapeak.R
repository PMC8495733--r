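#' Peak-centered signal matrix
#'
#' One row per peak: the window is the peak-interval midpoint extended
#' `flank` bp in each direction, split into `bin_width`-bp bins, and each
#' cell holds the summed read coverage over the bin's positions.  Reads
#' are optionally extended to the estimated fragment length from their 5'
#' end before computing coverage (the usual ChIP-seq signal convention).
#' Windows clipped at chromosome ends are zero-padded and flagged.
#'
#' @param reads Read set `GRanges`.
#' @param peaks Peak `GRanges` (non-empty).
#' @param flank Half-window size in bp (>= `bin_width`).
#' @param bin_width Bin size in bp.
#' @param frag_len Fragment length for read extension; `NULL` uses raw
#'   read intervals.
#' @param classes Optional per-peak class labels (e.g. "with"/"without"
#'   motif) stored as the row annotation.
#' @return A `signal_matrix`: numeric matrix (peaks x bins) with
#'   attributes `bin_width`, `flank`, `classes`, `clipped`.
#' @export
signal_matrix <- function(reads, peaks, flank = 1000L, bin_width = 10L,
                          frag_len = NULL, classes = NULL) {
  if (length(peaks) == 0L) stop("empty peak set")
  if (flank < bin_width) stop("flank must be >= bin_width")
  flank <- as.integer(flank); bin_width <- as.integer(bin_width)
  n_bins <- as.integer(ceiling(2 * flank / bin_width))
  frags <- if (is.null(frag_len)) reads else {
    p5 <- five_prime_pos(reads)
    minus <- as.character(GenomicRanges::strand(reads)) == "-"
    st <- ifelse(minus, pmax(1L, p5 - as.integer(frag_len) + 1L), p5)
    GenomicRanges::GRanges(GenomicRanges::seqnames(reads),
                           IRanges::IRanges(st, width = as.integer(frag_len)))
  }
  chrom_r <- as.character(GenomicRanges::seqnames(frags))
  chrom_p <- as.character(GenomicRanges::seqnames(peaks))
  out <- matrix(0, nrow = length(peaks), ncol = n_bins)
  clipped <- logical(length(peaks))
  for (ch in unique(chrom_p)) {
    rsel <- which(chrom_r == ch)
    psel <- which(chrom_p == ch)
    L <- max(if (length(rsel)) max(GenomicRanges::end(frags[rsel])) else 0L,
             max(GenomicRanges::end(peaks[psel])) + flank)
    cov <- rep(0L, L)
    if (length(rsel)) {
      covRle <- IRanges::coverage(IRanges::IRanges(
        GenomicRanges::start(frags[rsel]),
        GenomicRanges::end(frags[rsel])), width = L)
      cov <- as.integer(covRle)
    }
    center <- as.integer(floor((GenomicRanges::start(peaks[psel]) - 1L +
                                  GenomicRanges::end(peaks[psel])) / 2))
    for (k in seq_along(psel)) {
      w_start <- center[k] - flank + 1L     # 1-based inclusive window
      idx <- w_start:(w_start + n_bins * bin_width - 1L)
      vals <- numeric(length(idx))
      inb <- idx >= 1L & idx <= L
      vals[inb] <- cov[idx[inb]]
      if (!all(inb)) clipped[psel[k]] <- TRUE
      out[psel[k], ] <- colSums(matrix(vals, nrow = bin_width))
    }
  }
  rn <- peaks$name %||% names(peaks) %||%
    sprintf("peak_%05d", seq_along(peaks))
  rn[is.na(rn) | !nzchar(rn)] <-
    sprintf("peak_%05d", which(is.na(rn) | !nzchar(rn)))
  rownames(out) <- make.unique(rn)
  structure(out, class = c("signal_matrix", class(out)),
            bin_width = bin_width, flank = flank,
            classes = classes, clipped = clipped)
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf(
    "<signal_matrix> %d peaks x %d bins (%d bp bins, +/-%d bp)\n",
    nrow(x), ncol(x), attr(x, "bin_width"), attr(x, "flank")))
  invisible(x)
}

#' Z-score normalize a signal matrix
#'
#' Centers and scales the matrix cells to mean 0, sd 1 over the chosen
#' scope: all cells of the matrix (`"global"`, the per-dataset default)
#' or each row separately (`"per_row"`).  The result is invariant to
#' positive affine transforms of the input.
#'
#' @param m A [signal_matrix] (or plain matrix).
#' @param scope Normalization scope.
#' @return The normalized matrix, same class and attributes.
#' @export
zscore_normalize <- function(m, scope = c("global", "per_row")) {
  scope <- match.arg(scope)
  a <- attributes(m)
  if (scope == "global") {
    s <- stats::sd(m)
    if (!is.finite(s) || s == 0) stop("zero variance in matrix")
    out <- (m - mean(m)) / s
  } else {
    mu <- rowMeans(m)
    s <- apply(m, 1, stats::sd)
    if (any(!is.finite(s)) || any(s == 0))
      stop("zero variance in one or more rows")
    out <- (m - mu) / s
  }
  attributes(out) <- a
  out
}

#' Per-class aggregate metapeak profile
#'
#' Column (bin) means of the signal matrix within each peak class, the
#' curves drawn above metapeak heatmaps.
#'
#' @param m A [signal_matrix].
#' @param classes Per-row class labels; defaults to the matrix's stored
#'   `classes` annotation, or a single class `"all"`.
#' @return A `metapeak_profile`: list with `profiles` (class x bin
#'   matrix), `n` (class sizes), `bin_width`, `flank`.
#' @export
aggregate_profile <- function(m, classes = NULL) {
  classes <- classes %||% attr(m, "classes") %||% rep("all", nrow(m))
  stopifnot(length(classes) == nrow(m))
  keep <- !is.na(classes)
  cls <- unique(classes[keep])
  if (!length(cls)) stop("no non-empty class")
  prof <- do.call(rbind, lapply(cls, function(cl)
    colMeans(m[classes %in% cl, , drop = FALSE])))
  rownames(prof) <- cls
  structure(list(profiles = prof,
                 n = setNames(as.integer(table(classes[keep])[cls]), cls),
                 bin_width = attr(m, "bin_width"),
                 flank = attr(m, "flank")),
            class = "metapeak_profile")
}

#' @export
print.metapeak_profile <- function(x, ...) {
  cat("<metapeak_profile>\n")
  for (cl in rownames(x$profiles))
    cat(sprintf("  %s: n=%d, center %.3f, flank mean %.3f\n", cl,
                x$n[[cl]],
                x$profiles[cl, ceiling(ncol(x$profiles) / 2)],
                mean(x$profiles[cl, c(1:5,
                                      ncol(x$profiles) - 0:4)])))
  invisible(x)
}

#' @export
plot.metapeak_profile <- function(x, ...) {
  bw <- x$bin_width %||% 1
  fl <- x$flank %||% (ncol(x$profiles) * bw / 2)
  pos <- seq(-fl + bw / 2, by = bw, length.out = ncol(x$profiles))
  cols <- seq_len(nrow(x$profiles))
  plot(range(pos), range(x$profiles), type = "n",
       xlab = "distance from peak center (bp)", ylab = "mean signal", ...)
  for (i in cols) lines(pos, x$profiles[i, ], col = i, lwd = 2)
  legend("topright", legend = sprintf("%s (n=%d)", rownames(x$profiles),
                                      x$n),
         col = cols, lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Order a signal matrix for heatmap display and write it out
#'
#' Rows are sorted by decreasing total signal within each class, with a
#' deterministic lexicographic tie-break on the row (peak) name; the
#' ordered matrix is written as a TSV (bit-stable across re-runs) and
#' optionally rendered as a PNG heatmap.
#'
#' @param m A [signal_matrix].
#' @param tsv Output TSV path, or `NULL` to skip writing.
#' @param png_file Optional PNG path for a rendered heatmap.
#' @param classes Per-row classes; defaults to the stored annotation.
#' @return The ordered matrix, invisibly.
#' @export
render_heatmap <- function(m, tsv = NULL, png_file = NULL,
                           classes = NULL) {
  classes <- classes %||% attr(m, "classes") %||% rep("all", nrow(m))
  rs <- rowSums(m)
  nm <- rownames(m) %||% sprintf("peak_%05d", seq_len(nrow(m)))
  ord <- order(factor(classes, levels = unique(classes)), -rs, nm)
  out <- m[ord, , drop = FALSE]
  if (!is.null(tsv)) {
    df <- data.frame(name = rownames(out), class = classes[ord],
                     format(unclass(out), trim = TRUE, digits = 10),
                     check.names = FALSE)
    utils::write.table(df, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(png_file)) {
    grDevices::png(png_file, width = 600, height = 800)
    on.exit(grDevices::dev.off())
    graphics::image(t(unclass(out)[rev(seq_len(nrow(out))), ,
                                   drop = FALSE]),
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    axes = FALSE, xlab = "position", ylab = "peaks")
  }
  invisible(out)
}
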