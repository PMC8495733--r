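#' Electropherogram trace
#'
#' A fragment-size trace: paired vectors of fragment size (bp, strictly
#' increasing) and non-negative fluorescence intensity, as exported from a
#' Bioanalyzer-style instrument or produced by
#' [simulate_electropherogram()].
#'
#' @param size_bp Numeric vector of sizes in bp (length >= 2).
#' @param intensity Non-negative intensities, same length.
#' @param sort Sort by size instead of erroring on unordered input.
#' @return An `electropherogram` object.
#' @export
electropherogram <- function(size_bp, intensity, sort = FALSE) {
  if (length(size_bp) != length(intensity))
    stop("size and intensity vectors differ in length")
  if (length(size_bp) < 2L) stop("need at least 2 trace points")
  if (any(!is.finite(size_bp)) || any(!is.finite(intensity)))
    stop("non-numeric values in trace")
  if (any(intensity < 0)) stop("negative intensities in trace")
  if (is.unsorted(size_bp, strictly = TRUE)) {
    if (!sort) stop("sizes must be strictly increasing (or use sort=TRUE)")
    o <- order(size_bp)
    size_bp <- size_bp[o]; intensity <- intensity[o]
    if (anyDuplicated(size_bp)) stop("duplicated sizes in trace")
  }
  structure(list(size_bp = as.numeric(size_bp),
                 intensity = as.numeric(intensity)),
            class = "electropherogram")
}

#' @export
print.electropherogram <- function(x, ...) {
  cat(sprintf(
    "<electropherogram> %d points, %.0f-%.0f bp, avg in 100-500 bp: %s\n",
    length(x$size_bp), min(x$size_bp), max(x$size_bp),
    tryCatch(sprintf("%.1f bp", average_fragment_length(x)),
             error = function(e) "n/a")))
  invisible(x)
}

#' @export
plot.electropherogram <- function(x, window = c(100, 500), ...) {
  plot(x$size_bp, x$intensity, type = "l", xlab = "size (bp)",
       ylab = "intensity", ...)
  abline(v = window, lty = 3)
  invisible(x)
}

#' Parse a CSV electropherogram trace
#'
#' Reads a two-column instrument export (size in bp, intensity), with a
#' configurable column mapping for files carrying extra columns or header
#' junk.
#'
#' @param path CSV file path.
#' @param size_col,intensity_col Column indices (or names if `header`).
#' @param sep Field separator.
#' @param skip Header/junk lines to skip.
#' @param header Logical; does the file have a header row after `skip`?
#' @param sort Sort rows by size instead of rejecting unordered files.
#' @return An [electropherogram].
#' @export
parse_trace <- function(path, size_col = 1, intensity_col = 2, sep = ",",
                        skip = 0, header = FALSE, sort = FALSE) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  d <- utils::read.table(path, sep = sep, skip = skip, header = header,
                         stringsAsFactors = FALSE)
  size <- suppressWarnings(as.numeric(d[[size_col]]))
  intensity <- suppressWarnings(as.numeric(d[[intensity_col]]))
  ok <- is.finite(size) & is.finite(intensity)
  if (sum(ok) < 2L) stop("fewer than 2 usable numeric rows in ", path)
  electropherogram(size[ok], intensity[ok], sort = sort)
}

#' Write an electropherogram as CSV
#'
#' @param trace An [electropherogram].
#' @param path Output path; written as `size_bp,intensity` with header.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(
    data.frame(size_bp = trace$size_bp, intensity = trace$intensity),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average chromatin fragment length from a trace
#'
#' The intensity-weighted mean fragment size within a size window
#' (default 100--500 bp, both endpoints included).  Material outside the
#' window — notably large molecular-weight heterochromatin — is excluded
#' entirely so it cannot skew the average.  With `weighting = "molar"` the
#' intensity is first divided by fragment size, converting the mass-
#' proportional fluorescence signal to molar abundance.
#'
#' @param trace An [electropherogram].
#' @param window Length-2 numeric, inclusive size window in bp.
#' @param weighting `"intensity"` (fluorescence/mass weighting, default)
#'   or `"molar"`.
#' @return Average fragment length in bp.
#' @export
average_fragment_length <- function(trace, window = c(100, 500),
                                    weighting = c("intensity", "molar")) {
  stopifnot(inherits(trace, "electropherogram"),
            length(window) == 2L, window[1] < window[2])
  weighting <- match.arg(weighting)
  sel <- trace$size_bp >= window[1] & trace$size_bp <= window[2]
  w <- trace$intensity[sel]
  s <- trace$size_bp[sel]
  if (weighting == "molar") w <- w / s
  if (!length(w) || sum(w) <= 0)
    stop("no intensity within the size window")
  sum(s * w) / sum(w)
}
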