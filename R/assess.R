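#' Pass/LowPass/Fail assessment rule
#'
#' Codifies the metric ranges associated with successful
#' transcription-factor ChIP-seq: FRiP of at least 1%, RSC between 1.5
#' and 2.5, and average chromatin length between 190 and 290 bp.
#' POL2-like targets show no consistent RSC trend, so their rule omits
#' the RSC criterion and only bounds the chromatin length above (< 290
#' bp).  The rule is an explicit heuristic, standing in for subjective
#' signal-track inspection.
#'
#' @param factor_class Target class the rule is tuned for.
#' @param frip_min Minimum FRiP (fraction) below which a dataset fails.
#' @param rsc_range Acceptable RSC interval, or `NULL` to skip the RSC
#'   criterion.
#' @param size_range Acceptable average chromatin length interval (bp).
#' @return An `assessment_rule` object.
#' @export
assessment_rule <- function(factor_class = c("CTCF-like", "TAL1-like",
                                             "POL2-like"),
                            frip_min = 0.01,
                            rsc_range = NULL, size_range = NULL) {
  factor_class <- match.arg(factor_class)
  if (is.null(rsc_range))
    rsc_range <- if (factor_class == "POL2-like") NULL else c(1.5, 2.5)
  if (is.null(size_range))
    size_range <- if (factor_class == "POL2-like") c(0, 290)
                  else c(190, 290)
  stopifnot(frip_min > 0, frip_min < 1,
            is.null(rsc_range) || rsc_range[1] < rsc_range[2],
            size_range[1] < size_range[2])
  structure(list(factor_class = factor_class, frip_min = frip_min,
                 rsc_range = rsc_range, size_range = size_range),
            class = "assessment_rule")
}

#' @export
print.assessment_rule <- function(x, ...) {
  cat(sprintf("<assessment_rule> %s: FRiP >= %.3g", x$factor_class,
              x$frip_min))
  if (!is.null(x$rsc_range))
    cat(sprintf(", RSC in [%.2g, %.2g]", x$rsc_range[1], x$rsc_range[2]))
  cat(sprintf(", size in [%g, %g] bp\n", x$size_range[1],
              x$size_range[2]))
  invisible(x)
}

#' One dataset's QC metric bundle
#'
#' @param id Dataset identifier.
#' @param avg_chromatin_length Average unenriched chromatin length (bp),
#'   or NA.
#' @param nsc,rsc,est_fragment_length Cross-correlation metrics, or NA.
#' @param frip,frip_hc FRiP scores as fractions, or NA.
#' @param n_peaks Number of called peaks, or NA.
#' @param assessment Optional label, normally filled in by [assess()].
#' @return One-row data.frame of class `qc_record`.
#' @export
qc_record <- function(id, avg_chromatin_length = NA, nsc = NA, rsc = NA,
                      est_fragment_length = NA, frip = NA, frip_hc = NA,
                      n_peaks = NA, assessment = NA_character_) {
  for (v in c(frip, frip_hc))
    if (!is.na(v) && (v < 0 || v > 1))
      stop("FRiP values must be fractions in [0, 1]")
  structure(
    data.frame(id = id, avg_chromatin_length = avg_chromatin_length,
               nsc = nsc, rsc = rsc,
               est_fragment_length = est_fragment_length,
               frip = frip, frip_hc = frip_hc, n_peaks = n_peaks,
               assessment = assessment, stringsAsFactors = FALSE),
    class = c("qc_record", "data.frame"))
}

#' Assess a dataset as Pass, LowPass or Fail
#'
#' `Fail` when FRiP is below the rule's minimum; otherwise `Pass` when
#' every remaining criterion present in the record (RSC range, size
#' range) is satisfied — a criterion whose metric is missing, or that the
#' rule omits, is skipped and noted; otherwise `LowPass`.  All triggered
#' and skipped criteria are listed in `reasons`.
#'
#' @param record A [qc_record] (or list with `frip`, optionally `rsc`,
#'   `avg_chromatin_length`).
#' @param rule An [assessment_rule].
#' @return List with `label` ("Pass"/"LowPass"/"Fail") and `reasons`
#'   (character vector).
#' @export
assess <- function(record, rule = assessment_rule("CTCF-like")) {
  frip_v <- record$frip
  if (is.null(frip_v) || is.na(frip_v)) stop("record must carry a FRiP")
  reasons <- character(0)
  if (frip_v < rule$frip_min)
    return(list(label = "Fail",
                reasons = sprintf("FRiP %.4f below minimum %.4f",
                                  frip_v, rule$frip_min)))
  reasons <- c(reasons, sprintf("FRiP %.4f >= %.4f", frip_v,
                                rule$frip_min))
  ok <- TRUE
  rsc_v <- record$rsc %||% NA
  if (is.null(rule$rsc_range)) {
    reasons <- c(reasons, "RSC criterion not used for this factor class")
  } else if (is.na(rsc_v)) {
    reasons <- c(reasons, "RSC missing; criterion skipped")
  } else if (rsc_v < rule$rsc_range[1] || rsc_v > rule$rsc_range[2]) {
    ok <- FALSE
    reasons <- c(reasons, sprintf("RSC %.2f outside [%.2g, %.2g]", rsc_v,
                                  rule$rsc_range[1], rule$rsc_range[2]))
  } else {
    reasons <- c(reasons, sprintf("RSC %.2f in range", rsc_v))
  }
  size_v <- record$avg_chromatin_length %||% NA
  if (is.na(size_v)) {
    reasons <- c(reasons, "chromatin length missing; criterion skipped")
  } else if (size_v < rule$size_range[1] || size_v > rule$size_range[2]) {
    ok <- FALSE
    reasons <- c(reasons,
                 sprintf("chromatin length %.0f bp outside [%g, %g]",
                         size_v, rule$size_range[1], rule$size_range[2]))
  } else {
    reasons <- c(reasons, sprintf("chromatin length %.0f bp in range",
                                  size_v))
  }
  list(label = if (ok) "Pass" else "LowPass", reasons = reasons)
}

#' Bin datasets by chromatin length and test FRiP differences
#'
#' Assigns each record to a chromatin-length bin and compares the chosen
#' metric between bins with two-sample Student's t-tests (equal-variance
#' by default; `welch = TRUE` for the unequal-variance form).  With edges
#' `c(200, 250)` the bins are `<200`, `200-250` (inclusive) and `>250`
#' bp; with a single edge `c(290)` they are `<290` and `>=290`.  Raw
#' p-values are reported without multiple-testing correction.
#'
#' @param records Data frame of QC records (needs
#'   `avg_chromatin_length` and the metric column).
#' @param edges Strictly increasing bin edges in bp.
#' @param metric Column to compare (default `"frip"`).
#' @param all_pairs Test all bin pairs instead of adjacent bins only.
#' @param welch Use Welch's unequal-variance t-test.
#' @return A `bin_test` object: list with `bins` (per-bin n/mean/sd),
#'   `tests` (pair, t, df, p), `excluded` (bins with < 2 records).
#' @export
bin_and_test <- function(records, edges, metric = "frip",
                         all_pairs = FALSE, welch = FALSE) {
  stopifnot(is.data.frame(records), length(edges) >= 1L,
            !is.unsorted(edges, strictly = TRUE))
  x <- records$avg_chromatin_length
  y <- records[[metric]]
  if (is.null(y)) stop("no column '", metric, "' in records")
  bin_idx <- size_bin(x, edges)
  labels <- bin_labels(edges)
  bins <- data.frame(
    bin = labels,
    n = vapply(seq_along(labels), function(i) sum(bin_idx == i, na.rm = TRUE), 0L),
    mean = vapply(seq_along(labels), function(i)
      mean(y[bin_idx == i], na.rm = TRUE), 0),
    sd = vapply(seq_along(labels), function(i)
      stats::sd(y[bin_idx == i], na.rm = TRUE), 0))
  testable <- which(bins$n >= 2L)
  excluded <- bins$bin[bins$n < 2L]
  pairs <- if (all_pairs) {
    if (length(testable) < 2L) matrix(nrow = 0, ncol = 2)
    else t(utils::combn(testable, 2))
  } else {
    adj <- cbind(head(seq_along(labels), -1), tail(seq_along(labels), -1))
    adj[adj[, 1] %in% testable & adj[, 2] %in% testable, , drop = FALSE]
  }
  tests <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    yi <- y[bin_idx == i]; yj <- y[bin_idx == j]
    df_ij <- length(yi) + length(yj) - 2
    if (stats::sd(c(yi, yj)) == 0) {
      # degenerate zero-variance groups: identical values give t = 0
      tt <- list(statistic = 0, parameter = df_ij, p.value = 1)
    } else if (stats::sd(yi) == 0 && stats::sd(yj) == 0) {
      tt <- list(statistic = sign(mean(yi) - mean(yj)) * Inf,
                 parameter = df_ij, p.value = 0)
    } else {
      tt <- stats::t.test(yi, yj, var.equal = !welch)
    }
    data.frame(pair = sprintf("%s vs %s", labels[i], labels[j]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = unname(tt$p.value))
  }))
  if (is.null(tests))
    tests <- data.frame(pair = character(0), t = numeric(0),
                        df = numeric(0), p = numeric(0))
  structure(list(bins = bins, tests = tests, excluded = excluded,
                 metric = metric, edges = edges, welch = welch,
                 bin_index = bin_idx),
            class = "bin_test")
}

# Bin assignment: below the first edge -> bin 1; ties at the first edge go
# up (>= edge1) and ties at later edges stay down, matching the
# <200 / 200-250 / >250 and <290 / >=290 reading of the bin labels.
size_bin <- function(x, edges) {
  idx <- 1L + (x >= edges[1])
  if (length(edges) > 1L)
    for (e in edges[-1]) idx <- idx + (x > e)
  idx
}

bin_labels <- function(edges) {
  if (length(edges) == 1L)
    return(c(sprintf("<%g", edges), sprintf(">=%g", edges)))
  c(sprintf("<%g", edges[1]),
    sprintf("%g-%g", head(edges, -1), tail(edges, -1)),
    sprintf(">%g", tail(edges, 1)))
}

#' @export
print.bin_test <- function(x, ...) {
  cat(sprintf("Chromatin-length bins (%s, %s t-test):\n", x$metric,
              if (x$welch) "Welch" else "Student's"))
  print(x$bins, row.names = FALSE)
  if (nrow(x$tests)) print(x$tests, row.names = FALSE)
  if (length(x$excluded))
    cat("excluded from tests (n < 2):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Compute a full QC record for one dataset
#'
#' Pipeline glue: runs the cross-correlation profile, NSC/RSC, peak
#' calling (when no peak set is supplied), FRiP, FRiP-hc and trace
#' averaging for one dataset, then applies the assessment rule.
#'
#' @param id Dataset identifier.
#' @param reads Read set `GRanges`.
#' @param peaks Peak `GRanges`, or `NULL` to call peaks with
#'   [call_peaks_simple()].
#' @param hc Optional high-confidence reference peak set (enables
#'   FRiP-hc).
#' @param trace Optional [electropherogram] (enables the chromatin-length
#'   metrics).
#' @param rule An [assessment_rule].
#' @param max_shift Cross-correlation shift range.
#' @param peak_threshold Poisson cutoff for the internal caller.
#' @return A [qc_record] with the assessment label filled in; the
#'   `reasons` and called `peaks` are attached as attributes.
#' @export
compute_qc <- function(id, reads, peaks = NULL, hc = NULL, trace = NULL,
                       rule = assessment_rule("CTCF-like"),
                       max_shift = 400, peak_threshold = 1e-5) {
  prof <- strand_cc_profile(reads, max_shift = max_shift)
  cc <- nsc_rsc(prof)
  if (is.null(peaks))
    peaks <- call_peaks_simple(reads,
                               frag_len = cc$est_fragment_length,
                               fdr_like_threshold = peak_threshold)
  frip_v <- frip(reads, peaks)
  frip_hc_v <- if (!is.null(hc)) frip_hc(reads, peaks, hc) else NA_real_
  avg_len <- if (!is.null(trace)) average_fragment_length(trace)
             else NA_real_
  rec <- qc_record(id, avg_chromatin_length = avg_len, nsc = cc$nsc,
                   rsc = cc$rsc,
                   est_fragment_length = cc$est_fragment_length,
                   frip = frip_v, frip_hc = frip_hc_v,
                   n_peaks = length(peaks))
  a <- assess(rec, rule)
  rec$assessment <- a$label
  attr(rec, "reasons") <- a$reasons
  attr(rec, "peaks") <- peaks
  rec
}

#' QC records for every dataset of a simulated grid
#'
#' @param grid An `experiment_grid` from [simulate_experiment_grid()].
#' @param use_truth_peaks Use the truth intervals as the peak set instead
#'   of calling peaks per dataset.
#' @param ... Passed to [compute_qc()].
#' @return Data frame with one [qc_record] row per dataset plus the
#'   scenario metadata columns `factor_profile` and `mean_frag_len`.
#' @export
grid_qc <- function(grid, use_truth_peaks = FALSE, ...) {
  stopifnot(inherits(grid, "experiment_grid"))
  rows <- lapply(grid$datasets, function(d) {
    rule <- assessment_rule(
      if (d$meta$factor_profile %in% c("CTCF-like", "TAL1-like",
                                       "POL2-like"))
        d$meta$factor_profile else "CTCF-like")
    rec <- compute_qc(d$meta$id, d$reads,
                      peaks = if (use_truth_peaks) d$truth else NULL,
                      hc = d$truth, trace = d$trace, rule = rule, ...)
    rec$factor_profile <- d$meta$factor_profile
    rec$mean_frag_len <- d$meta$mean_frag_len
    rec
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  class(out) <- c("qc_record", "data.frame")
  out
}

#' Write the study-style QC report bundle
#'
#' Emits the QC records as TSV, a JSON summary (per-assessment counts,
#' bin table and t-tests when bin edges are given), and scatter plots of
#' FRiP (as a percentage, with the conventional 1% guideline line)
#' against chromatin length and against assessment label.
#'
#' @param records QC record data frame.
#' @param dir Output directory (created if needed).
#' @param edges Optional chromatin-length bin edges for [bin_and_test()].
#' @param metric Metric used in the binned test.
#' @return List of written paths plus the `bin_test` (or `NULL`),
#'   invisibly.
#' @export
build_report <- function(records, dir, edges = NULL, metric = "frip") {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "qc_records.tsv")
  utils::write.table(records, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bt <- if (!is.null(edges) &&
            any(!is.na(records$avg_chromatin_length)))
    bin_and_test(records, edges, metric = metric) else NULL
  summ <- list(
    n_datasets = nrow(records),
    assessment_counts = as.list(table(records$assessment)),
    frip_percent = list(mean = mean(records$frip, na.rm = TRUE) * 100,
                        min = min(records$frip, na.rm = TRUE) * 100,
                        max = max(records$frip, na.rm = TRUE) * 100))
  if (!is.null(bt)) {
    summ$bins <- bt$bins
    summ$tests <- bt$tests
  }
  json <- file.path(dir, "qc_summary.json")
  jsonlite::write_json(summ, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  figs <- character(0)
  if (any(!is.na(records$avg_chromatin_length))) {
    f <- file.path(dir, "frip_vs_size.png")
    grDevices::png(f, width = 600, height = 480)
    plot(records$avg_chromatin_length, records$frip * 100,
         xlab = "average chromatin length (bp)", ylab = "FRiP (%)",
         pch = 19)
    abline(h = 1, lty = 3, col = "gray40")
    grDevices::dev.off()
    figs <- c(figs, f)
  }
  if (any(!is.na(records$assessment))) {
    f <- file.path(dir, "frip_vs_assessment.png")
    grDevices::png(f, width = 480, height = 480)
    lab <- factor(records$assessment, c("Pass", "LowPass", "Fail"))
    plot(as.integer(lab), records$frip * 100, xaxt = "n",
         xlab = "assessment", ylab = "FRiP (%)", pch = 19)
    graphics::axis(1, at = 1:3, labels = levels(lab))
    abline(h = 1, lty = 3, col = "gray40")
    grDevices::dev.off()
    figs <- c(figs, f)
  }
  invisible(list(tsv = tsv, json = json, figures = figs, bin_test = bt))
}
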