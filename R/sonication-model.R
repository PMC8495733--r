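#' Parametric sonication decay model
#'
#' Average chromatin fragment length decays exponentially with the number
#' of sonication cycles, towards an asymptotic minimum size.  Samples with
#' more cells shear more slowly: at a fixed cycle number, the predicted
#' length is larger.  The model is
#' \deqn{L(c, n) = L_\infty + (L_0\,g(n) - L_\infty)\, e^{-k c / g(n)},}
#' with \eqn{g(n) = (n / n_{ref})^{\gamma}} a monotone cell-number factor
#' (\eqn{g = 1} at the reference cell count).
#'
#' @param L0 Unsheared effective size at the reference cell count (bp).
#' @param Linf Asymptotic fragment size as cycles grow (bp).
#' @param k Per-cycle decay rate (> 0).
#' @param cell_factor Exponent \eqn{\gamma \ge 0} of the cell-number factor.
#' @param n_ref Reference cell count at which `g(n) = 1`.
#' @return A `sonication_model` object.
#' @seealso [fit_decay()] to estimate a model from (cycles, length) data,
#'   [predict_fragment_length()], [cycles_for_target()].
#' @examples
#' m <- sonication_model()
#' predict_fragment_length(m, cycles = c(0, 10, 30))
#' @export
sonication_model <- function(L0 = 1500, Linf = 150, k = 0.15,
                             cell_factor = 0.35, n_ref = 2e7) {
  stopifnot(L0 > Linf, Linf > 0, k > 0, cell_factor >= 0, n_ref > 0)
  structure(list(L0 = L0, Linf = Linf, k = k, cell_factor = cell_factor,
                 n_ref = n_ref),
            class = "sonication_model")
}

cell_scaling <- function(model, n_cells) {
  (n_cells / model$n_ref)^model$cell_factor
}

#' Predicted average fragment length after sonication
#'
#' @param model A `sonication_model` or `sonication_fit`.
#' @param cycles Number of sonication cycles (>= 0, vectorized).
#' @param n_cells Cell count of the sample.  For a fitted model this must
#'   match one of the fitted cell-count groups (or be omitted when a single
#'   group was fitted).
#' @return Predicted average chromatin length(s) in bp.
#' @export
predict_fragment_length <- function(model, cycles, n_cells = NULL) {
  UseMethod("predict_fragment_length")
}

#' @export
predict_fragment_length.sonication_model <- function(model, cycles,
                                                     n_cells = NULL) {
  if (any(cycles < 0)) stop("'cycles' must be >= 0")
  g <- cell_scaling(model, n_cells %||% model$n_ref)
  model$Linf + (model$L0 * g - model$Linf) * exp(-model$k * cycles / g)
}

#' @export
predict_fragment_length.sonication_fit <- function(model, cycles,
                                                   n_cells = NULL) {
  if (any(cycles < 0)) stop("'cycles' must be >= 0")
  p <- fit_group_params(model, n_cells)
  p["Linf"] + p["A"] * exp(-p["k"] * cycles)
}

fit_group_params <- function(object, n_cells = NULL) {
  groups <- object$groups
  if (is.null(n_cells)) {
    if (nrow(groups) > 1L)
      stop("model was fitted per cell-count group; supply 'n_cells'")
    idx <- 1L
  } else {
    idx <- match(as.character(n_cells), rownames(groups))
    if (is.na(idx))
      stop(sprintf("no fitted group for n_cells = %s (groups: %s)",
                   format(n_cells), paste(rownames(groups), collapse = ", ")))
  }
  unlist(groups[idx, c("Linf", "A", "k")])
}

#' Fit the cycles-to-fragment-length decay curve
#'
#' Least-squares fit of \eqn{L = L_\infty + A e^{-k c}} to observed
#' (cycles, average length) points, separately for each cell-count group
#' (or with a shared asymptote across groups).  This is the planning model
#' behind "how many cycles do I need for 225 bp chromatin?".
#'
#' @param points Data frame with columns `cycles`, `avg_length` and
#'   optionally `n_cells` (one fit per distinct value).
#' @param shared_Linf Logical; estimate a single asymptote across groups.
#' @return A `sonication_fit` object (inherits `sonication_model`) with
#'   methods for `print`, `summary`, `coef`, `predict`, `plot`,
#'   `residuals` and `simulate`.
#' @examples
#' pts <- data.frame(cycles = seq(5, 25, 5),
#'                   avg_length = 150 + 350 * exp(-0.15 * seq(5, 25, 5)))
#' fit <- fit_decay(pts)
#' coef(fit)
#' cycles_for_target(fit, 225)
#' @export
fit_decay <- function(points, shared_Linf = FALSE) {
  stopifnot(is.data.frame(points),
            all(c("cycles", "avg_length") %in% names(points)))
  grp <- if (is.null(points$n_cells)) rep("all", nrow(points))
         else as.character(points$n_cells)
  split_pts <- split(points, grp)
  for (g in split_pts)
    if (length(unique(g$cycles)) < 3L)
      stop("need >= 3 distinct cycle values per cell-count group")

  fit_one <- function(d, Linf_fixed = NULL) {
    Linf0 <- Linf_fixed %||% max(1, 0.9 * min(d$avg_length))
    A0 <- max(d$avg_length) - min(d$avg_length)
    A0 <- if (A0 > 0) A0 else 1
    slope <- stats::coef(stats::lm(
      log(pmax(d$avg_length - Linf0, 1e-6)) ~ d$cycles))[2]
    k0 <- max(1e-3, -as.numeric(slope))
    if (is.null(Linf_fixed)) {
      minpack.lm::nlsLM(
        avg_length ~ Linf + A * exp(-k * cycles), data = d,
        start = list(Linf = Linf0, A = A0, k = k0),
        lower = c(Linf = 0, A = 0, k = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        avg_length ~ Linf_fixed + A * exp(-k * cycles), data = d,
        start = list(A = A0, k = k0),
        lower = c(A = 0, k = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }

  Linf_shared <- NULL
  if (shared_Linf && length(split_pts) > 1L) {
    # profile the common asymptote on a coarse grid, refine per group
    cand <- seq(0, min(points$avg_length) * 0.99, length.out = 50)
    rss <- vapply(cand, function(L) {
      sum(vapply(split_pts, function(d)
        sum(residuals(fit_one(d, Linf_fixed = L))^2), 0))
    }, 0)
    Linf_shared <- cand[which.min(rss)]
  }

  fits <- lapply(split_pts, fit_one, Linf_fixed = Linf_shared)
  groups <- do.call(rbind, lapply(names(fits), function(nm) {
    cf <- stats::coef(fits[[nm]])
    data.frame(n_cells = suppressWarnings(as.numeric(nm)),
               Linf = if ("Linf" %in% names(cf)) unname(cf["Linf"])
                      else Linf_shared,
               A = unname(cf["A"]), k = unname(cf["k"]),
               rss = sum(residuals(fits[[nm]])^2),
               n = nrow(split_pts[[nm]]))
  }))
  rownames(groups) <- names(fits)
  structure(list(groups = groups, fits = fits, data = points,
                 shared_Linf = shared_Linf),
            class = c("sonication_fit", "sonication_model"))
}

#' Smallest cycle count reaching a target fragment length
#'
#' Inverts the decay model: returns the smallest integer cycle count whose
#' predicted average length is at or below `target`.
#'
#' @inheritParams predict_fragment_length
#' @param target Target average chromatin length in bp; must lie strictly
#'   between the asymptote and the unsheared (0-cycle) length.
#' @return Integer number of cycles.
#' @export
cycles_for_target <- function(model, target, n_cells = NULL) {
  if (inherits(model, "sonication_fit")) {
    p <- fit_group_params(model, n_cells)
    Linf <- p["Linf"]; A <- p["A"]; k <- p["k"]; g <- 1
  } else {
    g <- cell_scaling(model, n_cells %||% model$n_ref)
    Linf <- model$Linf; A <- model$L0 * g - Linf; k <- model$k / g
  }
  L0 <- Linf + A
  if (target <= Linf || target >= L0)
    stop(sprintf(
      "target %.1f bp outside achievable range (%.1f, %.1f) bp",
      target, Linf, L0))
  c_star <- -log((target - Linf) / A) / k
  cyc <- max(0L, ceiling(c_star - 1e-9))
  # guard against floating-point edge: predicted(cyc) must be <= target
  while (Linf + A * exp(-k * cyc) > target + 1e-9) cyc <- cyc + 1L
  as.integer(cyc)
}

#' @export
print.sonication_model <- function(x, ...) {
  cat("Sonication decay model: L(c, n) = Linf + (L0*g(n) - Linf) ",
      "exp(-k*c/g(n))\n", sep = "")
  cat(sprintf("  L0 = %.1f bp, Linf = %.1f bp, k = %.4f /cycle, ",
              x$L0, x$Linf, x$k))
  cat(sprintf("g(n) = (n/%.3g)^%.2f\n", x$n_ref, x$cell_factor))
  invisible(x)
}

#' @export
print.sonication_fit <- function(x, ...) {
  cat("Sonication decay fit: L = Linf + A * exp(-k * cycles)\n")
  print(x$groups, row.names = TRUE)
  invisible(x)
}

#' @export
coef.sonication_fit <- function(object, ...) {
  as.matrix(object$groups[, c("Linf", "A", "k")])
}

#' @export
residuals.sonication_fit <- function(object, ...) {
  unlist(lapply(object$fits, residuals), use.names = FALSE)
}

#' @export
predict.sonication_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    d <- object$data
  } else d <- newdata
  n_cells <- d$n_cells
  if (is.null(n_cells)) n_cells <- rep(NA_real_, nrow(d))
  vapply(seq_len(nrow(d)), function(i) {
    nc <- if (is.na(n_cells[i]) && nrow(object$groups) == 1L) NULL
          else n_cells[i]
    predict_fragment_length(object, d$cycles[i], nc)
  }, 0)
}

#' @export
summary.sonication_fit <- function(object, ...) {
  res <- residuals(object)
  out <- list(groups = object$groups, sigma = sd(res),
              n = length(res), shared_Linf = object$shared_Linf)
  class(out) <- "summary.sonication_fit"
  out
}

#' @export
print.summary.sonication_fit <- function(x, ...) {
  cat(sprintf(
    "Sonication decay fit (%d points, residual sd %.2f bp)\n", x$n,
    x$sigma))
  if (!is.null(x$shared_Linf))
    cat(sprintf("  shared asymptote Linf = %.1f bp\n", x$shared_Linf))
  print(x$groups)
  invisible(x)
}

#' @export
plot.sonication_fit <- function(x, ...) {
  d <- x$data
  grp <- as.character(d$n_cells)
  cols <- setNames(seq_len(nrow(x$groups)), rownames(x$groups))
  plot(d$cycles, d$avg_length, col = cols[grp], pch = 19,
       xlab = "sonication cycles", ylab = "average chromatin length (bp)",
       ...)
  cs <- seq(min(d$cycles), max(d$cycles), length.out = 100)
  for (nm in rownames(x$groups)) {
    p <- unlist(x$groups[nm, c("Linf", "A", "k")])
    lines(cs, p["Linf"] + p["A"] * exp(-p["k"] * cs), col = cols[nm])
  }
  if (nrow(x$groups) > 1L)
    legend("topright", legend = paste(rownames(x$groups), "cells"),
           col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' @export
simulate.sonication_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sig <- sd(residuals(object))
  mu <- predict(object)
  with_seed(seed, {
    out <- as.data.frame(replicate(nsim, mu + rnorm(length(mu), 0, sig)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}
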