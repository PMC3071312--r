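#' Forward MAK2 amplification trajectory
#'
#' The two-parameter mechanistic PCR model: starting from an initial target
#' amount \code{d0} (in fluorescence units), each cycle adds
#' \code{k * ln(1 + F/k)} to the signal \code{F}:
#' \deqn{F_0 = D_0, \quad F_n = F_{n-1} + k \ln(1 + F_{n-1}/k).}
#' Early cycles double the signal (efficiency ~ 1); as \code{F} grows past
#' \code{k} the per-cycle gain saturates, reproducing the bend of a real
#' amplification curve without an explicit plateau term.
#'
#' @param d0 initial target, fluorescence units (>= 0).
#' @param k characteristic PCR constant, fluorescence units (> 0).
#' @param n_cycles number of cycles (default 45).
#' @return numeric vector of length \code{n_cycles}: fluorescence after
#'   cycles 1..n_cycles.
#' @export
mak2_forward <- function(d0, k, n_cycles = 45L) {
  if (k <= 0) stop("'k' must be positive")
  if (d0 < 0) stop("'d0' must be nonnegative")
  out <- numeric(n_cycles)
  f <- d0
  for (n in seq_len(n_cycles)) {
    f <- f + k * log1p(f / k)
    out[n] <- f
  }
  out
}

#' Construct a qPCR amplification curve
#'
#' @param fluorescence background-subtracted fluorescence per cycle
#'   (>= 10 cycles).
#' @param cycle cycle numbers (consecutive integers, default 1..length).
#' @param well well identifier.
#' @return an object of class \code{amplification_curve}.
#' @export
amplification_curve <- function(fluorescence, cycle = seq_along(fluorescence),
                                well = "A1") {
  if (length(fluorescence) < 10L) stop("a curve needs at least 10 cycles")
  if (length(cycle) != length(fluorescence) || any(diff(cycle) != 1))
    stop("'cycle' must be consecutive integers matching 'fluorescence'")
  structure(list(well = as.character(well), cycle = as.integer(cycle),
                 fluorescence = as.numeric(fluorescence)),
            class = "amplification_curve")
}

#' Fit the MAK2 model to an amplification curve
#'
#' Nonlinear least squares of \code{\link{mak2_forward}} against the
#' pre-plateau region of the curve: cycles up to (and including) the first
#' cycle exceeding \code{window_frac} of the maximum fluorescence.  The fit
#' is multistarted over a log-spaced grid of initial \code{(D0, k)} values
#' and the lowest-RSS solution is returned.  A curve whose maximum never
#' rises above \code{noise_floor} is reported as "no amplification"
#' (\code{d0 = 0}) rather than an error.
#'
#' @param curve an \code{\link{amplification_curve}}.
#' @param window_frac fraction of the maximum fluorescence ending the fit
#'   window (default 0.85).
#' @param noise_floor fluorescence below which a curve counts as flat.
#' @param d0_grid,k_grid multistart grids of initial values; defaults span
#'   \code{1e-10..1e-2} for D0 and \code{0.01..100} times the curve maximum
#'   for k.
#' @return an object of class \code{mak2_fit}: list with \code{d0},
#'   \code{k}, \code{window_last_cycle}, \code{rss}, \code{converged},
#'   \code{no_amplification}.
#' @export
fit_mak2 <- function(curve, window_frac = 0.85, noise_floor = 1e-6,
                     d0_grid = 10^seq(-10, -2, by = 2),
                     k_grid = NULL) {
  stopifnot(inherits(curve, "amplification_curve"))
  f <- curve$fluorescence
  fmax <- max(f)
  if (!is.finite(fmax) || fmax <= noise_floor) {
    return(structure(list(d0 = 0, k = NA_real_, window_last_cycle = NA_integer_,
                          rss = NA_real_, converged = TRUE,
                          no_amplification = TRUE, well = curve$well),
                     class = "mak2_fit"))
  }
  last <- which(f > window_frac * fmax)[1]
  last <- max(last, 10L)  # never fit fewer than 10 cycles
  y <- f[seq_len(last)]
  n <- length(y)
  if (is.null(k_grid)) k_grid <- fmax * 10^seq(-2, 2, by = 1)
  best <- NULL
  for (d0s in d0_grid) for (ks in k_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ mak2_forward(exp(ld0), exp(lk), n)[seq_len(n)],
        start = list(ld0 = log(d0s), lk = log(ks)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(d0 = exp(cf[["ld0"]]), k = exp(cf[["lk"]]), rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(d0 = NA_real_, k = NA_real_,
                          window_last_cycle = last, rss = NA_real_,
                          converged = FALSE, no_amplification = FALSE,
                          well = curve$well),
                     class = "mak2_fit"))
  }
  structure(list(d0 = best$d0, k = best$k, window_last_cycle = last,
                 rss = best$rss, converged = TRUE, no_amplification = FALSE,
                 well = curve$well),
            class = "mak2_fit")
}

#' @export
print.mak2_fit <- function(x, ...) {
  if (x$no_amplification) {
    cat("MAK2 fit [", x$well, "]: no amplification\n", sep = "")
  } else {
    cat(sprintf("MAK2 fit [%s]: D0 = %.4g, k = %.4g (window 1..%d, RSS %.3g)\n",
                x$well, x$d0, x$k, x$window_last_cycle, x$rss))
  }
  invisible(x)
}

#' Reference-gene normalization of initial target amounts
#'
#' @param d0_target fitted initial target amount of the gene of interest.
#' @param d0_reference fitted initial target amount of the reference
#'   (housekeeping) gene; must be positive.
#' @return the expression ratio, or \code{NA} when the reference is zero.
#' @export
normalize_expression <- function(d0_target, d0_reference) {
  ifelse(d0_reference > 0, d0_target / d0_reference, NA_real_)
}

#' Fit MAK2 to replicate assay wells and summarize
#'
#' Each well is fitted independently; per curve id the fitted parameters
#' are summarized as mean and sample standard error.
#'
#' @param curves data frame with columns \code{id, well, cycle,
#'   fluorescence} (triplicate wells share an \code{id}).
#' @param ... passed to \code{\link{fit_mak2}}.
#' @return data frame \code{id, d0, d0_se, k, k_se, n_wells}.
#' @export
fit_mak2_replicates <- function(curves, ...) {
  stopifnot(all(c("id", "well", "cycle", "fluorescence") %in% names(curves)))
  rows <- lapply(split(curves, curves$id), function(d) {
    fits <- lapply(split(d, d$well), function(w)
      fit_mak2(amplification_curve(w$fluorescence[order(w$cycle)],
                                   sort(w$cycle), well = w$well[1]), ...))
    d0 <- vapply(fits, `[[`, numeric(1), "d0")
    k <- vapply(fits, `[[`, numeric(1), "k")
    nw <- length(fits)
    data.frame(id = d$id[1],
               d0 = mean(d0), d0_se = if (nw > 1) stats::sd(d0) / sqrt(nw) else 0,
               k = mean(k, na.rm = TRUE),
               k_se = if (nw > 1) stats::sd(k) / sqrt(nw) else 0,
               n_wells = nw, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
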