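#' Construct a growth curve
#'
#' A single well's OD600 time series with an optional blank (medium-only)
#' absorbance to subtract before log-linear fitting.
#'
#' @param time_h numeric vector of time points in hours, strictly increasing,
#'   nonnegative, length >= 10.
#' @param od600 numeric vector of raw absorbance values, same length.
#' @param well well identifier (character).
#' @param blank blank absorbance value subtracted before fitting (scalar).
#' @return an object of class \code{growth_curve}.
#' @export
growth_curve <- function(time_h, od600, well = "A1", blank = 0) {
  time_h <- as.numeric(time_h); od600 <- as.numeric(od600)
  if (length(time_h) != length(od600))
    stop("'time_h' and 'od600' must have the same length")
  if (length(time_h) < 10L) stop("a growth curve needs at least 10 time points")
  if (any(time_h < 0)) stop("negative times are not allowed")
  if (any(diff(time_h) <= 0)) stop("'time_h' must be strictly increasing")
  structure(list(well = as.character(well), time_h = time_h, od600 = od600,
                 blank = as.numeric(blank)),
            class = "growth_curve")
}

# OLS slope, intercept and R^2 on (x, y); R^2 defined as 0 when y is constant.
.ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  r2 <- if (syy <= 0) 0 else {
    rss <- syy - sxy^2 / sxx
    max(0, min(1, 1 - rss / syy))
  }
  list(slope = slope, intercept = my - slope * mx, r_squared = r2, n = n)
}

#' Maximum specific growth rate from a growth curve
#'
#' Blank-subtracts the OD600 series, drops points at or below a positivity
#' floor, and fits ordinary least squares of \code{ln(OD600)} against time
#' over every contiguous window of at least \code{min_points} usable points.
#' The reported rate is the largest window slope among windows whose
#' regression reaches \code{min_r2}; this is an objective, reproducible
#' stand-in for a manually chosen log-phase interval.
#'
#' If no window qualifies (e.g. a constant or blank-level curve) a
#' "no-growth" fit with \code{mu_max = 0} and \code{no_growth = TRUE} is
#' returned rather than an error.
#'
#' @param curve a \code{\link{growth_curve}}.
#' @param min_points minimum window length in points (default 36, i.e. 6 h
#'   at the 10-minute read interval).  Because the reported rate is a
#'   maximum over windows, short windows -- whose slope estimates are noisy
#'   -- bias it upward; 6 h keeps that selection bias well under 2% at
#'   typical plate-reader noise while still fitting inside the exponential
#'   phase of a 48 h run.
#' @param min_r2 minimum R-squared a window must reach to be considered.
#' @param floor exclusion floor: blank-subtracted ODs at or below this are
#'   excluded pointwise from the log regression.  The default 0.02 is about
#'   ten times a typical plate-reader read noise; below it the log of the
#'   signal is noise-dominated (and its concavity inflates window slopes).
#'   Set a small positivity guard (e.g. 1e-4) for noise-free data.
#' @param max_points optional maximum window length (default unlimited).
#' @return an object of class \code{growth_fit}: list with \code{mu_max}
#'   (1/h), \code{window} (index range in the original series), \code{r_squared},
#'   \code{od_max} (maximum blank-subtracted OD), \code{n_points}, and
#'   \code{no_growth}.
#' @export
fit_mu_max <- function(curve, min_points = 36L, min_r2 = 0.98,
                       floor = 0.02, max_points = Inf) {
  stopifnot(inherits(curve, "growth_curve"))
  min_points <- as.integer(min_points)
  if (min_points < 3L) stop("'min_points' must be at least 3")
  od <- curve$od600 - curve$blank
  usable <- is.finite(od) & od > floor
  best <- NULL
  idx <- which(usable)
  if (length(idx) >= min_points) {
    # maximal runs of consecutive usable points
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    for (run in runs) {
      n <- length(run)
      if (n < min_points) next
      t <- curve$time_h[run]
      y <- log(od[run])
      # prefix sums for O(1) per-window OLS
      c1t <- cumsum(t);  c2t <- cumsum(t * t)
      c1y <- cumsum(y);  c2y <- cumsum(y * y)
      cty <- cumsum(t * y)
      wmax <- min(n, max_points)
      for (w in min_points:wmax) {
        i <- seq_len(n - w + 1L); j <- i + w - 1L
        st  <- c1t[j] - c(0, c1t)[i];  stt <- c2t[j] - c(0, c2t)[i]
        sy  <- c1y[j] - c(0, c1y)[i];  syy <- c2y[j] - c(0, c2y)[i]
        sty <- cty[j] - c(0, cty)[i]
        sxx <- stt - st * st / w
        sxy <- sty - st * sy / w
        stot <- syy - sy * sy / w
        slope <- sxy / sxx
        r2 <- ifelse(stot <= 0, 0, pmax(0, pmin(1, 1 - (stot - sxy^2 / sxx) / stot)))
        ok <- which(r2 >= min_r2)
        if (!length(ok)) next
        k <- ok[which.max(slope[ok])]
        if (is.null(best) || slope[k] > best$mu_max) {
          best <- list(mu_max = slope[k], window = c(run[k], run[k + w - 1L]),
                       r_squared = r2[k], n_points = w)
        }
      }
    }
  }
  od_max <- if (any(is.finite(od))) max(od[is.finite(od)]) else NA_real_
  if (is.null(best)) {
    fit <- list(mu_max = 0, window = c(NA_integer_, NA_integer_),
                r_squared = NA_real_, od_max = od_max, n_points = 0L,
                no_growth = TRUE, well = curve$well)
  } else {
    fit <- c(best, list(od_max = od_max, no_growth = FALSE, well = curve$well))
  }
  structure(fit, class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$no_growth) {
    cat("Growth fit [", x$well, "]: no growth detected\n", sep = "")
  } else {
    cat(sprintf("Growth fit [%s]: mu_max = %.4f 1/h (window %d..%d, R2 = %.4f), od_max = %.4f\n",
                x$well, x$mu_max, x$window[1], x$window[2], x$r_squared, x$od_max))
  }
  invisible(x)
}

#' Relative fitness
#'
#' Mutant maximum specific growth rate divided by the reference strain's
#' rate under the same condition.
#'
#' @param mu_mut mutant growth rate (1/h).
#' @param mu_ref reference growth rate (1/h); must be positive.
#' @return the ratio, or \code{NA} when \code{mu_ref} is zero.
#' @export
relative_fitness <- function(mu_mut, mu_ref) {
  ifelse(mu_ref > 0, mu_mut / mu_ref, NA_real_)
}

#' Normalized relative fitness
#'
#' Relative fitness divided by the relative fitness measured at the 0%
#' stressor condition, isolating stress-specific fitness effects; equals 1
#' at the 0% condition itself.
#'
#' @param rf relative fitness at the condition of interest.
#' @param rf_at_zero relative fitness at 0% stressor.
#' @return the ratio, or \code{NA} when \code{rf_at_zero} is zero.
#' @export
normalized_relative_fitness <- function(rf, rf_at_zero) {
  ifelse(rf_at_zero > 0, rf / rf_at_zero, NA_real_)
}

#' Percent relative inhibition
#'
#' Percent by which the reference (wild-type) strain's growth rate falls
#' short of a mutant's under a stressor.  The default convention is
#' \code{100 * (mu_mut - mu_wt) / mu_mut}: positive when the mutant outgrows
#' the wild type.  \code{convention = "wt"} divides by \code{mu_wt} instead.
#'
#' @param mu_wt wild-type growth rate (1/h).
#' @param mu_mut mutant growth rate (1/h); must be positive under the
#'   default convention.
#' @param convention denominator choice, \code{"mut"} (default) or \code{"wt"}.
#' @return percent, or \code{NA} when the denominator rate is zero.
#' @export
percent_relative_inhibition <- function(mu_wt, mu_mut, convention = c("mut", "wt")) {
  convention <- match.arg(convention)
  den <- if (convention == "mut") mu_mut else mu_wt
  ifelse(den > 0, 100 * (mu_mut - mu_wt) / den, NA_real_)
}

#' Percent improvement in tolerated stressor concentration
#'
#' @param conc_tolerated highest concentration tolerated by the evolved
#'   strain (same units as \code{conc_ref}, e.g. percent w/v).
#' @param conc_ref reference tolerated concentration; must be positive.
#' @return percent improvement, \code{100 * (conc_tolerated - conc_ref) / conc_ref}.
#' @export
tolerance_improvement <- function(conc_tolerated, conc_ref) {
  if (any(conc_ref <= 0)) stop("'conc_ref' must be positive")
  100 * (conc_tolerated - conc_ref) / conc_ref
}

#' Percent change relative to a reference value
#'
#' Used for growth-rate and final-density changes of mutants relative to the
#' parent strain.
#'
#' @param value_mut mutant value.
#' @param value_ref reference value; must be positive.
#' @return percent change.
#' @export
percent_change <- function(value_mut, value_ref) {
  if (any(value_ref <= 0)) stop("'value_ref' must be positive")
  100 * (value_mut - value_ref) / value_ref
}

#' Specific fluorescence
#'
#' Fluorescence normalized by culture density, as used in dye-accumulation
#' assays (e.g. ethidium bromide uptake as a readout of efflux-pump
#' activity).
#'
#' @param fluorescence measured fluorescence (arbitrary units).
#' @param od600 culture optical density; must be positive.
#' @return fluorescence per OD unit, or \code{NA} when \code{od600 <= 0}.
#' @export
specific_fluorescence <- function(fluorescence, od600) {
  ifelse(od600 > 0, fluorescence / od600, NA_real_)
}

#' Spectrophotometric assay parameters
#'
#' Defaults are the NADH-linked malate dehydrogenase assay constants:
#' extinction coefficient 6.22 / (mM cm) at 340 nm, 1 cm path length, and
#' 0.0045 g wet cells per reaction.
#'
#' @param epsilon_340 molar extinction coefficient, 1/(mM cm).
#' @param path_length optical path length, cm.
#' @param cell_mass g wet cells per reaction.
#' @return an object of class \code{assay_params}.
#' @export
assay_params <- function(epsilon_340 = 6.22, path_length = 1, cell_mass = 0.0045) {
  if (any(c(epsilon_340, path_length, cell_mass) <= 0))
    stop("all assay parameters must be positive")
  structure(list(epsilon_340 = epsilon_340, path_length = path_length,
                 cell_mass = cell_mass), class = "assay_params")
}

#' Malate dehydrogenase activity
#'
#' Converts a background-corrected rate of absorbance change at 340 nm
#' (NADH oxidation) into enzyme activity in units per g wet cells:
#' \code{dA340_per_min / (epsilon_340 * path_length * cell_mass)}.
#'
#' @param dA340_per_min background-corrected rate of change of A340 (AU/min).
#' @param params an \code{\link{assay_params}} object.
#' @return activity, U per g wet cells.
#' @export
mdh_activity <- function(dA340_per_min, params = assay_params()) {
  stopifnot(inherits(params, "assay_params"))
  dA340_per_min / (params$epsilon_340 * params$path_length * params$cell_mass)
}

#' Read a plate of OD600 time series
#'
#' Accepts either the long layout (columns \code{well,time_h,od600}) or the
#' wide layout (a \code{time_h} column plus one column per well).
#'
#' @param path CSV file path.
#' @param format \code{"auto"} (default), \code{"long"} or \code{"wide"}.
#' @return a long-format data frame with columns \code{well,time_h,od600}.
#' @export
read_plate_csv <- function(path, format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  is_long <- all(c("well", "time_h", "od600") %in% names(df))
  if (format == "long" || (format == "auto" && is_long)) {
    if (!is_long) stop("long format requires columns well,time_h,od600")
    return(df[, c("well", "time_h", "od600")])
  }
  if (!"time_h" %in% names(df)) stop("wide format requires a 'time_h' column")
  wells <- setdiff(names(df), "time_h")
  out <- do.call(rbind, lapply(wells, function(w)
    data.frame(well = w, time_h = df$time_h, od600 = df[[w]],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Fit growth rates for a whole plate and aggregate over replicate wells
#'
#' Fits \code{\link{fit_mu_max}} per well, subtracting either a per-well
#' blank from the plate map or the plate-level median of wells flagged as
#' blanks, then aggregates replicate wells of the same strain and condition
#' into a fitness record (mean mu_max, sample standard error, replicate
#' count).
#'
#' @param plate long-format plate data frame (\code{well,time_h,od600}).
#' @param plate_map data frame with columns \code{well,strain,condition} and
#'   optionally \code{blank} (logical flag marking medium-only wells) and/or
#'   \code{blank_value} (per-well blank absorbance).
#' @param ... passed to \code{\link{fit_mu_max}}.
#' @return a data frame with one row per strain x condition:
#'   \code{strain, condition, mu_max, se, n_wells, od_max}.
#' @export
fit_plate <- function(plate, plate_map, ...) {
  stopifnot(all(c("well", "time_h", "od600") %in% names(plate)),
            all(c("well", "strain", "condition") %in% names(plate_map)))
  blank_wells <- if ("blank" %in% names(plate_map))
    plate_map$well[isTRUE_vec(plate_map$blank)] else character()
  plate_blank <- if (length(blank_wells))
    stats::median(plate$od600[plate$well %in% blank_wells]) else 0
  wells <- setdiff(unique(plate$well), blank_wells)
  fits <- lapply(wells, function(w) {
    sub <- plate[plate$well == w, ]
    row <- match(w, plate_map$well)
    b <- if (!is.na(row) && "blank_value" %in% names(plate_map) &&
             is.finite(plate_map$blank_value[row]))
      plate_map$blank_value[row] else plate_blank
    fit_mu_max(growth_curve(sub$time_h, sub$od600, well = w, blank = b), ...)
  })
  mu <- vapply(fits, `[[`, numeric(1), "mu_max")
  odm <- vapply(fits, `[[`, numeric(1), "od_max")
  map_rows <- match(wells, plate_map$well)
  key <- interaction(plate_map$strain[map_rows], plate_map$condition[map_rows],
                     drop = TRUE, sep = "\r")
  agg <- lapply(split(seq_along(wells), key), function(i) {
    data.frame(strain = plate_map$strain[map_rows[i[1]]],
               condition = plate_map$condition[map_rows[i[1]]],
               mu_max = mean(mu[i]),
               se = if (length(i) > 1) stats::sd(mu[i]) / sqrt(length(i)) else 0,
               n_wells = length(i),
               od_max = mean(odm[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
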