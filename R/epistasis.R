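#' Canonical mutation set label
#'
#' Mutation subsets are identified by a sorted, semicolon-joined label so
#' that \code{"rph;mdh"} and \code{"mdh;rph"} name the same combination.
#'
#' @param labels character vector of mutation labels, or a single
#'   semicolon-joined string.
#' @return the canonical semicolon-joined label.
#' @export
mutation_set <- function(labels) {
  if (length(labels) == 1L) labels <- strsplit(labels, ";", fixed = TRUE)[[1]]
  labels <- trimws(labels)
  if (!length(labels) || any(!nzchar(labels))) stop("empty mutation label")
  if (anyDuplicated(labels)) stop("duplicate mutation labels in a set")
  paste(sort(labels), collapse = ";")
}

.set_members <- function(set) strsplit(set, ";", fixed = TRUE)[[1]]

#' Expected combination fitness under the multiplicative null
#'
#' Under the multiplicative fitness model the expected relative fitness of a
#' mutation combination is the product of its single-mutant relative
#' fitnesses.  The standard error is propagated to first order on the log
#' scale (delta method), assuming independent single-mutant measurements.
#'
#' @param singles named numeric vector of single-mutant relative fitness
#'   values (all positive), or a data frame with columns
#'   \code{label, w, se}.
#' @param se named numeric vector of standard errors matching
#'   \code{singles} (ignored when \code{singles} is a data frame; defaults
#'   to zero).
#' @return list with \code{expected_w} and \code{se}.  The empty set gives
#'   the empty product 1 with zero SE.
#' @export
multiplicative_expectation <- function(singles, se = NULL) {
  if (is.data.frame(singles)) {
    se <- stats::setNames(singles$se, singles$label)
    singles <- stats::setNames(singles$w, singles$label)
  }
  if (!length(singles)) return(list(expected_w = 1, se = 0))
  if (any(singles <= 0)) stop("all single-mutant fitnesses must be positive")
  if (is.null(se)) se <- stats::setNames(rep(0, length(singles)), names(singles))
  w <- prod(singles)
  # Var(log w) ~ sum (se_i / w_i)^2; back to the natural scale
  se_w <- w * sqrt(sum((se / singles)^2))
  list(expected_w = w, se = se_w)
}

#' Epistasis of one mutation combination
#'
#' Decomposes an observed combination fitness against the multiplicative
#' null: \code{epsilon = w / prod(w_i)}, reported as \code{log10(epsilon)}
#' with a confidence interval from \code{\link{epistasis_ci}}.  The sign of
#' the log-epistasis (positive = synergistic, negative = antagonistic) does
#' not depend on the log base.
#'
#' @param w observed relative fitness of the combination (positive).
#' @param singles named vector (or \code{label,w,se} data frame) of the
#'   constituent single-mutant fitnesses.
#' @param se_w standard error of \code{w}.
#' @param se named vector of single-mutant standard errors (see
#'   \code{\link{multiplicative_expectation}}).
#' @param level confidence level for the interval on \code{log10(epsilon)}.
#' @param subset optional label for the combination.
#' @return an object of class \code{epistasis_result}: list with
#'   \code{subset, w, expected_w, epsilon, log_epsilon, ci, significant}.
#' @export
epistasis <- function(w, singles, se_w = 0, se = NULL, level = 0.95,
                      subset = NULL) {
  if (w <= 0) stop("combination fitness 'w' must be positive")
  exp_w <- multiplicative_expectation(singles, se)
  eps <- w / exp_w$expected_w
  log_eps <- log10(w) - log10(exp_w$expected_w)
  ci <- epistasis_ci(w, singles, se_w = se_w, se = se, level = level)
  # guard: a zero-width interval at floating-point distance from 0 is null
  tol0 <- 1e-12
  structure(list(subset = subset, w = w, expected_w = exp_w$expected_w,
                 epsilon = eps, log_epsilon = log_eps, ci = ci,
                 significant = is.finite(ci[1]) &&
                   (ci[1] > tol0 || ci[2] < -tol0)),
            class = "epistasis_result")
}

#' Confidence interval for log10 epistasis
#'
#' \code{method = "delta"} builds a normal interval on
#' \code{log10(epsilon)} with variance
#' \code{[(se_w/w)^2 + sum((se_i/w_i)^2)] / ln(10)^2}.
#' \code{method = "bootstrap"} resamples per-replicate fitness values
#' (combination and each single) and takes percentile limits of the
#' resampled \code{log10(epsilon)}; it requires replicate-level data.
#'
#' @param w observed combination fitness.
#' @param singles named vector or \code{label,w,se} data frame of singles.
#' @param se_w standard error of \code{w}.
#' @param se named vector of single-mutant SEs.
#' @param method \code{"delta"} or \code{"bootstrap"}.
#' @param level confidence level.
#' @param replicates for the bootstrap: a list with element \code{w} (numeric
#'   vector of replicate combination fitnesses) and one numeric vector per
#'   single-mutant label.
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return numeric length-2 interval for \code{log10(epsilon)}.
#' @export
epistasis_ci <- function(w, singles, se_w = 0, se = NULL,
                         method = c("delta", "bootstrap"), level = 0.95,
                         replicates = NULL, n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  if (is.data.frame(singles)) {
    se <- stats::setNames(singles$se, singles$label)
    singles <- stats::setNames(singles$w, singles$label)
  }
  if (is.null(se)) se <- rep(0, length(singles))
  if (method == "delta") {
    log_eps <- log10(w) - sum(log10(singles))
    v <- ((se_w / w)^2 + sum((se / singles)^2)) / log(10)^2
    z <- stats::qnorm(1 - (1 - level) / 2)
    return(log_eps + c(-1, 1) * z * sqrt(v))
  }
  if (is.null(replicates) || is.null(replicates$w))
    stop("bootstrap CI requires replicate-level fitness values")
  labs <- names(singles)
  if (!all(labs %in% names(replicates)))
    stop("bootstrap CI requires replicate values for every single mutant")
  with_substream(seed, "epistasis_bootstrap", {
    boot <- vapply(seq_len(n_boot), function(b) {
      wb <- mean(sample(replicates$w, replace = TRUE))
      sb <- vapply(labs, function(l) mean(sample(replicates[[l]], replace = TRUE)),
                   numeric(1))
      if (wb <= 0 || any(sb <= 0)) return(NA_real_)
      log10(wb) - sum(log10(sb))
    }, numeric(1))
    stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                    na.rm = TRUE, names = FALSE)
  })
}

#' Scan a fitness landscape for epistasis
#'
#' Runs \code{\link{epistasis}} on every non-singleton subset of a fitness
#' table.  Singletons are reported with \code{epsilon = 1} (their own
#' fitness is the reference); subsets referencing a single mutant absent
#' from the table are flagged missing and skipped.
#'
#' @param fitness_table data frame with columns \code{subset}
#'   (semicolon-joined labels), \code{w}, and optionally \code{se}.
#' @param level confidence level for the intervals.
#' @return data frame with one row per subset: \code{subset, k, w,
#'   expected_w, epsilon, log_epsilon, ci_lo, ci_hi, significant, missing_singles}.
#' @export
landscape_scan <- function(fitness_table, level = 0.95) {
  stopifnot(all(c("subset", "w") %in% names(fitness_table)))
  if (!"se" %in% names(fitness_table)) fitness_table$se <- 0
  fitness_table$subset <- vapply(fitness_table$subset, mutation_set, character(1))
  members <- lapply(fitness_table$subset, .set_members)
  k <- lengths(members)
  singles_w <- stats::setNames(fitness_table$w[k == 1L],
                               fitness_table$subset[k == 1L])
  singles_se <- stats::setNames(fitness_table$se[k == 1L],
                                fitness_table$subset[k == 1L])
  rows <- lapply(seq_len(nrow(fitness_table)), function(i) {
    s <- fitness_table$subset[i]; m <- members[[i]]
    base <- data.frame(subset = s, k = k[i], w = fitness_table$w[i],
                       stringsAsFactors = FALSE)
    if (k[i] == 1L) {
      return(cbind(base, expected_w = fitness_table$w[i], epsilon = 1,
                   log_epsilon = 0, ci_lo = NA_real_, ci_hi = NA_real_,
                   significant = FALSE, missing_singles = FALSE))
    }
    if (!all(m %in% names(singles_w))) {
      return(cbind(base, expected_w = NA_real_, epsilon = NA_real_,
                   log_epsilon = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                   significant = FALSE, missing_singles = TRUE))
    }
    r <- epistasis(fitness_table$w[i], singles_w[m], se_w = fitness_table$se[i],
                   se = singles_se[m], level = level, subset = s)
    cbind(base, expected_w = r$expected_w, epsilon = r$epsilon,
          log_epsilon = r$log_epsilon, ci_lo = r$ci[1], ci_hi = r$ci[2],
          significant = r$significant, missing_singles = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$k > 1L, , drop = FALSE]  # singletons are the reference, not results
  rownames(out) <- NULL
  out[order(-abs(ifelse(is.na(out$log_epsilon), -Inf, out$log_epsilon))), ,
      drop = FALSE]
}
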