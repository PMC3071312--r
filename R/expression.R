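#' Array layout arithmetic
#'
#' Records the probe-level design of a spotted array: probe count,
#' technical replicates per probe, and (optionally) per-design-pass probe
#' and CDS counts.
#'
#' @param n_probes number of distinct probes.
#' @param replicates technical replicate spots per probe.
#' @param probe_gene optional data frame \code{probe, gene} mapping.
#' @param passes optional data frame with columns \code{probes, cds}
#'   (one row per design pass).
#' @return an object of class \code{array_layout}.
#' @export
array_layout <- function(n_probes, replicates, probe_gene = NULL,
                         passes = NULL) {
  if (n_probes < 1 || replicates < 1) stop("counts must be positive")
  structure(list(n_probes = as.integer(n_probes),
                 replicates = as.integer(replicates),
                 probe_gene = probe_gene, passes = passes),
            class = "array_layout")
}

#' Spot count and design summary for an array layout
#'
#' Total spots = probes x technical replicates; when per-pass counts are
#' recorded, the design summary totals probes and targeted CDSs across
#' passes and errors if the pass probe sum disagrees with the layout.
#'
#' @param layout an \code{\link{array_layout}}.
#' @return list with \code{n_spots}, \code{n_probes}, \code{replicates},
#'   and (when passes are present) \code{n_cds}.
#' @export
layout_spot_count <- function(layout) {
  stopifnot(inherits(layout, "array_layout"))
  out <- list(n_spots = layout$n_probes * layout$replicates,
              n_probes = layout$n_probes, replicates = layout$replicates)
  if (!is.null(layout$passes)) {
    if (sum(layout$passes$probes) != layout$n_probes)
      stop("per-pass probe counts do not sum to the layout probe count")
    out$n_cds <- sum(layout$passes$cds)
  }
  out
}

#' Background adjustment of spot intensities
#'
#' Subtracts the local background from the foreground intensity of each
#' spot.  Negative adjusted values are retained; the variance-stabilizing
#' transform downstream handles them.
#'
#' @param foreground numeric vector/matrix of foreground intensities.
#' @param background numeric vector/matrix of background intensities
#'   (recycled if scalar).
#' @return \code{foreground - background}.
#' @export
background_adjust <- function(foreground, background) {
  foreground - background
}

#' Generalized-log variance-stabilizing transform
#'
#' \code{glog2(x) = log2((y + sqrt(y^2 + lambda^2)) / 2)} with
#' \code{y = x - x0}: behaves like \code{log2(x)} for large intensities and
#' stays finite through zero and negative background-adjusted values.  When
#' \code{lambda} is \code{NULL} it is calibrated from the data as the
#' standard deviation of the lowest-decile intensities (the additive-noise
#' scale), with a floor of 1.
#'
#' @param x numeric vector or matrix of background-adjusted intensities.
#' @param lambda transition scale; \code{NULL} to calibrate from the data.
#' @param x0 offset subtracted before the transform.
#' @return transformed values, same shape as \code{x}; the calibrated
#'   \code{lambda} is attached as attribute \code{"lambda"}.
#' @export
glog_transform <- function(x, lambda = NULL, x0 = 0) {
  if (is.null(lambda)) {
    v <- as.numeric(x)
    low <- v[v <= stats::quantile(v, 0.1, na.rm = TRUE)]
    lambda <- max(stats::sd(low), 1)
    if (!is.finite(lambda)) lambda <- 1
  }
  if (lambda <= 0) stop("'lambda' must be positive")
  y <- x - x0
  out <- log2((y + sqrt(y^2 + lambda^2)) / 2)
  attr(out, "lambda") <- lambda
  out
}

#' Quantile normalization
#'
#' Forces every sample (column) to share the same empirical distribution:
#' each column's sorted values are replaced by the mean of sorted values
#' across columns, with ties resolved by average rank.  After the
#' transform, the sorted value vectors of all columns are identical.
#'
#' @param mat numeric matrix, rows = features, columns = samples (>= 2 for
#'   a non-trivial normalization; a single column is returned unchanged
#'   with a warning).
#' @return the normalized matrix.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) {
    warning("quantile normalization of a single sample is the identity")
    return(mat)
  }
  if (anyNA(mat)) stop("quantile normalization requires a complete matrix")
  ranks <- apply(mat, 2, rank, ties.method = "average")
  means <- rowMeans(apply(mat, 2, sort))
  # interpolate mean-quantile at (possibly fractional) average ranks
  out <- matrix(stats::approx(seq_len(nrow(mat)), means, xout = ranks,
                              rule = 2)$y,
                nrow = nrow(mat), dimnames = dimnames(mat))
  out
}

#' Normalize a background-adjusted intensity matrix
#'
#' Two sequential stages: a generalized-log variance-stabilizing transform
#' (\code{\link{glog_transform}}), then unweighted quantile normalization
#' (\code{\link{quantile_normalize}}).
#'
#' @param mat numeric matrix of background-adjusted intensities (rows =
#'   spots or probes, columns = samples).
#' @param lambda,x0 passed to \code{\link{glog_transform}}.
#' @return the normalized matrix.
#' @export
normalize_intensities <- function(mat, lambda = NULL, x0 = 0) {
  quantile_normalize(glog_transform(as.matrix(mat), lambda = lambda, x0 = x0))
}

#' Collapse technical spot replicates and apply the biological-replicate rule
#'
#' Per probe and array (sample), the expression value is the median over
#' the probe's technical replicate spots.  A probe is retained only if it
#' has acceptable signal (non-missing and at least \code{accept_min}) in at
#' least \code{min_bioreps} of the biological replicates of every
#' strain-by-condition cell; probes failing the rule are dropped and listed
#' in the \code{"dropped"} attribute.
#'
#' @param spots data frame with columns \code{probe, sample, value} (one
#'   row per spot, values on the normalized scale).
#' @param design data frame with columns \code{sample, strain, condition}
#'   (and optionally \code{replicate}).
#' @param accept_min minimum normalized value counted as acceptable signal
#'   (default \code{-Inf}: any non-missing value is acceptable).
#' @param min_bioreps required acceptable biological replicates per cell.
#' @return probe x sample numeric matrix of medians for retained probes,
#'   with attribute \code{"dropped"} (character vector of dropped probes).
#' @export
collapse_replicates <- function(spots, design, accept_min = -Inf,
                                min_bioreps = 2L) {
  stopifnot(all(c("probe", "sample", "value") %in% names(spots)),
            all(c("sample", "strain", "condition") %in% names(design)))
  probes <- sort(unique(spots$probe))
  samples <- design$sample
  med <- matrix(NA_real_, length(probes), length(samples),
                dimnames = list(probes, samples))
  agg <- tapply(spots$value,
                list(factor(spots$probe, probes),
                     factor(spots$sample, samples)),
                stats::median, na.rm = TRUE)
  med[] <- agg
  cell <- interaction(design$strain, design$condition, drop = TRUE)
  ok_cell <- sapply(levels(cell), function(cl) {
    cols <- which(cell == cl)
    rowSums(!is.na(med[, cols, drop = FALSE]) &
              med[, cols, drop = FALSE] >= accept_min) >= min_bioreps
  })
  retained <- rowSums(ok_cell) == nlevels(cell)
  out <- med[retained, , drop = FALSE]
  attr(out, "dropped") <- probes[!retained]
  out
}

#' Select one representative probe per gene
#'
#' When several probes target the same gene, keeps the probe with the
#' smallest overall variation: the sum, over strain-by-condition cells, of
#' the standard deviation across that cell's replicates.  Ties are broken
#' by lexicographic probe id.
#'
#' @param probe_matrix probe x sample matrix (rownames = probe ids).
#' @param probe_gene data frame \code{probe, gene}.
#' @param design data frame \code{sample, strain, condition} matching the
#'   matrix columns.
#' @return gene x sample matrix (rownames = gene ids); genes whose probes
#'   all dropped out are absent.
#' @export
select_probe_per_gene <- function(probe_matrix, probe_gene, design) {
  stopifnot(all(c("probe", "gene") %in% names(probe_gene)))
  cell <- interaction(design$strain, design$condition, drop = TRUE)
  sd_sum <- apply(probe_matrix, 1, function(v)
    sum(vapply(levels(cell), function(cl) {
      x <- v[cell == cl]; x <- x[!is.na(x)]
      if (length(x) > 1) stats::sd(x) else 0
    }, numeric(1))))
  map <- probe_gene[probe_gene$probe %in% rownames(probe_matrix), ]
  picked <- vapply(split(map$probe, map$gene), function(p) {
    p <- sort(p)                       # lexicographic tie-break
    p[which.min(sd_sum[p])]
  }, character(1))
  out <- probe_matrix[picked, , drop = FALSE]
  rownames(out) <- names(picked)
  out
}

#' Filter genes by intensity and variability
#'
#' Keeps genes whose value exceeds \code{intensity_min} in at least
#' \code{ceiling(frac * n_samples)} samples and whose interquartile range
#' (linear-interpolation quartiles, \code{type = 7}) exceeds
#' \code{iqr_min}.
#'
#' @param gene_matrix gene x sample matrix.
#' @param intensity_min intensity threshold (units of the normalized scale).
#' @param frac fraction of samples that must exceed the threshold.
#' @param iqr_min minimum interquartile range.
#' @return the filtered matrix.
#' @export
filter_genes <- function(gene_matrix, intensity_min = 100, frac = 0.25,
                         iqr_min = 0.5) {
  n <- ncol(gene_matrix)
  need <- ceiling(frac * n)
  hi <- rowSums(gene_matrix > intensity_min, na.rm = TRUE) >= need
  iqr <- apply(gene_matrix, 1, stats::IQR, na.rm = TRUE, type = 7)
  gene_matrix[hi & iqr > iqr_min, , drop = FALSE]
}

# Newton inversion of the trigamma function (for the prior-df moment fit).
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes prior variance from an ensemble of gene variances
#'
#' Fits a scaled-F model to the gene-wise sample variances by matching the
#' moments of \code{log(s^2)} (digamma/trigamma identities), yielding a
#' prior variance \code{s0^2} and prior degrees of freedom \code{d0} toward
#' which gene variances are shrunk.
#'
#' @param s2 numeric vector of gene-wise residual variances.
#' @param df residual degrees of freedom of each variance.
#' @return list with \code{s0_2} (prior variance) and \code{d0} (prior df,
#'   possibly \code{Inf}).
#' @export
estimate_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2)]
  if (!length(s2)) stop("no finite gene variances to fit a prior")
  if (all(s2 <= 0))
    stop("all gene variances are zero; cannot estimate a variance prior")
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- mean(e)
  vz <- mean((z - mean(z))^2) * length(z) / max(1, length(z) - 1)
  resid_var <- vz - trigamma(df / 2)
  if (resid_var > 0) {
    d0 <- 2 * .trigamma_inverse(resid_var)
    s0_2 <- exp(ev + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(ev)
  }
  list(s0_2 = s0_2, d0 = d0)
}

#' Moderated t-tests for the three study contrasts
#'
#' Per gene: cell means per strain-by-condition group, a pooled residual
#' variance over the groups entering the contrast, empirical-Bayes
#' shrinkage of that variance toward a prior estimated from all genes
#' (\code{\link{estimate_variance_prior}}), and a moderated t with
#' augmented degrees of freedom.  With \code{prior_df = 0} the statistic is
#' exactly the ordinary pooled two-sample Student t.
#'
#' Contrasts: \code{"ref_delta"} = stress vs control within the reference
#' strain; \code{"mut_delta"} = the same within the mutant strain;
#' \code{"difference"} = difference-of-differences,
#' \code{(mut_s - mut_0) - (ref_s - ref_0)}, i.e. genes whose stress
#' response differs between strains.
#'
#' @param gene_matrix gene x sample matrix on the normalized scale.
#' @param design data frame \code{sample, strain, condition}; \code{strain}
#'   and \code{condition} must each have exactly two levels.
#' @param contrast one of \code{"ref_delta"}, \code{"mut_delta"},
#'   \code{"difference"}.
#' @param ref_strain,ref_condition reference levels (defaults: first level
#'   of each factor).
#' @param prior_df prior degrees of freedom \code{d0}: \code{NULL}
#'   (default) estimates it from the variance ensemble; \code{0} disables
#'   moderation (ordinary t); \code{Inf} fully pools.
#' @param cutoff adjusted-p significance cutoff for the \code{significant}
#'   flag.
#' @return data frame \code{gene, contrast, effect, t, df, p, p_adj,
#'   significant}, sorted by p.  Genes with any missing value in a group
#'   entering the contrast are excluded and listed in attribute
#'   \code{"excluded"}.
#' @export
moderated_t_test <- function(gene_matrix, design,
                             contrast = c("ref_delta", "mut_delta", "difference"),
                             ref_strain = NULL, ref_condition = NULL,
                             prior_df = NULL, cutoff = 0.001) {
  contrast <- match.arg(contrast)
  stopifnot(all(c("sample", "strain", "condition") %in% names(design)),
            ncol(gene_matrix) == nrow(design))
  strain <- factor(design$strain); cond <- factor(design$condition)
  if (nlevels(strain) != 2 || nlevels(cond) != 2)
    stop("design must have exactly two strains and two conditions")
  if (is.null(ref_strain)) ref_strain <- levels(strain)[1]
  if (is.null(ref_condition)) ref_condition <- levels(cond)[1]
  mut_strain <- setdiff(levels(strain), ref_strain)
  stress <- setdiff(levels(cond), ref_condition)
  grp <- function(s, cc) which(strain == s & cond == cc)
  groups <- switch(contrast,
    ref_delta  = list(list(grp(ref_strain, stress), +1),
                      list(grp(ref_strain, ref_condition), -1)),
    mut_delta  = list(list(grp(mut_strain, stress), +1),
                      list(grp(mut_strain, ref_condition), -1)),
    difference = list(list(grp(mut_strain, stress), +1),
                      list(grp(mut_strain, ref_condition), -1),
                      list(grp(ref_strain, stress), -1),
                      list(grp(ref_strain, ref_condition), +1)))
  ns <- vapply(groups, function(g) length(g[[1]]), integer(1))
  if (any(ns < 2)) stop("each group entering the contrast needs >= 2 samples")
  sub <- lapply(groups, function(g) gene_matrix[, g[[1]], drop = FALSE])
  complete <- Reduce(`&`, lapply(sub, function(m) rowSums(is.na(m)) == 0))
  excluded <- rownames(gene_matrix)[!complete]
  sub <- lapply(sub, function(m) m[complete, , drop = FALSE])
  means <- vapply(sub, rowMeans, numeric(sum(complete)))
  if (!is.matrix(means)) means <- matrix(means, nrow = 1)
  signs <- vapply(groups, function(g) g[[2]], numeric(1))
  effect <- as.numeric(means %*% signs)
  ss <- Reduce(`+`, lapply(sub, function(m) rowSums((m - rowMeans(m))^2)))
  df_resid <- sum(ns - 1L)
  s2 <- ss / df_resid
  v_c <- sum(1 / ns)                       # contrast variance factor
  if (is.null(prior_df)) {
    prior <- estimate_variance_prior(s2, df_resid)
    d0 <- prior$d0; s0_2 <- prior$s0_2
  } else if (prior_df == 0) {
    d0 <- 0; s0_2 <- 0
  } else {
    prior <- estimate_variance_prior(s2, df_resid)
    d0 <- prior_df; s0_2 <- prior$s0_2
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s0_2, length(s2)); df_total <- Inf
  } else {
    s2_post <- (d0 * s0_2 + df_resid * s2) / (d0 + df_resid)
    df_total <- d0 + df_resid
  }
  tstat <- effect / sqrt(s2_post * v_c)
  p <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  res <- data.frame(gene = rownames(gene_matrix)[complete],
                    contrast = contrast, effect = effect, t = tstat,
                    df = df_total, p = p, stringsAsFactors = FALSE)
  adj <- adjust_bh(res$p, cutoff = cutoff)
  res$p_adj <- adj$p_adj
  res$significant <- adj$significant
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  attr(res, "prior") <- list(d0 = d0, s0_2 = s0_2)
  res
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up false-discovery-rate adjustment (via \code{stats::p.adjust})
#' with flags at \code{p_adj < cutoff}.
#'
#' @param p raw p-values in \code{[0, 1]}.
#' @param cutoff adjusted-p significance cutoff.
#' @return list with \code{p_adj} and logical \code{significant}.
#' @export
adjust_bh <- function(p, cutoff = 0.001) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = p_adj, significant = !is.na(p_adj) & p_adj < cutoff)
}
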