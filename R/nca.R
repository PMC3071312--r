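#' Build a connectivity matrix from gene-TF pairs
#'
#' @param pairs data frame with columns \code{gene, tf} (one row per
#'   regulatory edge, e.g. from a curated regulon database export).
#' @return binary genes x TFs matrix with dimnames.
#' @export
connectivity_matrix <- function(pairs) {
  stopifnot(all(c("gene", "tf") %in% names(pairs)))
  genes <- sort(unique(pairs$gene)); tfs <- sort(unique(pairs$tf))
  Z <- matrix(0L, length(genes), length(tfs), dimnames = list(genes, tfs))
  Z[cbind(match(pairs$gene, genes), match(pairs$tf, tfs))] <- 1L
  validate_connectivity(Z)
  Z
}

validate_connectivity <- function(Z) {
  if (any(rowSums(Z) == 0)) stop("connectivity has an unregulated (all-zero) gene row")
  if (any(colSums(Z) == 0)) stop("connectivity has a TF with an empty regulon")
  invisible(Z)
}

.generic_rank <- function(Z, seed = 42L) {
  if (!any(Z != 0)) return(0L)
  R <- matrix(0, nrow(Z), ncol(Z))
  with_substream(seed, "nca_generic_rank", {
    R[Z != 0] <- stats::runif(sum(Z != 0), 0.5, 1.5)
  })
  qr(R)$rank
}

#' Check the identifiability conditions for network component analysis
#'
#' The bilinear decomposition \code{E = A P} with \code{support(A)} fixed
#' by a connectivity matrix \code{Z} is identifiable (up to per-column
#' scaling) when (i) \code{A} has generically full column rank given its
#' support, (ii) for each TF, removing its column and every gene it
#' regulates leaves a matrix of full column rank, and (iii) the number of
#' conditions is at least the number of TFs.  Generic rank is evaluated on
#' a random filling of the support.
#'
#' @param Z binary genes x TFs connectivity matrix.
#' @param n_conditions number of expression conditions (columns of E)
#'   available to the decomposition.
#' @return list with logical \code{rank_ok}, \code{reduced_rank_ok} (named
#'   per TF), \code{conditions_ok}, and overall \code{identifiable}.
#' @export
check_identifiability <- function(Z, n_conditions) {
  validate_connectivity(Z)
  L <- ncol(Z)
  rank_ok <- .generic_rank(Z) == L
  reduced <- vapply(seq_len(L), function(j) {
    keep <- Z[, j] == 0
    sub <- Z[keep, -j, drop = FALSE]
    if (nrow(sub) < L - 1L) return(FALSE)
    .generic_rank(sub) == (L - 1L)
  }, logical(1))
  names(reduced) <- colnames(Z)
  conditions_ok <- n_conditions >= L
  list(rank_ok = rank_ok, reduced_rank_ok = reduced,
       conditions_ok = conditions_ok,
       identifiable = rank_ok && all(reduced) && conditions_ok)
}

.solve_ridge <- function(XtX, XtY, ridge) {
  out <- tryCatch(solve(XtX, XtY), error = function(e) NULL)
  if (is.null(out))
    out <- solve(XtX + diag(ridge, nrow(XtX)), XtY)
  out
}

#' Connectivity-constrained bilinear decomposition (NCA)
#'
#' Alternating least squares for \code{min ||E - A P||_F} subject to
#' \code{support(A)} contained in \code{Z}: the P-step is an unconstrained
#' least-squares solve given \code{A}; the A-step solves, for each gene,
#' a least-squares problem restricted to that gene's permitted TFs (genes
#' sharing a support pattern are solved in one block).  Iteration stops
#' when the relative residual improvement falls below \code{tol} or at
#' \code{max_iter} (the result then carries \code{converged = FALSE}).
#'
#' The intrinsic per-column scale/sign indeterminacy is resolved at exit:
#' each column of \code{A} is scaled to unit Euclidean norm with its sign
#' chosen so the largest-magnitude loading is positive, and \code{P} is
#' rescaled inversely.  Rank-deficient subproblems fall back to a ridge
#' solve with jitter \code{ridge}.
#'
#' @param E genes x samples expression matrix (rows must match \code{Z}).
#' @param Z binary genes x TFs connectivity matrix.
#' @param seed seed for the random restart initializations of \code{A}
#'   (the primary initialization is deterministic).
#' @param tol relative residual-improvement stopping tolerance.
#' @param max_iter maximum ALS iterations per start.
#' @param ridge jitter added to rank-deficient normal equations.
#' @param n_restarts additional random-initialization starts tried after
#'   the deterministic one; the lowest-residual solution wins.  Constrained
#'   ALS is biconvex, so restarts guard against local minima.
#' @param check require \code{Z} to pass \code{\link{check_identifiability}}
#'   (\code{TRUE} by default; \code{FALSE} downgrades a failure to a warning,
#'   for exploratory runs with more TFs than conditions).
#' @return an object of class \code{nca_fit}: list with \code{A}
#'   (genes x TFs, zeros off-support), \code{P} (TFs x samples),
#'   \code{residuals} (Frobenius residual trajectory of the winning start),
#'   \code{converged}, \code{iterations}, \code{seed}.
#' @export
decompose_nca <- function(E, Z, seed = 1L, tol = 1e-10, max_iter = 2000L,
                          ridge = 1e-8, n_restarts = 5L, check = TRUE) {
  E <- as.matrix(E); Z <- as.matrix(Z)
  if (nrow(E) != nrow(Z)) stop("rows of E must match rows of Z")
  validate_connectivity(Z)
  id <- check_identifiability(Z, ncol(E))
  if (!id$identifiable) {
    msg <- "connectivity fails the NCA identifiability conditions"
    if (check) stop(msg, "; pass check = FALSE to force an exploratory fit")
    warning(msg, "; the fit is exploratory and columns may be confounded")
  }
  L <- ncol(Z)
  pattern <- apply(Z != 0, 1, function(r) paste(which(r), collapse = ","))
  blocks <- split(seq_len(nrow(Z)), pattern)
  run_als <- function(A) {
    res <- numeric(0)
    prev <- Inf
    converged <- FALSE
    P <- NULL
    for (it in seq_len(max_iter)) {
      P <- .solve_ridge(crossprod(A), crossprod(A, E), ridge)
      for (b in seq_along(blocks)) {
        rows <- blocks[[b]]
        tfs <- which(Z[rows[1], ] != 0)
        Ps <- P[tfs, , drop = FALSE]
        sol <- .solve_ridge(tcrossprod(Ps),
                            tcrossprod(Ps, E[rows, , drop = FALSE]), ridge)
        A[rows, ] <- 0
        A[rows, tfs] <- t(sol)
      }
      r <- sqrt(sum((E - A %*% P)^2))
      res <- c(res, r)
      if (is.finite(prev) && (prev - r) < tol * max(prev, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
      prev <- r
    }
    list(A = A, P = P, res = res, converged = converged)
  }
  empty_A <- matrix(0, nrow(Z), L, dimnames = list(rownames(Z), colnames(Z)))
  # deterministic primary start: principal-subspace loadings masked to the
  # support -- lands in the global basin on identifiable instances
  sv <- svd(E, nu = min(L, ncol(E)), nv = 0)
  A0 <- empty_A
  proj <- sv$u %*% diag(sv$d[seq_len(ncol(sv$u))], ncol(sv$u))
  k <- min(L, ncol(proj))
  A0[, seq_len(k)] <- proj[, seq_len(k)]
  A0[Z == 0] <- 0
  A0[Z != 0 & A0 == 0] <- 1e-3  # keep the support fully populated
  starts <- list(A0)
  if (n_restarts > 0) {
    starts <- c(starts, with_substream(seed, "nca_init", {
      lapply(seq_len(n_restarts), function(i) {
        A <- empty_A
        A[Z != 0] <- stats::rnorm(sum(Z != 0))
        A
      })
    }))
  }
  best <- NULL
  for (A_start in starts) {
    fit <- run_als(A_start)
    if (is.null(best) || min(fit$res) < min(best$res)) best <- fit
    if (min(fit$res) <= tol * sqrt(sum(E^2))) break  # essentially exact
  }
  A <- best$A; P <- best$P; res <- best$res; converged <- best$converged
  if (!converged)
    warning("NCA did not converge in ", max_iter, " iterations")
  # scale/sign convention: unit-norm A columns, dominant loading positive
  for (j in seq_len(L)) {
    nrm <- sqrt(sum(A[, j]^2))
    if (nrm > 0) {
      sgn <- sign(A[which.max(abs(A[, j])), j])
      if (sgn == 0) sgn <- 1
      A[, j] <- A[, j] / (nrm * sgn)
      P[j, ] <- P[j, ] * (nrm * sgn)
    }
  }
  dimnames(P) <- list(colnames(Z), colnames(E))
  structure(list(A = A, P = P, residuals = res, converged = converged,
                 iterations = length(res), seed = seed),
            class = "nca_fit")
}

#' @export
print.nca_fit <- function(x, ...) {
  cat(sprintf("NCA fit: %d genes x %d TFs x %d samples; %d iterations, final residual %.3e%s\n",
              nrow(x$A), ncol(x$A), ncol(x$P), x$iterations,
              x$residuals[length(x$residuals)],
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Mean and t-based 95% confidence interval across replicates
#'
#' @param x numeric vector of per-replicate activities (length >= 2 for a
#'   defined interval; a single replicate returns an undefined, flagged CI).
#' @param level confidence level.
#' @return list with \code{mean, lo, hi, n, undefined}.
#' @export
activity_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) stop("no finite replicate values")
  m <- mean(x)
  if (n < 2)
    return(list(mean = m, lo = NA_real_, hi = NA_real_, n = n, undefined = TRUE))
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
  list(mean = m, lo = m - half, hi = m + half, n = n, undefined = FALSE)
}

#' TF-subset consensus over repeated small NCA runs
#'
#' With few conditions, only a handful of TFs can be decomposed at once, so
#' the analysis is repeated over subsets of \code{subset_size} TFs and a TF
#' is trusted only when its behaviour is consistent across the subsets that
#' contain it.  For every identifiable subset, the expression matrix is
#' restricted to genes regulated by at least one member TF and decomposed;
#' the TF's activity contrast between the two sample groups is recorded.
#'
#' A TF is \emph{retained} when (a) the sign of its contrast agrees across
#' at least \code{sign_threshold} of its subsets and (b) its median
#' absolute contrast is significant against a group-label permutation
#' null: the group labels are reassigned over all balanced splits of the
#' samples (enumerated exhaustively when there are at most
#' \code{max_exact_perms} splits, else a seeded random sample plus the
#' observed split) and the TF's own median absolute contrast is
#' recomputed for each; the permutation p-value is compared against
#' \code{level} Bonferroni-divided by the number of TFs, so the level is
#' family-wise across the panel.
#'
#' By default each subset's decomposition uses only genes whose regulators
#' all belong to the subset (\code{gene_rule = "exclusive"}): genes with an
#' out-of-subset regulator carry signal the subset model cannot express,
#' which otherwise leaks into the member TFs' activities.
#' \code{gene_rule = "any"} keeps every gene regulated by at least one
#' member TF.  To make contrast signs comparable across subsets, each TF's
#' activity row is sign-anchored to the loading of a fixed reference gene
#' (its highest-signal single-regulator gene, present in every subset that
#' contains the TF).
#'
#' @param E genes x samples expression matrix.
#' @param Z binary genes x TFs connectivity over the full TF panel.
#' @param groups factor of length \code{ncol(E)} with two levels defining
#'   the activity contrast (e.g. strain, or stress exposure).
#' @param subset_size TFs per decomposition (at most the number of samples).
#' @param max_subsets subsets are enumerated exhaustively when their count
#'   is at most this cap, otherwise a seeded random sample of this size is
#'   drawn.
#' @param n_perm random label splits drawn when exhaustive enumeration is
#'   not feasible.
#' @param max_exact_perms label splits are enumerated exhaustively up to
#'   this count.
#' @param sign_threshold required sign-consistency fraction.
#' @param level family-wise significance level of the permutation test.
#' @param gene_rule \code{"exclusive"} (default) or \code{"any"}; see above.
#' @param seed seed controlling subset sampling, decomposition inits and
#'   permutations.
#' @param ... passed to \code{\link{decompose_nca}} (defaults here favour
#'   speed: \code{tol = 1e-8}, \code{max_iter = 500}, \code{n_restarts = 0}).
#' @return an object of class \code{consensus_report}: data frame with one
#'   row per TF: \code{tf, n_subsets, median_abs_contrast, sign_consistency,
#'   p_perm, significant, retained, unevaluable}; the per-subset
#'   activity table is attached as attribute \code{"activities"}.
#' @export
subset_consensus <- function(E, Z, groups, subset_size = 4L,
                             max_subsets = 60L, n_perm = 1999L,
                             max_exact_perms = 20000L,
                             sign_threshold = 0.8, level = 0.05,
                             gene_rule = c("exclusive", "any"),
                             seed = 1L, ...) {
  gene_rule <- match.arg(gene_rule)
  E <- as.matrix(E); Z <- as.matrix(Z)
  groups <- factor(groups)
  stopifnot(length(groups) == ncol(E), nlevels(groups) == 2)
  if (subset_size > ncol(E))
    stop("'subset_size' may not exceed the number of samples")
  tfs <- colnames(Z)
  L <- length(tfs)
  dots <- list(...)
  if (is.null(dots$tol)) dots$tol <- 1e-8
  if (is.null(dots$max_iter)) dots$max_iter <- 500L
  if (is.null(dots$n_restarts)) dots$n_restarts <- 0L
  all_subsets <- utils::combn(L, subset_size, simplify = FALSE)
  if (length(all_subsets) > max_subsets) {
    all_subsets <- with_substream(seed, "consensus_subsets",
                                  sample(all_subsets, max_subsets))
  }
  # per-TF sign anchor: its single-regulator gene with the largest signal
  row_sig <- rowSums(E^2)
  anchor <- vapply(seq_len(L), function(j) {
    cand <- which(Z[, j] != 0 & rowSums(Z) == 1)
    if (!length(cand)) NA_integer_ else cand[which.max(row_sig[cand])]
  }, integer(1))
  act_rows <- list()
  n_unconverged <- 0L
  for (si in seq_along(all_subsets)) {
    js <- all_subsets[[si]]
    genes <- if (gene_rule == "exclusive")
      which(rowSums(Z[, js, drop = FALSE]) > 0 &
              rowSums(Z[, -js, drop = FALSE]) == 0)
    else which(rowSums(Z[, js, drop = FALSE]) > 0)
    if (length(genes) < length(js)) next
    Zs <- Z[genes, js, drop = FALSE]
    if (any(colSums(Zs) == 0)) next
    idc <- check_identifiability(Zs, ncol(E))
    if (!idc$identifiable) next
    fit <- withCallingHandlers(
      do.call(decompose_nca,
              c(list(E = E[genes, , drop = FALSE], Z = Zs,
                     seed = substream_seed(seed, paste0("sub", si)),
                     check = FALSE), dots)),
      warning = function(w) {
        # per-subset convergence is tracked on the fit objects; a warning
        # per subset would swamp the consensus run
        if (grepl("did not converge", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    n_unconverged <- n_unconverged + !fit$converged
    for (k in seq_along(js)) {
      j <- js[k]
      p_row <- fit$P[k, ]
      if (!is.na(anchor[j])) {
        gi <- match(anchor[j], genes)
        if (!is.na(gi) && is.finite(fit$A[gi, k]) && fit$A[gi, k] != 0 &&
            fit$A[gi, k] < 0)
          p_row <- -p_row
      }
      act_rows[[length(act_rows) + 1L]] <- c(subset = si, tf = j, p_row)
    }
  }
  gA <- groups == levels(groups)[1]
  if (!length(act_rows)) stop("no identifiable TF subset could be decomposed")
  act <- do.call(rbind, act_rows)
  actmat <- act[, -(1:2), drop = FALSE]
  tf_id <- act[, "tf"]
  n <- ncol(actmat)
  nA <- sum(gA)
  # contrast weights for the observed split and every permuted split
  wt_of <- function(selA) {
    w <- rep(1 / (n - nA), n); w[selA] <- -1 / nA; w
  }
  n_splits <- choose(n, nA)
  splits <- if (n_splits <= max_exact_perms) {
    utils::combn(n, nA, simplify = FALSE)
  } else {
    c(list(which(gA)), with_substream(seed, "consensus_perm",
      lapply(seq_len(n_perm), function(b) sample.int(n, nA))))
  }
  W <- vapply(splits, wt_of, numeric(n))
  C <- actmat %*% W                       # (subset x TF) rows over splits
  obs_con <- as.numeric(actmat %*% wt_of(which(gA)))
  med_abs <- vapply(seq_len(L), function(j) {
    v <- obs_con[tf_id == j]
    if (!length(v)) NA_real_ else stats::median(abs(v))
  }, numeric(1))
  sign_cons <- vapply(seq_len(L), function(j) {
    v <- obs_con[tf_id == j]
    if (!length(v)) return(NA_real_)
    max(mean(v > 0), mean(v < 0))
  }, numeric(1))
  p_perm <- vapply(seq_len(L), function(j) {
    rows <- tf_id == j
    if (!any(rows)) return(NA_real_)
    stat <- apply(abs(C[rows, , drop = FALSE]), 2, stats::median)
    mean(stat >= med_abs[j] - 1e-12)
  }, numeric(1))
  n_sub <- vapply(seq_len(L), function(j) sum(tf_id == j), integer(1))
  out <- data.frame(tf = tfs, n_subsets = n_sub,
                    median_abs_contrast = med_abs,
                    sign_consistency = sign_cons,
                    p_perm = p_perm,
                    significant = !is.na(p_perm) & p_perm <= level / L,
                    stringsAsFactors = FALSE)
  out$retained <- out$significant & !is.na(out$sign_consistency) &
    out$sign_consistency >= sign_threshold
  out$unevaluable <- out$n_subsets == 0L
  attr(out, "activities") <- act
  attr(out, "n_unconverged") <- n_unconverged
  class(out) <- c("consensus_report", class(out))
  out
}
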