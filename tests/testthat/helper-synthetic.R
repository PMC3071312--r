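# Shared builders for synthetic study designs used across test files.

# A 16-TF panel instance mirroring the expression study design:
# 4 conditions (2 strains x 2 isobutanol levels) x 3 biological replicates,
# with the first `n_changing` TFs planted to differ between strains.
make_consensus_instance <- function(seed, n_genes = 400, n_tfs = 16,
                                    n_changing = 4, effect = 3,
                                    noise = 0.05) {
  tfs <- paste0("TF", seq_len(n_tfs))
  Z <- gen_connectivity(n_genes, tfs, cfg = sim_config(seed = seed))
  P <- matrix(1, n_tfs, 4,
              dimnames = list(tfs, c("WT_0", "WT_0.5", "MUT_0", "MUT_0.5")))
  if (n_changing > 0)
    P[seq_len(n_changing), c(3, 4)] <- 1 + effect
  d <- gen_expression_dataset(Z, P, sim_config(seed = seed + 500,
                                               noise_sd = noise))
  list(Z = Z, P = P, E = d$truth$E, design = d$design,
       groups = factor(d$design$strain),
       changing = tfs[seq_len(n_changing)])
}

# A small identifiable NCA instance with dense planted activities.
make_nca_instance <- function(seed, n_genes = 200, n_tfs = 4,
                              n_conditions = 4, n_bioreps = 3,
                              noise = 0) {
  tfs <- paste0("TF", seq_len(n_tfs))
  Z <- gen_connectivity(n_genes, tfs, cfg = sim_config(seed = seed))
  P <- with_substream(seed + 1000, "test_planted_P",
                      matrix(stats::rnorm(n_tfs * n_conditions), n_tfs,
                             dimnames = list(tfs,
                                             paste0("c", seq_len(n_conditions)))))
  d <- gen_expression_dataset(Z, P, sim_config(seed = seed, noise_sd = noise),
                              n_bioreps = n_bioreps)
  list(Z = Z, P = P, E = d$truth$E, n_bioreps = n_bioreps)
}

# Scale/sign-invariant recovery score: per planted TF, |cor| between the
# recovered activity row and the planted activities expanded to replicates.
nca_recovery_r <- function(fit, P, n_bioreps) {
  vapply(seq_len(nrow(P)), function(j)
    abs(stats::cor(fit$P[j, ], rep(P[j, ], each = n_bioreps))), numeric(1))
}

# Independent brute-force scan for the best log-slope window, using plain
# per-window covariance formulas (no prefix sums).
oracle_mu_window <- function(time_h, od, blank, min_points, min_r2, floor,
                             max_points = Inf) {
  y_all <- od - blank
  usable <- is.finite(y_all) & y_all > floor
  idx <- which(usable)
  best <- list(mu = -Inf, window = c(NA, NA))
  if (length(idx) < min_points) return(list(mu = 0, window = c(NA, NA)))
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  for (run in runs) {
    n <- length(run)
    if (n < min_points) next
    for (w in min_points:min(n, max_points)) {
      for (s in 1:(n - w + 1L)) {
        ii <- run[s:(s + w - 1L)]
        t <- time_h[ii]; y <- log(y_all[ii])
        slope <- stats::cov(t, y) / stats::var(t)
        r2 <- if (stats::var(y) <= 0) 0 else stats::cor(t, y)^2
        if (r2 >= min_r2 && slope > best$mu)
          best <- list(mu = slope, window = c(ii[1], ii[w]))
      }
    }
  }
  if (!is.finite(best$mu)) list(mu = 0, window = c(NA, NA)) else best
}
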