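#' Generate a synthetic microplate growth experiment
#'
#' Emulates a 48-hour microplate run read every 10 minutes (289 time
#' points per well by default).  Each well follows a three-phase curve --
#' flat lag at the inoculum density, pure exponential growth at the
#' planted rate, then logistic saturation toward the carrying capacity --
#' plus a constant blank offset and additive Gaussian read noise.  The
#' pure-exponential segment makes the planted rate an exact in-window
#' ln-slope, so downstream rate estimation has an exact target.
#' Designated blank wells contain only the offset and noise.
#'
#' @param truth data frame with one row per well: \code{well, mu} (1/h,
#'   > 0), and optionally \code{lag_h} (default 2), \code{capacity}
#'   (default 1.0, must exceed \code{od0}), \code{od0} (default 0.002),
#'   \code{strain}, \code{condition}.
#' @param cfg a \code{\link{sim_config}}; \code{cfg$noise_sd} is the OD
#'   read noise (absorbance units).
#' @param t_end_h,dt_min run length (h) and read interval (min).
#' @param blank_offset constant absorbance of medium + plate.
#' @param n_blank_wells number of medium-only wells appended to the plate.
#' @return list with \code{plate} (long data frame \code{well, time_h,
#'   od600}), \code{map} (well annotations incl. \code{blank} flag), and
#'   \code{truth} (the input truth, untouched).
#' @export
gen_growth_plate <- function(truth, cfg = sim_config(), t_end_h = 48,
                             dt_min = 10, blank_offset = 0.04,
                             n_blank_wells = 3L) {
  stopifnot(is.data.frame(truth), all(c("well", "mu") %in% names(truth)))
  if (!"lag_h" %in% names(truth)) truth$lag_h <- 2
  if (!"capacity" %in% names(truth)) truth$capacity <- 1.0
  if (!"od0" %in% names(truth)) truth$od0 <- 0.002
  if (any(truth$mu <= 0)) stop("planted growth rates must be positive")
  if (any(truth$capacity <= 0)) stop("capacity must be positive")
  if (any(truth$capacity <= truth$od0)) stop("capacity must exceed the inoculum OD")
  if (t_end_h < 0 || dt_min <= 0) stop("negative times are not allowed")
  time_h <- seq(0, t_end_h, by = dt_min / 60)
  with_substream(cfg$seed, "growth_plate", {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      mu <- truth$mu[i]; lag <- truth$lag_h[i]
      K <- truth$capacity[i]; od0 <- truth$od0[i]
      t_sat <- lag + log(K / (2 * od0)) / mu   # exponential reaches K/2 here
      od <- ifelse(time_h < lag, od0,
            ifelse(time_h < t_sat, od0 * exp(mu * (time_h - lag)),
                   K / (1 + exp(-mu * (time_h - t_sat)))))
      noise <- if (cfg$noise_sd > 0)
        stats::rnorm(length(time_h), 0, cfg$noise_sd) else 0
      data.frame(well = truth$well[i], time_h = time_h,
                 od600 = od + blank_offset + noise, stringsAsFactors = FALSE)
    })
    blanks <- lapply(seq_len(n_blank_wells), function(i) {
      noise <- if (cfg$noise_sd > 0)
        stats::rnorm(length(time_h), 0, cfg$noise_sd) else 0
      data.frame(well = sprintf("BLK%d", i), time_h = time_h,
                 od600 = blank_offset + noise, stringsAsFactors = FALSE)
    })
    plate <- do.call(rbind, c(rows, blanks))
    map <- data.frame(
      well = c(truth$well, sprintf("BLK%d", seq_len(n_blank_wells))),
      strain = c(if ("strain" %in% names(truth)) truth$strain
                 else rep(NA_character_, nrow(truth)),
                 rep(NA_character_, n_blank_wells)),
      condition = c(if ("condition" %in% names(truth)) truth$condition
                    else rep(NA_character_, nrow(truth)),
                    rep(NA_character_, n_blank_wells)),
      blank = c(rep(FALSE, nrow(truth)), rep(TRUE, n_blank_wells)),
      stringsAsFactors = FALSE)
    list(plate = plate, map = map, truth = truth)
  })
}

#' Generate a combinatorial fitness landscape with planted epistasis
#'
#' Emits every nonempty subset of up to \code{K} single mutants with
#' relative fitness \code{eps_S * prod(w_i)} -- the multiplicative null
#' times a planted epistasis factor -- perturbed by multiplicative
#' lognormal noise of log-scale SD \code{cfg$noise_sd}.
#'
#' @param singles named numeric vector of single-mutant relative fitnesses
#'   (all positive; K = length, at most 12).
#' @param planted_eps named numeric vector of epistasis factors keyed by
#'   canonical subset label (see \code{\link{mutation_set}}); subsets not
#'   named default to 1 (no epistasis).  All factors must be positive.
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{fitness} (data frame \code{subset, k, w, se})
#'   and \code{truth} (data frame \code{subset, eps, w_true}).
#' @export
gen_fitness_landscape <- function(singles, planted_eps = NULL,
                                  cfg = sim_config()) {
  K <- length(singles)
  if (K > 12) stop("landscapes beyond K = 12 mutations are not supported")
  if (K < 1) stop("need at least one single mutant")
  if (any(singles <= 0)) stop("single-mutant fitnesses must be positive")
  if (is.null(names(singles)) || any(!nzchar(names(singles))))
    stop("'singles' must be a named vector")
  if (!is.null(planted_eps)) {
    if (any(planted_eps <= 0)) stop("epistasis factors must be positive")
    names(planted_eps) <- vapply(names(planted_eps), mutation_set, character(1))
  }
  subsets <- unlist(lapply(seq_len(K), function(k)
    utils::combn(names(singles), k, simplify = FALSE)), recursive = FALSE)
  labels <- vapply(subsets, function(s) mutation_set(s), character(1))
  eps <- rep(1, length(labels))
  if (!is.null(planted_eps)) {
    hit <- match(names(planted_eps), labels)
    if (anyNA(hit)) stop("planted_eps names a subset outside the landscape")
    eps[hit] <- planted_eps
  }
  w_true <- eps * vapply(subsets, function(s) prod(singles[s]), numeric(1))
  with_substream(cfg$seed, "fitness_landscape", {
    noise <- if (cfg$noise_sd > 0)
      exp(stats::rnorm(length(w_true), 0, cfg$noise_sd)) else 1
    w <- w_true * noise
    fitness <- data.frame(subset = labels, k = lengths(subsets), w = w,
                          se = w * cfg$noise_sd, stringsAsFactors = FALSE)
    truth <- data.frame(subset = labels, eps = eps, w_true = w_true,
                        stringsAsFactors = FALSE)
    list(fitness = fitness, truth = truth)
  })
}

#' Sample a sparse, NCA-identifiable gene-TF connectivity
#'
#' Draws a per-gene regulator count in \code{1..max_regulators} from a
#' truncated geometric distribution calibrated so the mean count equals
#' \code{mean_regulators}, then assigns regulators uniformly.  With
#' \code{identifiable = TRUE}, draws are rejected until the matrix passes
#' \code{\link{check_identifiability}} at \code{n_conditions}.
#'
#' @param n_genes number of genes.
#' @param tfs character vector of TF names.
#' @param mean_regulators target mean regulators per gene (default 1.5).
#' @param max_regulators largest regulator count per gene (default 5).
#' @param identifiable reject draws failing the identifiability criteria.
#' @param n_conditions condition count used for the identifiability check.
#' @param cfg a \code{\link{sim_config}}.
#' @param max_tries rejection-sampling cap.
#' @return binary genes x TFs matrix.
#' @export
gen_connectivity <- function(n_genes, tfs, mean_regulators = 1.5,
                             max_regulators = 5L, identifiable = TRUE,
                             n_conditions = length(tfs),
                             cfg = sim_config(), max_tries = 200L) {
  L <- length(tfs)
  if (mean_regulators < 1 || mean_regulators > max_regulators)
    stop("'mean_regulators' must lie in [1, max_regulators]")
  kk <- seq_len(min(max_regulators, L))
  # truncated geometric p(c) ~ r^(c-1) with mean mean_regulators
  probs <- if (mean_regulators == 1) c(1, rep(0, length(kk) - 1L)) else {
    f <- function(r) sum(kk * r^(kk - 1)) / sum(r^(kk - 1)) - mean_regulators
    r <- stats::uniroot(f, c(1e-8, 1 - 1e-8), tol = 1e-12)$root
    r^(kk - 1) / sum(r^(kk - 1))
  }
  with_substream(cfg$seed, "connectivity", {
    for (try in seq_len(max_tries)) {
      counts <- sample(kk, n_genes, replace = TRUE, prob = probs)
      Z <- matrix(0L, n_genes, L,
                  dimnames = list(sprintf("g%04d", seq_len(n_genes)), tfs))
      for (i in seq_len(n_genes))
        Z[i, sample.int(L, counts[i])] <- 1L
      if (any(colSums(Z) == 0)) next
      if (!identifiable) return(Z)
      if (check_identifiability(Z, n_conditions)$identifiable) return(Z)
    }
    stop("could not draw an identifiable connectivity in ", max_tries, " tries")
  })
}

#' Generate a spot-level expression dataset from planted TF activities
#'
#' Builds gene-level log-scale expression \code{E = A P} with loadings
#' \code{A} drawn with support exactly on the nonzeros of \code{Z} and the
#' planted activity matrix \code{P} (one row per TF, one column per
#' condition), expands each condition to \code{n_bioreps} biological
#' replicates (adding replicate noise of SD \code{cfg$noise_sd}) and each
#' probe to \code{n_tech} technical replicate spots with a constant
#' background offset (plus spot noise of SD \code{spot_noise_sd}).
#'
#' @param Z binary genes x TFs connectivity; no all-zero gene rows.
#' @param P TF activity matrix, rows = TFs of \code{Z}, columns =
#'   conditions.
#' @param cfg a \code{\link{sim_config}}; \code{cfg$noise_sd} is the
#'   biological-replicate noise on the log scale.
#' @param n_bioreps biological replicates per condition.
#' @param n_tech technical replicate spots per probe per array.
#' @param background constant background intensity added to every spot.
#' @param spot_noise_sd technical spot noise SD.
#' @return list with \code{spots} (data frame \code{spot, probe, sample,
#'   foreground, background}), \code{design} (\code{sample, strain,
#'   condition, replicate} -- \code{strain}/\code{condition} split from
#'   the column names of \code{P} when they contain "_", else condition =
#'   column name), \code{probe_gene} map, and \code{truth} (list with
#'   \code{A}, \code{P}, \code{E}).
#' @export
gen_expression_dataset <- function(Z, P, cfg = sim_config(), n_bioreps = 3L,
                                   n_tech = 6L, background = 50,
                                   spot_noise_sd = 0) {
  Z <- as.matrix(Z); P <- as.matrix(P)
  if (any(rowSums(Z) == 0)) stop("connectivity has an all-zero gene row")
  if (nrow(P) != ncol(Z)) stop("P must have one row per TF of Z")
  genes <- rownames(Z)
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(nrow(Z)))
  conds <- colnames(P)
  if (is.null(conds)) conds <- sprintf("c%d", seq_len(ncol(P)))
  with_substream(cfg$seed, "expression", {
    A <- matrix(0, nrow(Z), ncol(Z), dimnames = list(genes, colnames(Z)))
    A[Z != 0] <- stats::rnorm(sum(Z != 0), 0, 1)
    E <- A %*% P
    samples <- as.vector(t(outer(conds, seq_len(n_bioreps),
                                 function(cc, r) paste0(cc, ".r", r))))
    Emat <- matrix(NA_real_, nrow(Z), length(samples),
                   dimnames = list(genes, samples))
    j <- 0L
    for (cc in seq_along(conds)) for (r in seq_len(n_bioreps)) {
      j <- j + 1L
      noise <- if (cfg$noise_sd > 0)
        stats::rnorm(nrow(Z), 0, cfg$noise_sd) else 0
      Emat[, j] <- E[, cc] + noise
    }
    probes <- paste0(genes, "_p1")
    spot_rows <- expand.grid(tech = seq_len(n_tech), probe = probes,
                             sample = samples, stringsAsFactors = FALSE)
    gi <- match(sub("_p1$", "", spot_rows$probe), genes)
    si <- match(spot_rows$sample, samples)
    val <- Emat[cbind(gi, si)]
    spot_noise <- if (spot_noise_sd > 0)
      stats::rnorm(nrow(spot_rows), 0, spot_noise_sd) else 0
    spots <- data.frame(
      spot = sprintf("%s.%s.s%d", spot_rows$probe, spot_rows$sample,
                     spot_rows$tech),
      probe = spot_rows$probe, sample = spot_rows$sample,
      foreground = val + background + spot_noise,
      background = background, stringsAsFactors = FALSE)
    cond_of <- sub("\\.r[0-9]+$", "", samples)
    has_strain <- all(grepl("_", cond_of))
    design <- data.frame(
      sample = samples,
      strain = if (has_strain) sub("_.*$", "", cond_of) else "S1",
      condition = if (has_strain) sub("^[^_]*_", "", cond_of) else cond_of,
      replicate = as.integer(sub("^.*\\.r", "", samples)),
      stringsAsFactors = FALSE)
    list(spots = spots,
         design = design,
         probe_gene = data.frame(probe = probes, gene = genes,
                                 stringsAsFactors = FALSE),
         truth = list(A = A, P = P, E = Emat))
  })
}

#' Generate allele-state trajectories with staggered fixation
#'
#' Each locus is wild type before its sweep starts, \code{Mixed} while the
#' sweep is under way, and \code{Mut} from its fixation generation on,
#' evaluated exactly at the sampled generations.  A sweep width of zero
#' flips the locus from WT to Mut between adjacent samples.
#'
#' @param loci data frame with columns \code{locus, fix_gen} and
#'   optionally \code{sweep_width} (generations; default 0).
#' @param sampled_generations increasing vector of genotyped generations.
#' @return data frame \code{locus, generation, state} (one row per locus
#'   per sampled generation).
#' @export
gen_allele_trajectories <- function(loci, sampled_generations) {
  stopifnot(all(c("locus", "fix_gen") %in% names(loci)))
  if (any(diff(sampled_generations) <= 0))
    stop("'sampled_generations' must be strictly increasing")
  if (!"sweep_width" %in% names(loci)) loci$sweep_width <- 0
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    start <- loci$fix_gen[i] - loci$sweep_width[i]
    state <- ifelse(sampled_generations < start, "WT",
             ifelse(sampled_generations < loci$fix_gen[i], "Mixed", "Mut"))
    data.frame(locus = loci$locus[i], generation = sampled_generations,
               state = state, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate qPCR amplification curves from planted MAK2 parameters
#'
#' Delegates to \code{\link{mak2_forward}}, clamps at the plateau and adds
#' additive Gaussian fluorescence noise.
#'
#' @param params data frame with columns \code{id, well, d0, k} and
#'   optionally \code{plateau} (default \code{Inf}, no clamp).
#' @param cfg a \code{\link{sim_config}}; \code{cfg$noise_sd} in
#'   fluorescence units.
#' @param n_cycles cycles per curve (default 45).
#' @return data frame \code{id, well, cycle, fluorescence}.
#' @export
gen_amplification_curves <- function(params, cfg = sim_config(),
                                     n_cycles = 45L) {
  stopifnot(all(c("id", "well", "d0", "k") %in% names(params)))
  if (any(params$k <= 0)) stop("'k' must be positive")
  if (any(params$d0 < 0)) stop("'d0' must be nonnegative")
  if (!"plateau" %in% names(params)) params$plateau <- Inf
  with_substream(cfg$seed, "qpcr_curves", {
    rows <- lapply(seq_len(nrow(params)), function(i) {
      f <- pmin(mak2_forward(params$d0[i], params$k[i], n_cycles),
                params$plateau[i])
      noise <- if (cfg$noise_sd > 0)
        stats::rnorm(n_cycles, 0, cfg$noise_sd) else 0
      data.frame(id = params$id[i], well = params$well[i],
                 cycle = seq_len(n_cycles), fluorescence = f + noise,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a variant-triage test set: candidates, coverage, reads
#'
#' Plants \code{n_true} variant candidates with quality/frequency above
#' the triage thresholds and \code{n_decoy} below them; a coverage track
#' with planted zero-depth intervals (candidate deletions) on an otherwise
#' uniform-depth genome; and a read set in which a chosen subset of reads
#' carries a long homopolymer run.
#'
#' @param n_true,n_decoy counts of true and decoy candidates (each half
#'   SNPs, half indels, alternating).
#' @param genome_length genome length in bp (all coordinates below it).
#' @param gap_intervals data frame \code{start, end} (0-based half-open)
#'   of planted zero-coverage intervals; must not overlap.
#' @param mean_depth depth outside the gaps.
#' @param n_reads total reads; \code{n_homopolymer} of them receive a run
#'   of \code{homopolymer_run} identical bases.
#' @param read_length read length in bases.
#' @param homopolymer_run planted run length (must exceed the downstream
#'   filter's limit to be caught).
#' @param n_homopolymer number of reads carrying the planted run.
#' @param snp_quality_min,indel_freq_min the triage thresholds the planted
#'   candidates straddle.
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{candidates} (\code{coordinate, class, quality,
#'   frequency, true}), \code{coverage} (bedGraph-like \code{start, end,
#'   depth}), \code{reads} (named character vector; names of planted
#'   homopolymer reads carry suffix \code{"_hp"}), and \code{truth}.
#' @export
gen_variant_candidates <- function(n_true = 5L, n_decoy = 5L,
                                   genome_length = 4650000L,
                                   gap_intervals = data.frame(start = 100000,
                                                              end = 109900),
                                   mean_depth = 125L,
                                   n_reads = 10L, read_length = 36L,
                                   homopolymer_run = 15L,
                                   n_homopolymer = 3L,
                                   snp_quality_min = 150,
                                   indel_freq_min = 0.4,
                                   cfg = sim_config()) {
  if (nrow(gap_intervals)) {
    gi <- gap_intervals[order(gap_intervals$start), , drop = FALSE]
    if (any(gi$end <= gi$start)) stop("gap intervals must satisfy end > start")
    if (any(gi$start[-1] < gi$end[-nrow(gi)]))
      stop("planted deletions must not overlap")
    if (any(gi$end > genome_length)) stop("gap interval beyond genome length")
    gap_intervals <- gi
  }
  with_substream(cfg$seed, "variants", {
    mk <- function(n, true) {
      if (n == 0) return(NULL)
      cls <- rep(c("SNP", "indel"), length.out = n)
      data.frame(
        coordinate = sample.int(genome_length, n),
        class = cls,
        quality = ifelse(cls == "SNP",
                         if (true) stats::runif(n, snp_quality_min + 50, 999)
                         else stats::runif(n, 10, snp_quality_min - 10),
                         round(stats::runif(n, 30, 60))),
        frequency = ifelse(cls == "indel",
                           if (true) stats::runif(n, indel_freq_min + 0.1, 1)
                           else stats::runif(n, 0.02, indel_freq_min - 0.05),
                           stats::runif(n, 0.8, 1)),
        true = true, stringsAsFactors = FALSE)
    }
    candidates <- rbind(mk(n_true, TRUE), mk(n_decoy, FALSE))
    candidates <- candidates[order(candidates$coordinate), , drop = FALSE]
    rownames(candidates) <- NULL
    # coverage: uniform tiles split at planted gaps
    bounds <- sort(unique(c(0, genome_length,
                            gap_intervals$start, gap_intervals$end)))
    cov <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
    in_gap <- vapply(seq_len(nrow(cov)), function(i)
      any(gap_intervals$start <= cov$start[i] & cov$end[i] <= gap_intervals$end),
      logical(1))
    cov$depth <- ifelse(in_gap, 0L, mean_depth)
    bases <- c("A", "C", "G", "T")
    reads <- vapply(seq_len(n_reads), function(i) {
      r <- sample(bases, read_length, replace = TRUE)
      # break accidental long runs so only planted reads carry one
      rl <- rle(r)
      if (any(rl$lengths >= homopolymer_run)) r <- rep(bases, length.out = read_length)
      paste(r, collapse = "")
    }, character(1))
    hp_idx <- sample.int(n_reads, n_homopolymer)
    for (i in hp_idx) {
      b <- sample(bases, 1)
      pos <- sample.int(read_length - homopolymer_run + 1L, 1)
      r <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      r[pos:(pos + homopolymer_run - 1L)] <- b
      reads[i] <- paste(r, collapse = "")
    }
    names(reads) <- sprintf("read%02d%s", seq_len(n_reads),
                            ifelse(seq_len(n_reads) %in% hp_idx, "_hp", ""))
    list(candidates = candidates, coverage = cov, reads = reads,
         truth = list(true_coordinates = candidates$coordinate[candidates$true],
                      gap_intervals = gap_intervals,
                      homopolymer_reads = names(reads)[hp_idx]))
  })
}

#' Write a generated dataset with a parameter manifest
#'
#' Writes each data-frame element of a generator's output as a
#' tab-separated file with a one-line header, character vectors of reads
#' as FASTA, and a \code{manifest.tsv} recording the seed and parameters.
#'
#' @param dataset a list returned by one of the \code{gen_*} generators.
#' @param dir output directory (created if absent).
#' @param cfg the \code{\link{sim_config}} used, recorded in the manifest.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir, cfg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(dataset)) {
    el <- dataset[[nm]]
    if (is.data.frame(el)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(el, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    } else if (is.character(el) && !is.null(names(el))) {
      p <- file.path(dir, paste0(nm, ".fasta"))
      writeLines(paste0(">", names(el), "\n", el), p)
      paths <- c(paths, p)
    }
  }
  man <- file.path(dir, "manifest.tsv")
  fields <- c(package = "evotol",
              seed = if (!is.null(cfg)) cfg$seed else NA,
              noise_sd = if (!is.null(cfg)) cfg$noise_sd else NA)
  utils::write.table(data.frame(key = names(fields), value = unname(fields)),
                     man, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, man))
}
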