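#' Load a mutation catalog
#'
#' Reads a TSV mutation table with columns \code{carrier, gene, coordinate,
#' class, nt_change, protein_change} (extra columns are kept; \code{#}
#' lines are comments).  \code{class} must be one of \code{SNP},
#' \code{short-indel} or \code{SV}; malformed rows are reported with their
#' line numbers.
#'
#' @param path TSV file path.
#' @return data frame of mutation records.
#' @export
load_mutation_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(df)
  if (!"carrier" %in% names(df) && "population" %in% names(df))
    df$carrier <- df$population  # population catalogs: the population is the carrier
  required <- c("carrier", "gene", "class")
  if (!all(required %in% names(df)))
    stop("mutation table must have columns: ", paste(required, collapse = ", "))
  bad <- which(!df$class %in% c("SNP", "short-indel", "SV"))
  if (length(bad))
    stop("unknown mutation class ", sQuote(df$class[bad[1]]),
         " in row ", bad[1], " of ", path)
  if ("coordinate" %in% names(df)) {
    df$coordinate <- suppressWarnings(as.numeric(df$coordinate))
    if (any(!is.na(df$coordinate) & df$coordinate < 1))
      stop("genomic coordinates are 1-based and must be >= 1")
  }
  df
}

#' Load a genotype-call table
#'
#' Reads a TSV of allele states with columns \code{locus, generation,
#' state} (\code{WT}, \code{Mut}, \code{Mixed} or \code{NT}); \code{#}
#' lines are comments.
#'
#' @param path TSV file path.
#' @return data frame of genotype calls.
#' @export
load_genotype_calls <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("locus", "generation", "state")
  if (!all(required %in% names(df)))
    stop("genotype calls need columns: ", paste(required, collapse = ", "))
  bad <- which(!df$state %in% c("WT", "Mut", "Mixed", "NT"))
  if (length(bad))
    stop("unknown genotype state ", sQuote(df$state[bad[1]]), " in row ", bad[1])
  df
}

#' Tally mutations by carrier or class
#'
#' @param records mutation-record data frame (see
#'   \code{\link{load_mutation_table}}).
#' @param by grouping column, \code{"carrier"} or \code{"class"}.
#' @return named integer vector of counts.
#' @export
count_mutations <- function(records, by = c("carrier", "class")) {
  by <- match.arg(by)
  if (nrow(records) == 0) return(stats::setNames(integer(), character()))
  tab <- table(records[[by]])
  stats::setNames(as.integer(tab), names(tab))
}

#' Parallel-evolution tally across populations
#'
#' Counts how many distinct populations carry at least one mutation at a
#' locus.  Independent lineages fixing mutations at the same locus is the
#' classic signature of parallel adaptation.  \code{merge_acrAB = TRUE}
#' folds \code{acrA} and \code{acrB} records into a combined \code{acrAB}
#' locus (the two genes form one efflux-pump operon); the merge is always
#' explicit, never implicit.
#'
#' @param population_records data frame with columns \code{population, gene}
#'   (one row per detected mutation).
#' @param locus locus label to tally.
#' @param merge_acrAB merge \code{acrA}/\code{acrB} under \code{acrAB}.
#' @return integer count of populations; 0 with a warning for a locus absent
#'   from the table.
#' @export
parallel_evolution_tally <- function(population_records, locus,
                                     merge_acrAB = FALSE) {
  stopifnot(all(c("population", "gene") %in% names(population_records)))
  gene <- population_records$gene
  if (merge_acrAB) gene[gene %in% c("acrA", "acrB")] <- "acrAB"
  hit <- gene == locus
  if (!any(hit)) {
    warning("locus ", sQuote(locus), " not found in population records")
    return(0L)
  }
  length(unique(population_records$population[hit]))
}

#' Allele frequency from clone counts
#'
#' @param n_mutant_clones number of clones carrying the mutant allele.
#' @param n_total_clones total clones screened (positive).
#' @return allele frequency in percent.
#' @export
allele_frequency <- function(n_mutant_clones, n_total_clones) {
  if (any(n_total_clones <= 0)) stop("'n_total_clones' must be positive")
  if (any(n_mutant_clones < 0 | n_mutant_clones > n_total_clones))
    stop("'n_mutant_clones' must lie in [0, n_total_clones]")
  100 * n_mutant_clones / n_total_clones
}

#' Order loci by first detected generation
#'
#' For each locus, finds the first sampled generation whose call is
#' \code{Mut} or \code{Mixed} (a mixed population state counts as detection,
#' matching whole-population screening); \code{NT} (not-tested) generations
#' are skipped.  Loci never observed non-wild-type are reported as not
#' detected.  Ties share a rank, forming a mutation cluster.
#'
#' @param calls data frame with columns \code{locus, generation, state}
#'   where \code{state} is one of \code{WT, Mut, Mixed, NT}.
#' @return data frame \code{locus, first_detected, rank} sorted by
#'   \code{first_detected} (ascending, \code{NA} for undetected loci last);
#'   tied loci share the same rank.
#' @export
mutation_order <- function(calls) {
  stopifnot(all(c("locus", "generation", "state") %in% names(calls)))
  bad <- setdiff(unique(calls$state), c("WT", "Mut", "Mixed", "NT"))
  if (length(bad)) stop("unknown genotype state(s): ", paste(bad, collapse = ", "))
  first <- vapply(split(calls, calls$locus), function(d) {
    d <- d[d$state %in% c("Mut", "Mixed"), , drop = FALSE]
    if (nrow(d) == 0) NA_real_ else min(d$generation)
  }, numeric(1))
  out <- data.frame(locus = names(first), first_detected = unname(first),
                    stringsAsFactors = FALSE)
  out <- out[order(out$first_detected, out$locus, na.last = TRUE), , drop = FALSE]
  detected <- !is.na(out$first_detected)
  out$rank <- NA_integer_
  if (any(detected))
    out$rank[detected] <- match(out$first_detected[detected],
                                sort(unique(out$first_detected[detected])))
  rownames(out) <- NULL
  out
}

#' Join a mutation order with a fitness trajectory
#'
#' Purely descriptive attribution: for each interval between consecutive
#' genotyped generations, lists the loci first detected in that interval and
#' the growth-rate change across it.  No causal claim is made; a locus and a
#' fitness jump sharing an interval is correlation only.
#'
#' @param order output of \code{\link{mutation_order}}.
#' @param fitness_by_generation data frame with columns \code{generation,
#'   mu_max} (one condition at a time).
#' @return data frame with one row per inter-sample interval:
#'   \code{gen_from, gen_to, delta_mu, loci} (semicolon-joined, \code{""}
#'   when none), \code{missing_fitness} flag.
#' @export
trajectory_join <- function(order, fitness_by_generation) {
  stopifnot(all(c("generation", "mu_max") %in% names(fitness_by_generation)))
  tr <- fitness_by_generation[order(fitness_by_generation$generation), ]
  gens <- tr$generation
  if (length(gens) < 2) stop("fitness trajectory needs at least two generations")
  rows <- lapply(seq_len(length(gens) - 1L), function(i) {
    lo <- gens[i]; hi <- gens[i + 1L]
    in_interval <- !is.na(order$first_detected) &
      order$first_detected > lo & order$first_detected <= hi
    dmu <- tr$mu_max[i + 1L] - tr$mu_max[i]
    data.frame(gen_from = lo, gen_to = hi, delta_mu = dmu,
               loci = paste(order$locus[in_interval], collapse = ";"),
               missing_fitness = !is.finite(dmu), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Triage candidate variants by quality and frequency
#'
#' SNP candidates are kept when their consensus quality reaches
#' \code{snp_quality_min}; indels when the fraction of supporting reads
#' reaches \code{indel_freq_min}.  Boundary values are kept (\code{>=}).
#' The defaults (150, 0.4) are the discard thresholds below which
#' resequencing candidates are almost always false positives; the stricter
#' quality preset 200 historically used to select candidates for Sanger
#' verification is available via \code{preset = "verification"}.
#'
#' @param candidates data frame with columns \code{coordinate, class
#'   (SNP|indel), quality, frequency}.
#' @param snp_quality_min minimum consensus quality for SNPs.
#' @param indel_freq_min minimum supporting-read fraction for indels.
#' @param preset \code{"discovery"} (150/0.4, default) or
#'   \code{"verification"} (200/0.4); explicit thresholds override the preset.
#' @return the kept subset of \code{candidates}.
#' @export
filter_variants <- function(candidates, snp_quality_min = NULL,
                            indel_freq_min = NULL,
                            preset = c("discovery", "verification")) {
  preset <- match.arg(preset)
  if (is.null(snp_quality_min))
    snp_quality_min <- if (preset == "discovery") 150 else 200
  if (is.null(indel_freq_min)) indel_freq_min <- 0.4
  if (snp_quality_min < 0 || indel_freq_min < 0)
    stop("thresholds must be nonnegative")
  stopifnot(all(c("class", "quality", "frequency") %in% names(candidates)))
  bad <- setdiff(unique(candidates$class), c("SNP", "indel"))
  if (length(bad)) stop("unknown candidate class(es): ", paste(bad, collapse = ", "))
  keep <- ifelse(candidates$class == "SNP",
                 candidates$quality >= snp_quality_min,
                 candidates$frequency >= indel_freq_min)
  candidates[keep, , drop = FALSE]
}

#' Detect coverage gaps
#'
#' Tabulates maximal genomic runs whose read depth is at or below
#' \code{max_depth} and whose length reaches \code{min_length}; such gaps
#' are candidate large deletions.  Intervals are 0-based half-open
#' (bedGraph convention).
#'
#' @param track data frame with columns \code{start, end, depth} (0-based
#'   half-open, sorted, non-overlapping; an optional \code{seq} column is
#'   carried through and gaps never span sequences).
#' @param min_length minimum gap length in bp.
#' @param max_depth maximum depth counted as a gap (default 0).
#' @return data frame \code{seq (if present), start, end, length}.
#' @export
detect_coverage_gaps <- function(track, min_length = 1000L, max_depth = 0L) {
  stopifnot(all(c("start", "end", "depth") %in% names(track)))
  seqs <- if ("seq" %in% names(track)) track$seq else rep("seq1", nrow(track))
  out <- list()
  for (s in unique(seqs)) {
    tr <- track[seqs == s, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    if (any(tr$end <= tr$start)) stop("intervals must satisfy end > start")
    if (any(tr$start[-1] < tr$end[-nrow(tr)]))
      stop("coverage intervals must be non-overlapping and sorted")
    low <- tr$depth <= max_depth
    if (!any(low)) next
    # merge adjacent/contiguous low-depth intervals into maximal runs
    idx <- which(low)
    run_id <- cumsum(c(1L, diff(idx) != 1L |
                         tr$start[idx[-1]] != tr$end[idx[-length(idx)]]))
    for (g in split(idx, run_id)) {
      lo <- tr$start[g[1]]; hi <- tr$end[g[length(g)]]
      if (hi - lo >= min_length)
        out[[length(out) + 1L]] <- data.frame(seq = s, start = lo, end = hi,
                                              length = hi - lo,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(seq = character(), start = numeric(), end = numeric(),
                      length = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  if (!"seq" %in% names(track)) res$seq <- NULL
  rownames(res) <- NULL
  res
}

#' Filter reads containing long homopolymer runs
#'
#' Erroneous homopolymer runs are a common artifact in unmapped short
#' reads; reads containing any single-base run (including N) strictly
#' longer than \code{max_run} are discarded before de novo assembly.
#' Empty reads are kept vacuously.
#'
#' @param reads character vector of A/C/G/T/N read sequences (a named
#'   vector keeps its names).
#' @param max_run longest permitted run length.
#' @return the kept reads.
#' @export
homopolymer_filter <- function(reads, max_run = 10L) {
  stopifnot(max_run >= 1L)
  if (any(grepl("[^ACGTN]", reads)))
    stop("reads must be A/C/G/T/N strings")
  has_long_run <- vapply(reads, function(r) {
    if (!nzchar(r)) return(FALSE)
    rl <- rle(strsplit(r, "", fixed = TRUE)[[1]])
    any(rl$lengths > max_run)
  }, logical(1), USE.NAMES = FALSE)
  reads[!has_long_run]
}

#' Convert between 1-based and 0-based half-open coordinates
#'
#' Mutation catalogs use 1-based positions; coverage tracks use 0-based
#' half-open intervals.
#'
#' @param pos 1-based position(s).
#' @return \code{coord_1based_to_0based}: 0-based half-open
#'   \code{(start, end)} data frame; \code{coord_0based_to_1based}: 1-based
#'   position of an interval start.
#' @export
coord_1based_to_0based <- function(pos) data.frame(start = pos - 1, end = pos)

#' @rdname coord_1based_to_0based
#' @param start 0-based interval start(s).
#' @export
coord_0based_to_1based <- function(start) start + 1
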