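clone_fixture <- function() {
  load_mutation_table(system.file("extdata", "mutation_catalog_clones.tsv",
                                  package = "evotol"))
}
pop_fixture <- function() {
  load_mutation_table(system.file("extdata", "mutation_catalog_populations.tsv",
                                  package = "evotol"))
}

test_that("the clone mutation catalog loads with its full row structure", {
  tab <- clone_fixture()
  expect_identical(nrow(tab), 39L)
  counts <- count_mutations(tab, by = "carrier")
  expect_identical(counts[["X3.5"]], 11L)
  expect_identical(counts[["G3.266.7"]], 8L)
  expect_identical(counts[["G3.2/G3.6"]], 20L)
  # conservation: per-carrier counts sum to the record count
  expect_identical(sum(counts), nrow(tab))
  expect_identical(sum(count_mutations(tab, by = "class")), nrow(tab))
})

test_that("malformed mutation tables fail loudly", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("carrier\tgene\tclass", "X1\tacrA\tweird"), tmp)
  expect_error(load_mutation_table(tmp), "unknown mutation class.*row 1")
  writeLines("carrier\tgene\tclass", tmp)
  expect_identical(nrow(load_mutation_table(tmp)), 0L)
})

test_that("parallel-evolution tallies match the endpoint populations", {
  pops <- pop_fixture()
  names(pops)[names(pops) == "population"] <- "population"
  expect_identical(parallel_evolution_tally(pops, "marC"), 6L)
  expect_identical(parallel_evolution_tally(pops, "acrAB", merge_acrAB = TRUE), 5L)
  expect_identical(parallel_evolution_tally(pops, "mdh"), 3L)
  expect_identical(parallel_evolution_tally(pops, "hfq"), 2L)
  expect_warning(n <- parallel_evolution_tally(pops, "tolC"), "not found")
  expect_identical(n, 0L)
})

test_that("allele frequency converts clone counts to percent", {
  expect_equal(allele_frequency(2, 8), 25)
  expect_equal(allele_frequency(4, 8), 50)
  expect_equal(allele_frequency(0, 8), 0)
  expect_error(allele_frequency(1, 0), "positive")
  expect_error(allele_frequency(9, 8), "lie in")
})

test_that("mutation order on the lineage fixture follows first detection", {
  calls <- load_genotype_calls(
    system.file("extdata", "x3_allele_trajectories_synthetic.tsv",
                package = "evotol"))
  ord <- mutation_order(calls)
  tqsA <- ord[ord$locus == "mdtJ-tqsA", ]
  cluster <- ord[ord$locus %in% c("mdh", "deaD", "plsX"), ]
  expect_identical(tqsA$first_detected, 180)
  expect_true(all(cluster$first_detected == 266))
  expect_true(all(tqsA$rank < cluster$rank))
  # tied loci share one rank (a mutation cluster)
  expect_identical(length(unique(cluster$rank)), 1L)
  # a Mixed call counts as detection
  expect_identical(ord$first_detected[ord$locus == "yfgO"], 90)
})

test_that("mutation order matches a brute-force scan on random call tables", {
  set.seed(14)
  for (rep in 1:10) {
    loci <- paste0("locus", 1:6)
    gens <- sort(sample(0:400, 5))
    calls <- expand.grid(locus = loci, generation = gens,
                         stringsAsFactors = FALSE)
    calls$state <- sample(c("WT", "Mut", "Mixed", "NT"), nrow(calls),
                          replace = TRUE, prob = c(0.5, 0.25, 0.15, 0.1))
    ord <- mutation_order(calls)
    for (l in loci) {
      hit <- calls$generation[calls$locus == l &
                                calls$state %in% c("Mut", "Mixed")]
      expected <- if (length(hit)) min(hit) else NA_real_
      expect_equal(ord$first_detected[ord$locus == l], as.numeric(expected))
    }
  }
})

test_that("degenerate call tables order sensibly", {
  one <- data.frame(locus = "a", generation = 10, state = "Mut")
  expect_identical(mutation_order(one)$rank, 1L)
  allwt <- data.frame(locus = c("a", "b"), generation = 10, state = "WT")
  ord <- mutation_order(allwt)
  expect_true(all(is.na(ord$first_detected)))
  # all loci fixed before the first sample: every call Mut, one shared rank
  fixed <- gen_allele_trajectories(
    data.frame(locus = c("a", "b"), fix_gen = c(-5, -1)), c(0, 50))
  expect_true(all(fixed$state == "Mut"))
  ordf <- mutation_order(fixed)
  expect_identical(unique(ordf$rank), 1L)
})

test_that("trajectory join attributes fitness change to interval loci", {
  calls <- gen_allele_trajectories(
    data.frame(locus = "sweep", fix_gen = 150), c(0, 100, 200, 300))
  ord <- mutation_order(calls)
  fitness <- data.frame(generation = c(0, 100, 200, 300),
                        mu_max = c(0.2, 0.2, 0.5, 0.5))
  tj <- trajectory_join(ord, fitness)
  jump <- tj[tj$gen_from == 100, ]
  expect_identical(jump$loci, "sweep")
  expect_equal(jump$delta_mu, 0.3)
  expect_identical(tj$loci[tj$gen_from == 200], "")
  # two loci appearing in one interval are both listed
  calls2 <- gen_allele_trajectories(
    data.frame(locus = c("a", "b"), fix_gen = c(150, 160)), c(0, 100, 200))
  tj2 <- trajectory_join(mutation_order(calls2), fitness[1:3, ])
  expect_setequal(strsplit(tj2$loci[tj2$gen_from == 100], ";")[[1]],
                  c("a", "b"))
})

test_that("variant triage keeps boundaries and separates planted sets", {
  cands <- data.frame(coordinate = 1:4, class = c("SNP", "SNP", "indel", "indel"),
                      quality = c(149, 150, 40, 40),
                      frequency = c(0.9, 0.9, 0.39, 0.4))
  kept <- filter_variants(cands)
  expect_identical(kept$coordinate, c(2L, 4L))
  # stricter preset used for verification-grade candidates
  keptv <- filter_variants(cands, preset = "verification")
  expect_identical(keptv$coordinate, 4L)
  v <- gen_variant_candidates(n_true = 5, n_decoy = 5, cfg = sim_config(21))
  kept2 <- filter_variants(v$candidates)
  expect_identical(nrow(kept2), 5L)
  expect_true(all(kept2$true))
})

test_that("raising a triage threshold never enlarges the kept set", {
  v <- gen_variant_candidates(n_true = 10, n_decoy = 10, cfg = sim_config(4))
  prev <- nrow(v$candidates) + 1L
  for (q in c(0, 100, 150, 300, 1000)) {
    n <- nrow(filter_variants(v$candidates, snp_quality_min = q))
    expect_lte(n, prev)
    prev <- n
  }
  prev <- nrow(v$candidates) + 1L
  for (f in c(0, 0.2, 0.4, 0.8, 1.01)) {
    n <- nrow(filter_variants(v$candidates, indel_freq_min = f))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("coverage gaps are maximal runs over the depth threshold", {
  uniform <- data.frame(start = c(0, 500), end = c(500, 1000), depth = 100)
  expect_identical(nrow(detect_coverage_gaps(uniform, min_length = 10)), 0L)
  # adjacent sub-threshold intervals merge into one maximal gap
  track <- data.frame(start = c(0, 100, 150, 300), end = c(100, 150, 300, 400),
                      depth = c(50, 0, 0, 50))
  gaps <- detect_coverage_gaps(track, min_length = 100)
  expect_identical(nrow(gaps), 1L)
  expect_identical(gaps$start, 100)
  expect_identical(gaps$end, 300)
  # no two returned gaps are adjacent or overlapping
  track2 <- data.frame(start = seq(0, 900, 100), end = seq(100, 1000, 100),
                       depth = c(0, 0, 9, 0, 50, 0, 0, 50, 0, 0))
  g2 <- detect_coverage_gaps(track2, min_length = 100, max_depth = 10)
  expect_true(all(g2$start[-1] > g2$end[-nrow(g2)]))
})

test_that("a planted deletion-sized gap is recovered exactly", {
  v <- gen_variant_candidates(gap_intervals = data.frame(start = 100000,
                                                         end = 109900),
                              cfg = sim_config(6))
  gaps <- detect_coverage_gaps(v$coverage, min_length = 1000)
  expect_identical(nrow(gaps), 1L)
  expect_identical(gaps$start, 1e5)
  expect_identical(gaps$end, 109900)
  expect_identical(gaps$length, 9900)
})

test_that("homopolymer filter agrees with a regex oracle on random reads", {
  expect_identical(homopolymer_filter("ACGTACGT", max_run = 5), "ACGTACGT")
  expect_identical(length(homopolymer_filter(strrep("A", 20), max_run = 10)), 0L)
  expect_identical(homopolymer_filter("", max_run = 5), "")
  set.seed(77)
  reads <- vapply(1:200, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), sample(10:60, 1), replace = TRUE,
                 prob = c(0.3, 0.24, 0.24, 0.2, 0.02)), collapse = ""),
    character(1))
  # plant some long runs
  reads[seq(5, 200, by = 9)] <- paste0("ACGT", strrep("G", 12), "TTAC")
  for (mr in c(5, 8, 11)) {
    kept <- homopolymer_filter(reads, max_run = mr)
    oracle <- reads[!grepl(sprintf("([ACGTN])\\1{%d,}", mr), reads)]
    expect_identical(kept, oracle)
  }
})

test_that("coordinate converters invert each other", {
  expect_identical(coord_1based_to_0based(101)$start, 100)
  expect_identical(coord_0based_to_1based(100), 101)
  expect_identical(coord_0based_to_1based(coord_1based_to_0based(42)$start), 42)
})
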