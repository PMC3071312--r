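four_cell_design <- function(n_rep = 3) {
  data.frame(sample = paste0("s", 1:(4 * n_rep)),
             strain = rep(c("WT", "MUT"), each = 2 * n_rep),
             condition = rep(rep(c("0", "0.5"), each = n_rep), 2),
             stringsAsFactors = FALSE)
}

test_that("array-layout arithmetic reproduces the spotted-array design", {
  passes <- data.frame(probes = c(12037, 41), cds = c(4253, 27))
  lay <- array_layout(12078, 6, passes = passes)
  out <- layout_spot_count(lay)
  expect_identical(out$n_spots, 72468L)
  expect_identical(out$n_cds, 4280)
  expect_identical(layout_spot_count(array_layout(1, 1))$n_spots, 1L)
  bad <- array_layout(12000, 6, passes = passes)
  expect_error(layout_spot_count(bad), "do not sum")
})

test_that("background adjustment is plain subtraction, negatives retained", {
  expect_equal(background_adjust(500, 100), 400)
  expect_equal(background_adjust(100, 150), -50)
  fg <- matrix(runif(12, 0, 1000), 3)
  bg <- matrix(runif(12, 0, 200), 3)
  expect_equal(background_adjust(fg, bg), fg - bg)
})

test_that("quantile normalization equalizes sorted columns exactly", {
  set.seed(11)
  for (dims in list(c(50, 3), c(200, 12), c(10, 2))) {
    m <- matrix(rnorm(prod(dims), 8, 2), dims[1], dims[2])
    q <- quantile_normalize(m)
    s <- apply(q, 2, sort)
    expect_true(all(abs(s - s[, 1]) < 1e-12))
    # rank order within each column is preserved
    expect_identical(apply(q, 2, order), apply(m, 2, order))
  }
  expect_warning(quantile_normalize(matrix(1:5)), "single sample")
})

test_that("quantile normalization matches a hand-computed 3x4 oracle", {
  m <- matrix(c(2, 5, 3,
                4, 1, 6,
                9, 8, 7,
                1, 3, 2), nrow = 3)
  q <- quantile_normalize(m)
  means <- rowMeans(apply(m, 2, sort))
  for (j in 1:4)
    expect_equal(q[, j], means[rank(m[, j])], tolerance = 1e-12)
  # cross-check against the reference implementation
  skip_if_not_installed("limma")
  expect_equal(unname(q), unname(limma::normalizeQuantiles(m)),
               tolerance = 1e-12)
})

test_that("the glog transform is finite through zero and log-like above", {
  x <- c(-100, 0, 50, 1e3, 1e6)
  y <- glog_transform(x, lambda = 10)
  expect_true(all(is.finite(y)))
  expect_equal(y[5], log2(1e6), tolerance = 1e-4)
  expect_error(glog_transform(1, lambda = -1), "positive")
})

test_that("technical-spot medians and the biological-replicate rule apply", {
  des <- four_cell_design(3)
  spots <- expand.grid(tech = 1:3, probe = c("p1", "p2"), sample = des$sample,
                       stringsAsFactors = FALSE)
  spots$value <- 5
  spots$value[spots$probe == "p1" & spots$sample == "s1"] <- c(1, 2, 100)
  # p2 is missing in two replicates of every cell -> dropped
  spots$value[spots$probe == "p2" &
                spots$sample %in% des$sample[des$sample != "s1"]] <- NA
  mat <- collapse_replicates(spots[, c("probe", "sample", "value")], des)
  expect_identical(rownames(mat), "p1")
  expect_identical(attr(mat, "dropped"), "p2")
  expect_equal(mat["p1", "s1"], 2)  # median of (1, 2, 100)
})

test_that("replicate retention matches brute-force rule application", {
  des <- four_cell_design(3)
  set.seed(40)
  probes <- paste0("p", 1:30)
  spots <- expand.grid(tech = 1:2, probe = probes, sample = des$sample,
                       stringsAsFactors = FALSE)
  spots$value <- rnorm(nrow(spots), 8)
  drop_idx <- sample(nrow(spots), 500)
  spots$value[drop_idx] <- NA
  mat <- collapse_replicates(spots[, c("probe", "sample", "value")], des)
  cell <- interaction(des$strain, des$condition)
  for (p in probes) {
    med <- tapply(spots$value[spots$probe == p], spots$sample[spots$probe == p],
                  median, na.rm = TRUE)[des$sample]
    ok_all <- all(vapply(levels(cell), function(cl)
      sum(!is.na(med[cell == cl])) >= 2, logical(1)))
    expect_identical(p %in% rownames(mat), ok_all)
  }
})

test_that("probe selection minimizes the summed replicate SD with a tie rule", {
  des <- four_cell_design(3)
  m <- matrix(8, 3, 12, dimnames = list(c("pA", "pB", "pC"), des$sample))
  m["pA", ] <- 8 + rep(c(-0.1, 0, 0.1), 4)           # sd sum 0.4
  m["pB", ] <- 8 + rep(c(-0.25, 0.05, 0.225), 4)     # sd sum ~0.9
  pg <- data.frame(probe = c("pA", "pB", "pC"), gene = c("g1", "g1", "g2"))
  g <- select_probe_per_gene(m, pg, des)
  expect_equal(unname(g["g1", ]), unname(m["pA", ]))
  # exact tie -> lexicographically smaller probe id wins
  m2 <- m; m2["pB", ] <- m2["pA", ]
  pg2 <- data.frame(probe = c("pB", "pA"), gene = "g1")
  g2 <- select_probe_per_gene(m2[1:2, ], pg2, des)
  expect_equal(unname(g2["g1", ]), unname(m2["pA", ]))
})

test_that("the intensity and IQR gene filters match a brute-force oracle", {
  set.seed(13)
  m <- matrix(rlnorm(20 * 12, log(80), 1), 20, 12,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  m[1, ] <- 200                 # constant: fails the IQR filter
  m[2, ] <- c(150, 150, rep(10, 10))  # >100 in only 2 of 12: fails intensity
  kept <- filter_genes(m)
  expect_false("g1" %in% rownames(kept))
  expect_false("g2" %in% rownames(kept))
  oracle <- rownames(m)[vapply(seq_len(nrow(m)), function(i) {
    sum(m[i, ] > 100) >= ceiling(0.25 * 12) &&
      (quantile(m[i, ], 0.75) - quantile(m[i, ], 0.25)) > 0.5
  }, logical(1))]
  expect_identical(rownames(kept), oracle)
})

test_that("identical groups give a null moderated statistic", {
  set.seed(55)
  des <- four_cell_design(3)
  m <- matrix(rnorm(25 * 12, 8, 1), 25, 12,
              dimnames = list(paste0("g", 1:25), des$sample))
  # make the stressed group an exact copy of the control group
  wt0 <- des$strain == "WT" & des$condition == "0"
  wt5 <- des$strain == "WT" & des$condition == "0.5"
  m[, wt5] <- m[, wt0]
  res <- moderated_t_test(m, des, "ref_delta", ref_strain = "WT",
                          ref_condition = "0")
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))
})

test_that("with zero prior weight the statistic is the pooled Student t", {
  set.seed(7)
  des <- four_cell_design(3)
  m <- matrix(rnorm(40 * 12, 8, 1), 40, 12,
              dimnames = list(paste0("g", 1:40), des$sample))
  res <- moderated_t_test(m, des, "ref_delta", ref_strain = "WT",
                          ref_condition = "0", prior_df = 0)
  for (g in c("g1", "g17", "g40")) {
    x <- m[g, des$strain == "WT" & des$condition == "0.5"]
    y <- m[g, des$strain == "WT" & des$condition == "0"]
    tt <- t.test(x, y, var.equal = TRUE)
    row <- res[res$gene == g, ]
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("the shrunk variance lies between the gene and prior variances", {
  set.seed(19)
  des <- four_cell_design(3)
  m <- matrix(rnorm(300 * 12, 8, rep(runif(300, 0.3, 3), 12)), 300, 12,
              dimnames = list(paste0("g", 1:300), des$sample))
  res <- moderated_t_test(m, des, "ref_delta", ref_strain = "WT",
                          ref_condition = "0")
  prior <- attr(res, "prior")
  expect_true(prior$d0 > 0)
  # reconstruct per-gene residual s2 and check the posterior is between
  grp <- interaction(des$strain, des$condition)
  use <- des$strain == "WT"
  s2 <- apply(m[, use], 1, function(v) {
    g <- grp[use]
    sum(tapply(v, g, function(x) sum((x - mean(x))^2))[table(g) > 0]) /
      (sum(use) - 2)
  })
  s2_post <- (prior$d0 * prior$s0_2 + (sum(use) - 2) * s2) /
    (prior$d0 + sum(use) - 2)
  expect_true(all(s2_post >= pmin(s2, prior$s0_2) - 1e-12))
  expect_true(all(s2_post <= pmax(s2, prior$s0_2) + 1e-12))
})

test_that("moderated statistics agree with the reference implementation", {
  skip_if_not_installed("limma")
  set.seed(23)
  des <- four_cell_design(3)
  m <- matrix(rnorm(200 * 12, 8, rep(runif(200, 0.3, 2), 12)), 200, 12,
              dimnames = list(paste0("g", 1:200), des$sample))
  res <- moderated_t_test(m, des, "ref_delta", ref_strain = "WT",
                          ref_condition = "0")
  use <- des$strain == "WT"
  design <- stats::model.matrix(~factor(des$condition[use], c("0", "0.5")))
  fit <- limma::eBayes(limma::lmFit(m[, use], design))
  ord <- match(res$gene, rownames(m))
  expect_equal(res$t, fit$t[ord, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(res$p, fit$p.value[ord, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("difference-of-differences contrast targets the interaction", {
  set.seed(29)
  des <- four_cell_design(3)
  m <- matrix(rnorm(100 * 12, 8, 0.3), 100, 12,
              dimnames = list(paste0("g", 1:100), des$sample))
  # gene 1: pure interaction; gene 2: same shift in both strains
  mut_s <- des$strain == "MUT" & des$condition == "0.5"
  any_s <- des$condition == "0.5"
  m[1, mut_s] <- m[1, mut_s] + 3
  m[2, any_s] <- m[2, any_s] + 3
  res <- moderated_t_test(m, des, "difference", ref_strain = "WT",
                          ref_condition = "0")
  expect_identical(res$gene[1], "g1")
  expect_true(res$significant[res$gene == "g1"])
  expect_false(res$significant[res$gene == "g2"])
  expect_equal(res$effect[res$gene == "g1"], 3, tolerance = 0.5)
})

test_that("planted effects are detected with high sensitivity at low noise", {
  set.seed(37)
  des <- four_cell_design(3)
  n_genes <- 1000
  m <- matrix(rnorm(n_genes * 12, 8, 0.25), n_genes, 12,
              dimnames = list(paste0("g", 1:n_genes), des$sample))
  planted <- seq_len(n_genes / 10)
  shift <- des$strain == "WT" & des$condition == "0.5"
  m[planted, shift] <- m[planted, shift] + 2
  res <- moderated_t_test(m, des, "ref_delta", ref_strain = "WT",
                          ref_condition = "0")
  hits <- res$gene[res$significant]
  sens <- mean(paste0("g", planted) %in% hits)
  expect_gte(sens, 0.8)
})

test_that("BH adjustment matches hand computation and flags at the cutoff", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  adj <- adjust_bh(p, cutoff = 0.05)
  expect_equal(adj$p_adj, c(0.04, 0.04, 0.04, 0.5), tolerance = 1e-12)
  expect_identical(adj$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(adjust_bh(0.2)$p_adj, 0.2)
  expect_false(any(adjust_bh(rep(1, 5))$significant))
  expect_error(adjust_bh(c(0.5, 1.2)), "lie in")
  # monotone in the raw-p order
  set.seed(3)
  pr <- runif(50)
  a <- adjust_bh(pr)$p_adj
  expect_true(all(diff(a[order(pr)]) >= -1e-12))
})

test_that("the full preprocessing chain recovers gene values at zero noise", {
  Z <- gen_connectivity(40, paste0("TF", 1:3), identifiable = FALSE,
                        cfg = sim_config(2))
  P <- matrix(rnorm(12), 3, 4)
  d <- gen_expression_dataset(Z, P, sim_config(seed = 2, noise_sd = 0))
  adj <- background_adjust(d$spots$foreground, d$spots$background)
  spots <- data.frame(probe = d$spots$probe, sample = d$spots$sample,
                      value = adj)
  mat <- collapse_replicates(spots, d$design)
  gene <- select_probe_per_gene(mat, d$probe_gene, d$design)
  expect_equal(gene[rownames(d$truth$E), colnames(d$truth$E)], d$truth$E,
               tolerance = 1e-12)
})
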