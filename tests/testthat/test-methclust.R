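make_beta <- function(beta, spacing = 300) {
  rownames(beta) <- sprintf("cg%05d", seq_len(nrow(beta)))
  if (is.null(colnames(beta)))
    colnames(beta) <- paste0("s", seq_len(ncol(beta)))
  beta_matrix(beta, rep("chr1", nrow(beta)),
              seq_len(nrow(beta)) * spacing)
}

test_that("variable-probe selection matches the brute-force sd-sort oracle", {
  set.seed(10)
  for (trial in 1:20) {
    beta <- matrix(runif(200 * 6), 200, 6)
    bm <- make_beta(beta)
    sel <- select_variable_probes(bm, 50)
    expect_setequal(sel$probes$probe_id, sd_sort_oracle(bm$beta, 50))
  }
  # identity and error boundary
  bm <- make_beta(matrix(runif(60), 10, 6))
  expect_identical(select_variable_probes(bm, 10)$probes$probe_id,
                   bm$probes$probe_id)
  expect_error(select_variable_probes(bm, 11), "exceeds")
})

test_that("clear sd structure is selected exactly", {
  set.seed(4)
  beta <- matrix(0.5, 600, 6)
  hot <- sample(600, 100)
  beta[hot, ] <- 0.5 + matrix(rnorm(100 * 6, 0, 0.3), 100, 6)
  beta <- pmin(pmax(beta, 0), 1)
  bm <- make_beta(beta)
  sel <- select_variable_probes(bm, 100)
  expect_setequal(sel$probes$probe_id, sprintf("cg%05d", sort(hot)))
})

test_that("complete-linkage clustering recovers a planted 5-vs-3 split", {
  sim <- simulate_methylation(n_group1 = 5, n_group2 = 3, n_probes = 3000,
                              n_dmrs = 40, delta_beta = 0.4, noise_sd = 0.02,
                              seed = 8)
  top <- select_variable_probes(sim$beta, 100)
  cl <- cluster_samples(top, k = 2)
  expect_equal(ari(cl$labels, sim$labels[names(cl$labels)]), 1)
  # k = number of samples gives singletons
  expect_length(unique(cluster_samples(top, k = 8)$labels), 8)
  expect_error(cluster_samples(top, k = 9), "exceeds")
})

test_that("a duplicated sample sits at distance zero and merges first", {
  set.seed(2)
  beta <- matrix(runif(300), 100, 3)
  beta <- cbind(beta, beta[, 3])
  colnames(beta) <- c("a", "b", "c", "c_dup")
  bm <- make_beta(beta)
  cl <- cluster_samples(bm, k = 2)
  expect_identical(cl$tree$height[1], 0)
  first_pair <- sort(-cl$tree$merge[1, ])
  expect_setequal(colnames(beta)[first_pair], c("c", "c_dup"))
  expect_identical(unname(cl$labels["c"]), unname(cl$labels["c_dup"]))
})

test_that("vectorized Welch tests agree with stats::t.test probe by probe", {
  set.seed(11)
  beta <- matrix(runif(50 * 8), 50, 8)
  bm <- make_beta(beta)
  labels <- setNames(rep(c("g1", "g2"), c(5, 3)), colnames(bm$beta))
  res <- test_probes(bm, labels, group1 = "g1")
  for (i in seq_len(nrow(bm$beta))) {
    tt <- t.test(bm$beta[i, 1:5], bm$beta[i, 6:8])
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$delta_beta[i],
                 unname(tt$estimate[1] - tt$estimate[2]), tolerance = 1e-12)
  }
})

test_that("degenerate probes are reported, not fatal", {
  beta <- rbind(rep(0.5, 8),                     # constant everywhere
                c(rep(0.4, 5), rep(0.4, 3)),     # constant, equal means
                matrix(runif(16), 2, 8))
  bm <- make_beta(beta)
  labels <- setNames(rep(c("g1", "g2"), c(5, 3)), colnames(bm$beta))
  res <- test_probes(bm, labels, group1 = "g1")
  expect_identical(res$p[res$zero_variance], c(1, 1))
  expect_identical(res$delta_beta[1], 0)
  # identical group means with nonzero variance: p near 1, delta 0
  v <- c(0.3, 0.5, 0.4, 0.45, 0.35)
  beta2 <- matrix(c(v, v[1:3]), nrow = 1)
  beta2 <- rbind(beta2, beta2)
  bm2 <- make_beta(beta2)
  res2 <- test_probes(bm2, labels, group1 = "g1")
  expect_gt(res2$p[1], 0.9)
  expect_lt(abs(res2$delta_beta[1]), 0.03)
  # a group below 2 samples is an error
  expect_error(test_probes(bm, setNames(c("g1", rep("g2", 7)),
                                        colnames(bm$beta)), "g1"),
               "at least 2")
})

test_that("a strong planted effect is significant in closed form", {
  # delta 0.4 with sd 0.05 in 5-vs-3 groups gives t ~ 11; p far below 0.05
  sim <- simulate_methylation(n_probes = 500, n_dmrs = 5, delta_beta = 0.4,
                              noise_sd = 0.05, seed = 21)
  res <- test_probes(sim$beta, sim$labels, group1 = "mutant")
  planted <- unlist(mapply(seq,
                           sim$truth$planted$regions$first_probe,
                           sim$truth$planted$regions$first_probe +
                             sim$truth$planted$regions$probe_count - 1))
  expect_true(all(res$p[planted] < 0.05))
  expect_true(all(res$delta_beta[planted] < -0.2))
})

test_that("planted contiguous regions are called exactly, extras absent", {
  sim <- simulate_methylation(n_probes = 20000, n_dmrs = 25, dmr_probes = 5,
                              delta_beta = 0.4, noise_sd = 0.05, seed = 13)
  dmrs <- find_dmrs(sim$beta, sim$labels, group1 = "mutant")
  expect_identical(nrow(dmrs), 25L)
  expect_true(all(dmrs$direction == "hypo"))
  expect_identical(dmrs$probe_count, rep(5L, 25))
  expect_identical(dmrs$start, sim$truth$planted$regions$start)
  expect_identical(dmrs$end, sim$truth$planted$regions$end)
  # no significant probes -> empty frame
  null <- simulate_methylation(n_probes = 2000, n_dmrs = 0, seed = 3)
  expect_identical(nrow(find_dmrs(null$beta, null$labels, "mutant")), 0L)
})

test_that("regions split at gaps wider than max_gap", {
  # two blocks of 3 probes each, separated by a 5 kb gap, all significant
  n1 <- 5; n2 <- 3
  beta_mut <- matrix(0.2, 6, n1)
  beta_wt <- matrix(0.8, 6, n2)
  beta <- cbind(beta_mut, beta_wt) +
    matrix(rnorm(6 * 8, 0, 0.01), 6, 8)
  beta <- pmin(pmax(beta, 0), 1)
  rownames(beta) <- sprintf("cg%02d", 1:6)
  colnames(beta) <- c(paste0("m", 1:5), paste0("w", 1:3))
  pos <- c(1000, 1500, 2000, 7000, 7500, 8000)
  bm <- beta_matrix(beta, rep("chr1", 6), pos)
  labels <- setNames(rep(c("mut", "wt"), c(5, 3)), colnames(beta))
  dmrs <- find_dmrs(bm, labels, group1 = "mut", max_gap = 1000)
  expect_identical(nrow(dmrs), 2L)
  expect_identical(dmrs$start, c(1000L, 7000L))
  # with a permissive gap the two blocks merge
  merged <- find_dmrs(bm, labels, group1 = "mut", max_gap = 10000)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$probe_count, 6L)
})

test_that("DMR calls are invariant to sample order within groups", {
  sim <- simulate_methylation(n_probes = 4000, n_dmrs = 8, seed = 5)
  d1 <- find_dmrs(sim$beta, sim$labels, group1 = "mutant")
  perm <- c(3, 1, 5, 2, 4, 8, 6, 7)   # shuffle within each group
  bm2 <- beta_matrix(sim$beta$beta[, perm], sim$beta$probes$chrom,
                     sim$beta$probes$pos)
  d2 <- find_dmrs(bm2, sim$labels, group1 = "mutant")
  expect_identical(d1, d2)
})

test_that("DMR BED output is zero-based half-open", {
  dmrs <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                     probe_count = 3L, direction = "hypo",
                     mean_delta_beta = -0.4, min_p = 1e-6)
  path <- tempfile(fileext = ".bed")
  write_dmr_bed(dmrs, path)
  bed <- read.delim(path, header = FALSE)
  expect_identical(bed$V2, 999L)
  expect_identical(bed$V3, 2000L)
})
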