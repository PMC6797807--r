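test_that("cosine similarity is 1 on identical and 0 on disjoint profiles", {
  v <- c(rep(2, 48), rep(0, 48))
  w <- c(rep(0, 48), rep(3, 48))
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(v, w), 0)
  expect_equal(cosine_similarity(v, 10 * v), 1)   # scale invariance
  expect_error(cosine_similarity(v, numeric(96)), "zero-norm")
})

test_that("a single-signature catalog is recovered almost exactly", {
  sigs <- test_sigs()
  s7 <- sigs[, "Signature.7", drop = FALSE]
  counts <- round(1000 * s7[, 1])
  cat7 <- structure(as.integer(counts), names = sbs_channels(),
                    class = "catalog96", sample_id = "pure7",
                    total = sum(as.integer(counts)), n_excluded = 0L)
  f <- fit_exposures(cat7, s7)
  expect_equal(unname(f$exposures), 1000, tolerance = 0.01)
  expect_lt(f$residual_norm, 2)  # rounding only
  # identity-like case: the catalog's own normalized profile as the only
  # signature returns the catalog total with zero residual
  own <- matrix(as.integer(counts) / sum(counts), ncol = 1,
                dimnames = list(sbs_channels(), "self"))
  fo <- fit_exposures(cat7, as_signature_matrix(own))
  expect_equal(unname(fo$exposures), sum(counts), tolerance = 1e-6)
  expect_equal(fo$residual_norm, 0, tolerance = 1e-9)
})

test_that("an exact two-signature mixture is recovered within rounding", {
  sigs <- test_sigs()
  S2 <- sigs[, c("Signature.1", "Signature.5")]
  counts <- round(600 * S2[, 1] + 400 * S2[, 2])
  cat2 <- structure(as.integer(counts), names = sbs_channels(),
                    class = "catalog96", sample_id = "mix",
                    total = sum(as.integer(counts)), n_excluded = 0L)
  f <- fit_exposures(cat2, S2)
  expect_equal(unname(f$exposures), c(600, 400), tolerance = 0.01)
  # grid-search oracle agrees to within one grid step
  o <- grid_nnls_oracle(as.integer(counts), S2[, 1], S2[, 2], emax = 1200)
  expect_lte(abs(o$e1 - f$exposures[1]), 1)
  expect_lte(abs(o$e2 - f$exposures[2]), 1)
})

test_that("stored reconstruction and residual are internally consistent", {
  sigs <- test_sigs()
  sim <- simulate_catalog(c(Signature.1 = 0.5, Signature.7 = 0.5), 500,
                          sigs, seed = 3)
  f <- fit_exposures(sim$catalog, sigs[, 1:10])
  expect_equal(unname(f$reconstructed),
               as.numeric(unclass(sigs[, 1:10]) %*% f$exposures))
  expect_equal(f$residual_norm,
               sqrt(sum((as.numeric(sim$catalog) - f$reconstructed)^2)))
  expect_true(all(f$exposures >= 0))
})

test_that("fitting rejects empty catalogs and mismatched labels", {
  sigs <- test_sigs()
  m <- data.frame(ref = "C", alt = "A", context5 = "A", context3 = "A")
  cat0 <- suppressWarnings(build_catalog(m[0, ], "empty"))
  expect_error(fit_exposures(cat0, sigs), "empty catalog")
  relabeled <- structure(rep(1L, 96), names = rev(sbs_channels()),
                         class = "catalog96", sample_id = "x",
                         total = 96L, n_excluded = 0L)
  expect_error(fit_exposures(relabeled, sigs), "labels")
})

test_that("bootstrap exceedance separates dominant from absent signatures", {
  sigs <- test_sigs()
  sim <- simulate_catalog(c(Signature.7 = 1), 10000, sigs, seed = 5)
  sub <- sigs[, c("Signature.1", "Signature.5", "Signature.7")]
  b <- bootstrap_confidence(sim$catalog, sub, n_boot = 200, seed = 9)
  expect_equal(unname(b$exceedance_prob["Signature.7"]), 1.0)
  expect_lt(b$exceedance_prob["Signature.1"], 0.1)
  expect_lt(b$exceedance_prob["Signature.5"], 0.1)
})

test_that("one-replicate bootstrap yields 0/1 probabilities and small samples warn", {
  sigs <- test_sigs()
  sim <- simulate_catalog(c(Signature.1 = 1), 200, sigs, seed = 2)
  b1 <- bootstrap_confidence(sim$catalog, sigs[, 1:5], n_boot = 1, seed = 1)
  expect_true(all(b1$exceedance_prob %in% c(0, 1)))
  expect_error(bootstrap_confidence(sim$catalog, sigs[, 1:5], n_boot = 0),
               "n_boot")
  small <- simulate_catalog(c(Signature.1 = 1), 30, sigs, seed = 2)
  expect_warning(bootstrap_confidence(small$catalog, sigs[, 1:5],
                                      n_boot = 5, seed = 1), "fewer than 50")
})

test_that("identical seeds reproduce the bootstrap byte for byte", {
  sigs <- test_sigs()
  sim <- simulate_catalog(c(Signature.1 = 0.6, Signature.7 = 0.4), 800,
                          sigs, seed = 21)
  b1 <- bootstrap_confidence(sim$catalog, sigs[, 1:8], n_boot = 50, seed = 77)
  b2 <- bootstrap_confidence(sim$catalog, sigs[, 1:8], n_boot = 50, seed = 77)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
})

test_that("selection retains planted signatures and k = K reduces to the full fit", {
  sigs <- test_sigs()
  truth <- c(Signature.1 = 0.3, Signature.5 = 0.5, Signature.7 = 0.2)
  sim <- simulate_catalog(truth, 1500, sigs, seed = 123)
  f <- fit_signatures(sim$catalog, sigs, k = 3, n_boot = 100, seed = 5)
  expect_setequal(f$selected, names(truth))

  sub <- sigs[, 1:4]
  fK <- fit_signatures(sim$catalog, sub, k = 4, n_boot = 20, seed = 5)
  expect_equal(fK$fit$exposures[colnames(sub)],
               fit_exposures(sim$catalog, sub)$exposures)

  pure <- simulate_catalog(c(Signature.7 = 1), 2000, sigs, seed = 4)
  f1 <- fit_signatures(pure$catalog, sigs, k = 1, n_boot = 50, seed = 6)
  expect_identical(f1$selected, "Signature.7")
})

test_that("bootstrap exceedance is monotone in the true exposure fraction", {
  sigs <- test_sigs()
  ladder <- c(0, 0.02, 0.05, 0.10, 0.20)
  seeds <- 1:5
  exceed <- sapply(ladder, function(fr) {
    mean(sapply(seeds, function(s) {
      f <- c(Signature.7 = fr, Signature.5 = 1 - fr)
      f <- f[f > 0]
      sim <- simulate_catalog(f, 2000, sigs, seed = s)
      b <- bootstrap_confidence(sim$catalog,
                                sigs[, c("Signature.1", "Signature.5",
                                         "Signature.7")],
                                n_boot = 100, seed = s + 500)
      b$exceedance_prob["Signature.7"]
    }))
  })
  expect_true(all(diff(exceed) >= 0))
  expect_lt(exceed[1], 0.5)
  expect_equal(exceed[5], 1.0)
})

test_that("sigfit methods expose the fitted model consistently", {
  sigs <- test_sigs()
  sim <- simulate_catalog(c(Signature.1 = 0.6, Signature.5 = 0.4), 900,
                          sigs, seed = 31)
  f <- fit_signatures(sim$catalog, sigs[, 1:6], k = 2, n_boot = 50, seed = 8)
  expect_identical(coef(f), f$fit$exposures)
  expect_equal(unname(as.numeric(sim$catalog) - fitted(f)),
               unname(residuals(f)))
  s <- summary(f)
  expect_s3_class(s, "summary.sigfit")
  expect_identical(sum(s$table$selected), 2L)
  sims <- simulate(f, nsim = 2, seed = 99)
  expect_length(sims, 2)
  expect_identical(attr(sims[[1]], "total"), attr(sim$catalog, "total"))
  expect_output(print(f), "selected")
})
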