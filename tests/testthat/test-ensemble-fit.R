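test_that("energy filter is inclusive at the cutoff and preserves order", {
  m <- matrix(rnorm(16), 4, 4,
              dimnames = list(paste0("3J(N,C", 1:4, ")"), c("a", "b", "c", "d")))
  lib <- conformerLibrary("x", m, c(a = 0, b = 4.9, c = 5.0, d = 5.1))
  kept <- filterConformers(lib, 5.0)
  expect_identical(conformerLabels(kept), c("a", "b", "c"))  # <= 5 inclusive
  expect_identical(conformerLabels(filterConformers(lib, Inf)),
                   conformerLabels(lib))
  allzero <- conformerLibrary("x", m, c(a = 0, b = 0, c = 0, d = 0))
  expect_identical(conformerLabels(filterConformers(allzero, 5)),
                   conformerLabels(allzero))
  expect_error(filterConformers(lib, -1), "cutoff")
})

test_that("a pure endpoint is recovered exactly", {
  lib <- tinyLibrary()
  jexp <- abs(couplingMatrix(lib)[, "A"])
  f <- fitPopulations(asRecords(jexp), lib)
  expect_equal(unname(populations(f)["A"]), 1, tolerance = 1e-6)
  expect_lt(maeHz(f), 1e-8)
  expect_false(isDegenerate(f))
})

test_that("two-conformer mixtures match an independent fine-grid oracle", {
  lib <- tinyLibrary()
  jm <- couplingMatrix(lib)
  set.seed(41)
  for (rep in 1:20) {
    x <- stats::runif(1)
    jexp <- abs(as.numeric(jm %*% c(x, 1 - x))) +
      abs(stats::rnorm(nrow(jm), 0, 0.2))
    names(jexp) <- rownames(jm)
    f <- fitPopulations(jexp, lib)
    oracle <- bruteTwoConformerMae(jexp, jm, step = 1e-3)
    expect_lt(abs(unname(populations(f)["A"]) - oracle), 2e-3)
  }
})

test_that("noiseless 4-conformer mixtures are recovered to 0.01", {
  sim <- simulateEnsemble(nConformers = 4, populations = c(0.5, 0.3, 0.2, 0),
                          noiseSigma = 0, seed = 7)
  f <- fitPopulations(sim$experimental, sim$library)
  expect_lt(max(abs(populations(f) - sim$truth$populations)), 0.01)
})

test_that("vertex solutions never beat the optimum", {
  set.seed(42)
  for (seed in 1:5) {
    sim <- simulateEnsemble(nConformers = 3, populations = "random",
                            noiseSigma = 0.3, seed = seed)
    f <- fitPopulations(sim$experimental, sim$library)
    jm <- couplingMatrix(sim$library)
    jexp <- couplingVector(sim$experimental, "synthetic")[rownames(jm)]
    for (k in seq_len(ncol(jm))) {
      vert <- mean(abs(jexp - abs(jm[, k])))
      expect_lte(f@details$optMae, vert + 1e-9)
    }
  }
})

test_that("adding a conformer never increases the optimal MAE", {
  set.seed(43)
  sim <- simulateEnsemble(nConformers = 4, populations = "random",
                          noiseSigma = 0.4, seed = 99)
  lib4 <- sim$library
  jexp <- couplingVector(sim$experimental, "synthetic")
  m <- couplingMatrix(lib4)
  lib3 <- conformerLibrary("synthetic", m[, 1:3],
                           relativeEnergies(lib4)[1:3])
  f3 <- fitPopulations(jexp, lib3)
  f4 <- fitPopulations(jexp, lib4)
  expect_lte(f4@details$optMae, f3@details$optMae + 1e-9)
})

test_that("conformer order permutes the population map but not the MAE", {
  sim <- simulateEnsemble(nConformers = 4, populations = c(0.4, 0.3, 0.2, 0.1),
                          noiseSigma = 0.2, seed = 5)
  jexp <- couplingVector(sim$experimental, "synthetic")
  f <- fitPopulations(jexp, sim$library)
  m <- couplingMatrix(sim$library)
  perm <- c(3, 1, 4, 2)
  libP <- conformerLibrary("synthetic", m[, perm],
                           relativeEnergies(sim$library)[perm])
  fP <- fitPopulations(jexp, libP)
  expect_equal(maeHz(fP), maeHz(f), tolerance = 1e-6)
  expect_equal(populations(fP)[names(populations(f))], populations(f),
               tolerance = 0.02)
})

test_that("identical conformer columns trigger degeneracy warning + flag", {
  m <- cbind(A = c(5, -2, 1), B = c(5, -2, 1), C = c(0.5, 3, -1))
  rownames(m) <- c("3J(NH,H1)", "2J(N,H1)", "1J(N,C1)")
  lib <- conformerLibrary("x", m, c(A = 0, B = 1, C = 2))
  jexp <- stats::setNames(abs(m %*% c(0.5, 0.0, 0.5))[, 1], rownames(m))
  expect_warning(f <- fitPopulations(jexp, lib), "identical coupling vectors")
  expect_true(isDegenerate(f))
  # maximum-entropy reporting splits the identical pair evenly
  p <- populations(f)
  expect_equal(unname(p["A"]), unname(p["B"]), tolerance = 0.02)
})

test_that("simplex-recovery property: seeded replicates at sigma = 0.2", {
  # 4 conformers x 8 informative couplings; mean absolute population
  # error per component over 100 seeded replicates must stay small
  errs <- vapply(1:100, function(seed) {
    sim <- simulateEnsemble(nConformers = 4, populations = "random",
                            noiseSigma = 0.2, seed = seed)
    f <- fitPopulations(sim$experimental, sim$library)
    mean(abs(populations(f) - sim$truth$populations))
  }, numeric(1))
  expect_lte(mean(errs), 0.10)
})

test_that("grid and refined solvers agree on 3-4 conformer instances", {
  nIdentifiable <- 0L
  for (seed in c(3, 14, 15, 92, 65)) {
    k <- if (seed %% 2) 3 else 4
    sim <- simulateEnsemble(nConformers = k, populations = "random",
                            noiseSigma = 0.25, seed = seed)
    f <- fitPopulations(sim$experimental, sim$library)
    d <- f@details
    # objective values always agree closely; the argmins are compared
    # only when the optimum is identifiable (not a flat valley)
    expect_lt(abs(d$gridMae - d$optMae), 0.01)
    if (!isDegenerate(f)) {
      nIdentifiable <- nIdentifiable + 1L
      expect_lt(max(abs(d$gridOptimum - d$refinedOptimum)), 0.02)
    }
  }
  expect_gte(nIdentifiable, 1L)
})

test_that("underdetermined and empty fits are handled", {
  lib <- tinyLibrary()
  expect_error(fitPopulations(c("9J(X,Y)" = 1), lib), "all couplings excluded")
  one <- conformerLibrary("x", couplingMatrix(lib)[, 1, drop = FALSE],
                          c(A = 0))
  expect_error(fitPopulations(asRecords(abs(couplingMatrix(lib)[, 1])), one),
               "at least 2 conformers")
})

test_that("scan sensitivity equals per-column range", {
  sc <- data.frame(phi = c(-180, -60, 60),
                   "3J(NH,H1)" = c(-2, 3, 11),
                   "1J(N,Ci)" = c(4, 4, 4), check.names = FALSE)
  s <- scanSensitivity(sc)
  expect_equal(unname(s["3J(NH,H1)"]), 13)   # 11 - (-2)
  expect_equal(unname(s["1J(N,Ci)"]), 0)
  expect_error(scanSensitivity(sc[1, ]), "at least 2")

  # Karplus scan range equals direct evaluation on the same grid
  model <- list("3J(NH,H1)" = list(params = basicKarplus(7, -1, 1), phase = 0))
  sc2 <- simulatePhiScan(model, step = 20)
  direct <- karplusJ(sc2$phi, basicKarplus(7, -1, 1))
  expect_equal(unname(scanSensitivity(sc2)["3J(NH,H1)"]),
               max(direct) - min(direct))
})

test_that("coupling informativeness ranking matches brute-force spreads", {
  lib <- tinyLibrary()
  r <- rankCouplingInformativeness(lib)
  m <- couplingMatrix(lib)
  spread <- apply(m, 1, function(v) max(v) - min(v))
  expect_equal(r$spread, unname(sort(spread, decreasing = TRUE)))
  expect_equal(r$id[1], names(which.max(spread)))
  # constant couplings rank last
  m2 <- rbind(m, "3J(N,Cm)" = c(1.4, 1.4))
  lib2 <- conformerLibrary("x", m2, relativeEnergies(lib))
  r2 <- rankCouplingInformativeness(lib2)
  expect_equal(r2$id[nrow(r2)], "3J(N,Cm)")
})
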