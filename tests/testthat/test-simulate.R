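# Simulation generators: determinism, exact correlations by construction,
# censoring mechanics, and imputation.

test_that("perfect pairs hit exactly +/-1 across seeds", {
  for (s in c(1, 7, 19, 101, 555)) {
    p <- simPerfectPair(n = 400, seed = s)
    expect_equal(iciKt(p$x, p$y)$tau, 1)
    n <- simPerfectPair(n = 400, direction = "negative", seed = s)
    expect_equal(iciKt(n$x, n$y)$tau, -1)
  }
})

test_that("generators are pure functions of seed", {
  expect_identical(simPerfectPair(n = 100, seed = 3),
                   simPerfectPair(n = 100, seed = 3))
  expect_identical(simRealisticPair(n = 100, seed = 3),
                   simRealisticPair(n = 100, seed = 3))
  expect_identical(simLodCohort(nSamples = 5, nFeatures = 40, seed = 3),
                   simLodCohort(nSamples = 5, nFeatures = 40, seed = 3))
  p <- simPerfectPair(n = 100, seed = 3)
  expect_identical(simInsertLowMissing(p, 20, seed = 4),
                   simInsertLowMissing(p, 20, seed = 4))
  # seeding does not disturb the caller's RNG stream
  set.seed(1); a <- rnorm(1)
  set.seed(1); invisible(simPerfectPair(n = 10, seed = 99)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("outlier insertion perturbs the configured point count", {
  p <- simPerfectPair(n = 1000, seed = 2)
  o <- simAddOutliers(p, fraction = 0.005, seed = 5)
  expect_equal(sum(o$y != p$y), 5)
  expect_identical(simAddOutliers(p, fraction = 0), p)
  expect_warning(simAddOutliers(simPerfectPair(n = 100, seed = 1),
                                fraction = 0.005), "no outliers")
})

test_that("outliers disturb Pearson more than Kendall on the negative pair", {
  set.seed(4)
  devP <- devK <- numeric(10)
  for (i in 1:10) {
    p <- simPerfectPair(n = 1000, direction = "negative", seed = 40 + i)
    o <- simAddOutliers(p, fraction = 0.005, seed = 140 + i)
    devP[i] <- abs(cor(o$x, o$y) - cor(p$x, p$y))
    devK[i] <- abs(cor(o$x, o$y, method = "kendall") -
                   cor(p$x, p$y, method = "kendall"))
  }
  expect_gt(mean(devP), mean(devK))
})

test_that("low-end missingness lands in the bottom half of one vector", {
  p <- simPerfectPair(n = 1000, seed = 6)
  m <- simInsertLowMissing(p, 250, seed = 7)
  expect_equal(sum(is.na(m$y)), 250)
  expect_equal(sum(is.na(m$x)), 0)
  expect_true(all(which(is.na(m$y)) %in% order(p$y)[1:500]))
  # negative pair: censored values are still that vector's lowest
  pn <- simPerfectPair(n = 1000, direction = "negative", seed = 6)
  mn <- simInsertLowMissing(pn, 250, seed = 7)
  expect_true(all(which(is.na(mn$y)) %in% order(pn$y)[1:500]))
  expect_error(simInsertLowMissing(p, 500), "below half")
  expect_identical(simInsertLowMissing(p, 0), p)
})

test_that("cutoff censoring is monotone and exact", {
  p <- list(x = c(0.5, 1.2, 3.0), y = c(2, 0.1, 0.9))
  cc <- censorCutoff(p, 1.0)
  expect_equal(cc$x, c(NA, 1.2, 3.0))
  expect_equal(cc$y, c(2, NA, NA))
  expect_identical(censorCutoff(p, 0), p)
  # zero-imputation variant
  expect_equal(censorCutoff(p, 1.0, impute = "zero")$x, c(0, 1.2, 3.0))
  # monotone missingness over the cutoff grid
  r <- simRealisticPair(n = 500, seed = 11)
  miss <- sapply(seq(0, 1.5, 0.1), function(ct) {
    cc <- censorCutoff(r, ct)
    sum(is.na(cc$x)) + sum(is.na(cc$y))
  })
  expect_true(all(diff(miss) >= 0))
  expect_equal(length(miss), 16)
})

test_that("random censoring hits the requested number of cells", {
  r <- simRealisticPair(n = 300, seed = 13)
  for (k in seq(0, 300, 50)) {
    cr <- censorRandom(r, k, seed = 17)
    expect_equal(sum(is.na(cr$x)) + sum(is.na(cr$y)), k)
  }
  expect_identical(censorRandom(r, 0), r)
  expect_error(censorRandom(r, 601), "exceeds")
})

test_that("realistic pairs start near 0.90 and collapse to 1 without noise", {
  p <- simRealisticPair(n = 1000, seed = 23)
  expect_gt(iciKt(p$x, p$y)$tau, 0.86)
  expect_lt(iciKt(p$x, p$y)$tau, 0.94)
  p0 <- simRealisticPair(n = 200, noiseSd = 0, seed = 23)
  expect_equal(iciKt(p0$x, p0$y)$tau, 1)
})

test_that("the LOD cohort has the configured shape and noise behavior", {
  m <- simLodCohort(nSamples = 10, nFeatures = 100, seed = 31)
  expect_equal(dim(m), c(100, 10))
  m0 <- simLodCohort(nSamples = 4, nFeatures = 50, noiseSd = 0, seed = 31)
  expect_true(all(m0 == m0[, 1]))
})

test_that("dynamic-range censoring grows with the level", {
  m <- simLodCohort(nSamples = 30, nFeatures = 500, seed = 37)
  miss <- sapply(c(0.5, 1, 1.5), function(lev)
    sum(is.na(censorDynamicRange(m, lev, seed = 41))))
  expect_true(all(diff(miss) > 0))
  expect_equal(sum(is.na(censorDynamicRange(m, 0, seed = 41))), 0)
})

test_that("half-minimum imputation fills every gap at half the minimum", {
  m <- simLodCohort(nSamples = 5, nFeatures = 100, seed = 43)
  cm <- censorDynamicRange(m, 1, seed = 47)
  mn <- min(cm, na.rm = TRUE)
  im <- halfMinImpute(cm)
  expect_false(anyNA(im))
  expect_true(all(im[is.na(cm)] == mn / 2))
  expect_identical(halfMinImpute(m), m)
  expect_error(halfMinImpute(matrix(NA_real_, 2, 2)), "all-missing")
})
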