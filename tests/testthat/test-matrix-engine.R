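# All-pairs engine: symmetry, chunked determinism, tau-max scaling,
# completeness compositing, baselines, and the long-format round trip.

test_that("identical samples give a unit tau matrix", {
  v <- rlnorm(30)
  m <- cbind(a = v, b = v, c = v)
  cs <- iciKtMatrix(m)
  expect_true(all(tauMatrix(cs) == 1))
  expect_true(all(completenessMatrix(cs) == 1))
})

test_that("matrix cells equal the pairwise function, and are symmetric", {
  m <- smallCohort(nFeatures = 40, nSamples = 5, seed = 8)
  m[sample(length(m), 30)] <- NA
  cs <- iciKtMatrix(m, perspective = "global")
  tau <- tauMatrix(cs)
  expect_equal(tau, t(tau))
  for (p in list(c(1, 2), c(2, 5), c(3, 4))) {
    r <- iciKt(m[, p[1]], m[, p[2]], perspective = "global")
    expect_equal(tau[p[1], p[2]], r$tau, tolerance = 1e-12)
    expect_equal(completenessMatrix(cs)[p[1], p[2]], r$completeness)
    expect_equal(pValueMatrix(cs)[p[1], p[2]], r$p_value, tolerance = 1e-12)
  }
  # diagonal computed: self completeness is the per-sample present fraction
  expect_equal(completenessMatrix(cs)[2, 2], mean(!is.na(m[, 2])))
})

test_that("results are identical for 1, 2 and 8 workers", {
  m <- smallCohort(nFeatures = 50, nSamples = 6, seed = 4)
  m[sample(length(m), 40)] <- NA
  cs1 <- iciKtMatrix(m, cores = 1)
  cs2 <- iciKtMatrix(m, cores = 2)
  cs8 <- iciKtMatrix(m, cores = 8)
  expect_identical(tauMatrix(cs1), tauMatrix(cs2))
  expect_identical(tauMatrix(cs1), tauMatrix(cs8))
  expect_identical(pValueMatrix(cs1), pValueMatrix(cs8))
})

test_that("tau-max scaling divides by one common factor and preserves order", {
  m <- smallCohort(nFeatures = 50, nSamples = 5, seed = 21)
  m[m < quantile(m, 0.15)] <- NA     # induce shared-missing ties
  raw <- iciKtMatrix(m, scaleMax = FALSE)
  scl <- iciKtMatrix(m, scaleMax = TRUE)
  mx <- max(tauMaxMatrix(raw)[upper.tri(tauMaxMatrix(raw))], na.rm = TRUE)
  expect_equal(tauMatrix(scl), tauMatrix(raw) / mx, tolerance = 1e-12)
  ord1 <- order(tauMatrix(raw)[upper.tri(tauMatrix(raw))])
  ord2 <- order(tauMatrix(scl)[upper.tri(tauMatrix(scl))])
  expect_identical(ord1, ord2)
  # no ties, no missing: scaling is a no-op
  clean <- matrix(rnorm(80), 20, 4,
                  dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(tauMatrix(iciKtMatrix(clean, scaleMax = TRUE)),
               tauMatrix(iciKtMatrix(clean)), tolerance = 1e-12)
})

test_that("completeness compositing shrinks tau element-wise", {
  m <- smallCohort(nFeatures = 50, nSamples = 5, seed = 13)
  m[sample(length(m), 50)] <- NA
  cs <- iciKtMatrix(m)
  comp <- compositeCorrelation(cs)
  expect_true(all(abs(comp) <= abs(tauMatrix(cs)) + 1e-12, na.rm = TRUE))
  # completeness of one means identity
  clean <- iciKtMatrix(smallCohort(nFeatures = 30, nSamples = 4, seed = 2))
  expect_equal(compositeCorrelation(clean), tauMatrix(clean))
})

test_that("baseline variants implement their transforms", {
  m <- smallCohort(nFeatures = 40, nSamples = 5, seed = 17)
  m <- 10^m                                  # strictly positive abundances
  # without missingness, zero-replacement is irrelevant
  expect_equal(tauMatrix(baselineCorrelation(m, "pearson_base")),
               tauMatrix(baselineCorrelation(m, "pearson_base_nozero")))
  # kt_base on complete data equals the ICI-Kt engine
  expect_equal(tauMatrix(baselineCorrelation(m, "kt_base")),
               tauMatrix(iciKtMatrix(m)), tolerance = 1e-12)
  # log transform of identical monotone vectors
  m2 <- cbind(a = c(1, 10, 100), b = c(1, 10, 100))
  expect_equal(tauMatrix(baselineCorrelation(m2, "pearson_log1p"))[1, 2], 1)
  # a zero under pearson_log is dropped (log 0 -> missing)
  m3 <- cbind(a = c(0, 2, 4, 8), b = c(1, 2, 4, 8))
  bl <- baselineCorrelation(m3, "pearson_log")
  expect_equal(tauMatrix(bl)[1, 2],
               cor(log(c(2, 4, 8)), log(c(2, 4, 8))), tolerance = 1e-12)
  # pearson_base really replaces missing by zero
  m4 <- cbind(a = c(NA, 2, 4, 8), b = c(1, 2, 4, 8))
  expect_equal(tauMatrix(baselineCorrelation(m4, "pearson_base"))[1, 2],
               cor(c(0, 2, 4, 8), c(1, 2, 4, 8)), tolerance = 1e-12)
})

test_that("long format round trips losslessly", {
  m <- smallCohort(nFeatures = 30, nSamples = 4, seed = 9)
  m[sample(length(m), 15)] <- NA
  cs <- iciKtMatrix(m)
  lg <- correlationLong(cs, diagonal = TRUE)
  expect_equal(nrow(lg), 4 * 5 / 2)
  back <- correlationSetFromLong(lg, perspective = "global")
  expect_equal(tauMatrix(back), tauMatrix(cs))
  expect_equal(completenessMatrix(back), completenessMatrix(cs))
  # two samples: one off-diagonal row
  cs2 <- iciKtMatrix(m[, 1:2])
  expect_equal(nrow(correlationLong(cs2, diagonal = FALSE)), 1)
})

test_that("undefined pairs propagate as NA cells with a warning", {
  m <- cbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4), c = c(2, 1, 4, 3))
  rownames(m) <- paste0("f", 1:4)
  expect_warning(cs <- iciKtMatrix(m), "undefined")
  expect_true(is.na(tauMatrix(cs)["a", "b"]))
  expect_false(is.na(tauMatrix(cs)["b", "c"]))
})
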