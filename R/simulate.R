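# Simulated datasets for validating the ICI-Kt methodology: perfectly
# correlated pairs with controlled noise, outliers and low-end missingness;
# a realistic noisy pair; left-censoring and random-censoring operators;
# and a multi-sample cohort with per-sample dynamic-range censoring.
#
# Every generator is a pure function of its parameters and `seed`
# (seeding via withr::with_seed leaves the caller's RNG state untouched).

.withSeed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Perfectly correlated simulated sample pair
#'
#' Draws `n` values from a log-normal distribution and sorts them
#' ascending (`x`); the partner `y` is `x` plus uniform noise, re-sorted so
#' the pair keeps a Kendall correlation of exactly +1.  The negative
#' direction negates the re-sorted partner, leaving its values in
#' descending order: the pair then starts at -1 for Kendall *and*
#' (essentially) for Pearson, so both correlation families see a perfectly
#' anti-correlated pair.  Default parameters: log-normal meanlog 1, sdlog
#' 0.5 on the natural-log scale, n = 1000, uniform noise on
#' `[-0.5, 0.5]`.
#'
#' @param n number of features per sample.
#' @param meanlog,sdlog log-normal parameters (natural-log scale).
#' @param noiseRange range of the uniform noise added to `y`.
#' @param direction `"positive"` (tau = 1) or `"negative"` (tau = -1).
#' @param seed integer seed; the generator is deterministic given it.
#' @return List with elements `x`, `y` and `direction`.
#' @examples
#' p <- simPerfectPair(n = 100, seed = 7)
#' iciKt(p$x, p$y)$tau  # exactly 1
#' @export
simPerfectPair <- function(n = 1000, meanlog = 1, sdlog = 0.5,
                           noiseRange = c(-0.5, 0.5),
                           direction = c("positive", "negative"),
                           seed = NULL) {
  direction <- match.arg(direction)
  if (n < 2) stop("need n >= 2")
  .withSeed(seed, {
    x <- sort(rlnorm(n, meanlog, sdlog))
    y <- sort(x + runif(n, noiseRange[1], noiseRange[2]))
    if (direction == "negative") y <- -y
    list(x = x, y = y, direction = direction)
  })
}

#' Add high-end outlier points to a simulated pair
#'
#' Replaces the noise of a small fraction of points at the high end of the
#' distribution with uniform noise plus a log-normal draw (defaults:
#' meanlog 1.2, sdlog 0.1), a combined variance source added to the
#' original values.  With the default 0.5% fraction and n = 1000 this
#' perturbs 5 points.
#'
#' @param pair a pair from [simPerfectPair()].
#' @param fraction fraction of points made outliers (default 0.005).
#' @param meanlog,sdlog log-normal parameters of the outlier shift.
#' @param noiseRange uniform component of the outlier shift.
#' @param seed integer seed.
#' @return The pair with perturbed `y`.
#' @export
simAddOutliers <- function(pair, fraction = 0.005, meanlog = 1.2,
                           sdlog = 0.1, noiseRange = c(-0.5, 0.5),
                           seed = NULL) {
  n <- length(pair$x)
  nOut <- floor(fraction * n)
  if (fraction > 0 && nOut < 1) {
    warning("fraction * n < 1: no outliers inserted", call. = FALSE)
    return(pair)
  }
  if (nOut == 0) return(pair)
  .withSeed(seed, {
    idx <- order(pair$x, decreasing = TRUE)[seq_len(nOut)]
    pair$y[idx] <- pair$y[idx] +
      runif(nOut, noiseRange[1], noiseRange[2]) + rlnorm(nOut, meanlog, sdlog)
    pair
  })
}

#' Insert low-end missing values into one vector of a pair
#'
#' Sets `nMissing` randomly chosen positions among the lowest half of the
#' target vector's values to missing, emulating left-censorship of one
#' analytical sample.  At most `floor(n/2) - 1` values may be removed
#' (499 of 1000 at the default size).
#'
#' @param pair a simulated pair.
#' @param nMissing number of values to censor.
#' @param target which vector receives the missingness (`"y"` default).
#' @param seed integer seed.
#' @return The pair with `NA` in the censored positions.
#' @export
simInsertLowMissing <- function(pair, nMissing, target = c("y", "x"),
                                seed = NULL) {
  target <- match.arg(target)
  n <- length(pair[[target]])
  if (nMissing >= n / 2)
    stop("nMissing must be below half the vector length")
  if (nMissing == 0) return(pair)
  .withSeed(seed, {
    pool <- order(pair[[target]])[seq_len(floor(n / 2))]
    idx <- sample(pool, nMissing)
    pair[[target]][idx] <- NA_real_
    pair
  })
}

#' Realistic noisy simulated sample pair
#'
#' A base sample drawn from a log-normal distribution (meanlog 1, sdlog
#' 0.5) and a partner with added normal noise (sd 0.2): the pair starts at
#' an ICI-Kt correlation of about 0.90 with no missing values.
#'
#' @inheritParams simPerfectPair
#' @param noiseSd standard deviation of the additive normal noise.
#' @return List with elements `x` (base) and `y` (noised).
#' @export
simRealisticPair <- function(n = 1000, meanlog = 1, sdlog = 0.5,
                             noiseSd = 0.2, seed = NULL) {
  .withSeed(seed, {
    x <- rlnorm(n, meanlog, sdlog)
    y <- x + rnorm(n, 0, noiseSd)
    list(x = x, y = y)
  })
}

#' Censor values below an intensity cutoff
#'
#' Sets every value below `cutoff` to missing (or to zero), in each vector
#' of a pair, each cell of a matrix, or the values of an
#' [AbundanceMatrix-class].  A cutoff below the data minimum leaves the
#' input unchanged.
#'
#' @param x a pair list (elements `x`, `y`), numeric matrix, or
#'   [AbundanceMatrix-class].
#' @param cutoff intensity threshold.
#' @param impute `"na"` (missing, default) or `"zero"`.
#' @return Object of the same shape with censored cells.
#' @export
censorCutoff <- function(x, cutoff, impute = c("na", "zero")) {
  impute <- match.arg(impute)
  repl <- if (impute == "na") NA_real_ else 0
  cens <- function(v) { v[!is.na(v) & v < cutoff] <- repl; v }
  if (is.list(x) && !is.data.frame(x) && !is(x, "AbundanceMatrix")) {
    x$x <- cens(x$x); x$y <- cens(x$y)
    x
  } else if (is(x, "AbundanceMatrix")) {
    AbundanceMatrix(cens(abundanceValues(x)))
  } else {
    cens(x)
  }
}

#' Censor randomly chosen positions
#'
#' Sets `nPositions` uniformly random cells of the pair's 2 x n matrix (or
#' of a matrix) to missing or zero, emulating missingness that carries no
#' left-censorship signal.
#'
#' @inheritParams censorCutoff
#' @param nPositions number of cells to censor.
#' @param seed integer seed.
#' @return Object of the same shape with censored cells.
#' @export
censorRandom <- function(x, nPositions, impute = c("na", "zero"),
                         seed = NULL) {
  impute <- match.arg(impute)
  repl <- if (impute == "na") NA_real_ else 0
  if (is.list(x) && !is.data.frame(x) && !is(x, "AbundanceMatrix")) {
    n <- length(x$x)
    if (nPositions > 2 * n)
      stop("nPositions exceeds the number of cells")
    if (nPositions == 0) return(x)
    .withSeed(seed, {
      idx <- sample(2L * n, nPositions)
      xi <- idx[idx <= n]; yi <- idx[idx > n] - n
      x$x[xi] <- repl; x$y[yi] <- repl
      x
    })
  } else {
    m <- if (is(x, "AbundanceMatrix")) abundanceValues(x) else x
    if (nPositions > length(m))
      stop("nPositions exceeds the number of cells")
    if (nPositions > 0)
      m <- .withSeed(seed, { m[sample(length(m), nPositions)] <- repl; m })
    if (is(x, "AbundanceMatrix")) AbundanceMatrix(m) else m
  }
}

#' Simulated cohort with a common base sample and per-sample noise
#'
#' A base sample is drawn on the natural-log scale (normal with mean
#' `meanlog`, sd `sdlog`, i.e. a log-normal sample), per-sample normal
#' noise (sd `noiseSd`) is added on that scale, values are carried back to
#' natural space, and log10 is applied so the data represent orders of
#' magnitude of abundance.  The default emulates a 100-sample, 1000-feature
#' cohort with a shared underlying abundance profile, the test bed for
#' dynamic-range censoring.
#'
#' @param nSamples,nFeatures cohort dimensions.
#' @param meanlog,sdlog log-normal parameters of the base sample.
#' @param noiseSd per-sample log-scale noise sd; 0 gives identical samples.
#' @param log10Scale apply log10 to the natural-space values (default).
#' @param seed integer seed.
#' @return Numeric feature x sample matrix with dimnames.
#' @export
simLodCohort <- function(nSamples = 100, nFeatures = 1000, meanlog = 1,
                         sdlog = 0.5, noiseSd = 0.2, log10Scale = TRUE,
                         seed = NULL) {
  .withSeed(seed, {
    logBase <- rnorm(nFeatures, meanlog, sdlog)
    m <- vapply(seq_len(nSamples), function(j) {
      v <- exp(logBase + rnorm(nFeatures, 0, noiseSd))
      if (log10Scale) log10(v) else v
    }, numeric(nFeatures))
    dimnames(m) <- list(sprintf("feature_%04d", seq_len(nFeatures)),
                        sprintf("sample_%03d", seq_len(nSamples)))
    m
  })
}

#' Per-sample dynamic-range censoring
#'
#' For each sample, a censoring value is drawn as the sample minimum plus a
#' uniform draw on `[0, maxLevel]`; values below it become missing.  Levels
#' 0.5, 1 and 1.5 (on the log10 scale of [simLodCohort()]) represent low,
#' medium and high variability of the dynamic range across samples.
#'
#' @param m numeric feature x sample matrix (or
#'   [AbundanceMatrix-class]).
#' @param maxLevel upper bound of the per-sample censoring draw.
#' @param seed integer seed.
#' @return Censored object of the same class as the input.
#' @export
censorDynamicRange <- function(m, maxLevel, seed = NULL) {
  if (!is.numeric(maxLevel) || length(maxLevel) != 1 || maxLevel < 0)
    stop("maxLevel must be a single non-negative number")
  isAM <- is(m, "AbundanceMatrix")
  v <- if (isAM) abundanceValues(m) else m
  v <- .withSeed(seed, {
    for (j in seq_len(ncol(v))) {
      cut <- min(v[, j], na.rm = TRUE) + runif(1, 0, maxLevel)
      v[!is.na(v[, j]) & v[, j] < cut, j] <- NA_real_
    }
    v
  })
  if (isAM) AbundanceMatrix(v) else v
}

#' Half-minimum imputation
#'
#' Replaces every missing cell by half the smallest observed value in the
#' dataset, the conventional global imputation partner for Pearson
#' correlation after censoring.
#'
#' @param x numeric vector, matrix or [AbundanceMatrix-class].
#' @return Object of the same shape with no missing cells.
#' @export
halfMinImpute <- function(x) {
  v <- if (is(x, "AbundanceMatrix")) abundanceValues(x) else x
  if (all(is.na(v))) stop("cannot impute an all-missing dataset")
  v[is.na(v)] <- min(v, na.rm = TRUE) / 2
  if (is(x, "AbundanceMatrix")) AbundanceMatrix(v) else v
}
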