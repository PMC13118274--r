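# Pairwise ICI-Kt: reference brute-force census, closed-form statistics,
# and the fast sentinel + mergesort path.

.checkPair <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y))
    stop("x and y must be numeric vectors")
  if (length(x) != length(y))
    stop("x and y must have the same length")
  if (length(x) < 2)
    stop("need at least two x-y points")
}

# tie-group sizes in a vector when missing values are regarded as one
# shared tied value strictly below everything observed
.tieGroups <- function(v) {
  obs <- v[!is.na(v)]
  sizes <- as.numeric(table(obs))
  nmiss <- sum(is.na(v))
  if (nmiss >= 2) sizes <- c(sizes, nmiss)
  sizes[sizes >= 2]
}

.undefinedWarning <- function(reason) {
  warning(sprintf("undefined ICI-Kt correlation: %s", reason), call. = FALSE)
}

#' Brute-force pair census under the ICI concordance rules
#'
#' Reference O(n^2) enumeration of all unordered point pairs, classified by
#' the extended concordant/discordant definitions in which a
#' present-versus-missing comparison carries ordering information: a missing
#' value behaves as if it were below every observed value.  Eight rules
#' define concordance and eight discordance; pairs tied in a margin
#' (including missing-vs-missing) count toward that margin's tie total.
#'
#' @param x,y numeric vectors of equal length (>= 2); missing values as `NA`.
#' @param perspective `"local"` removes x-y points missing in *both* vectors
#'   before counting; `"global"` retains them as pairs tied in both margins.
#' @return A [PairCounts-class] census.
#' @examples
#' countPairsBruteforce(c(1, 2, NA), c(NA, 3, 2))
#' @seealso [iciKt()] for the equivalent O(n log n) computation.
#' @export
countPairsBruteforce <- function(x, y,
                                 perspective = c("local", "global")) {
  perspective <- match.arg(perspective)
  .checkPair(x, y)
  if (perspective == "local") {
    keep <- !(is.na(x) & is.na(y))
    x <- x[keep]; y <- y[keep]
    if (length(x) < 2)
      stop("fewer than two x-y points remain after removing jointly missing points")
  }
  n <- length(x)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  xi <- x[i]; xj <- x[j]; yi <- y[i]; yj <- y[j]
  nxi <- is.na(xi); nxj <- is.na(xj); nyi <- is.na(yi); nyj <- is.na(yj)

  x_gt <- !nxi & !nxj & xi > xj
  x_lt <- !nxi & !nxj & xi < xj
  y_gt <- !nyi & !nyj & yi > yj
  y_lt <- !nyi & !nyj & yi < yj

  concordant <-
    (x_gt & y_gt) | (x_lt & y_lt) |
    (x_gt & !nyi & nyj) | (x_lt & nyi & !nyj) |
    (!nxi & nxj & y_gt) | (nxi & !nxj & y_lt) |
    (!nxi & nxj & !nyi & nyj) | (nxi & !nxj & nyi & !nyj)
  discordant <-
    (x_gt & y_lt) | (x_lt & y_gt) |
    (x_gt & nyi & !nyj) | (x_lt & !nyi & nyj) |
    (!nxi & nxj & y_lt) | (nxi & !nxj & y_gt) |
    (!nxi & nxj & nyi & !nyj) | (nxi & !nxj & !nyi & nyj)

  tie_x <- (!nxi & !nxj & xi == xj) | (nxi & nxj)
  tie_y <- (!nyi & !nyj & yi == yj) | (nyi & nyj)

  new("PairCounts",
      nConcordant = sum(concordant), nDiscordant = sum(discordant),
      nXtie = sum(tie_x), nYtie = sum(tie_y),
      nTieCommon = sum(tie_x & tie_y),
      nTot = n * (n - 1) / 2,
      sStatistic = sum(concordant) - sum(discordant),
      n = n,
      xTies = .tieGroups(x), yTies = .tieGroups(y))
}

#' Kendall tau-b from a pair census
#'
#' \deqn{\tau_b = \frac{n_c - n_d}
#'   {\sqrt{(n_{tot} - n_{xtie})(n_{tot} - n_{ytie})}}}
#'
#' @param counts a [PairCounts-class] census.
#' @return The tau-b value in `[-1, 1]`, or `NA` with a warning when the
#'   denominator vanishes (all x or all y tied), which is an undefined
#'   correlation rather than a zero one.
#' @examples
#' tauBFromCounts(PairCounts(nConcordant = 2, nDiscordant = 1, n = 3))
#' @export
tauBFromCounts <- function(counts) {
  stopifnot(is(counts, "PairCounts"))
  dx <- counts@nTot - counts@nXtie
  dy <- counts@nTot - counts@nYtie
  if (dx <= 0 || dy <= 0) {
    .undefinedWarning("all values tied in x or in y")
    return(NA_real_)
  }
  (counts@nConcordant - counts@nDiscordant) / sqrt(dx * dy)
}

#' Theoretical maximum Kendall tau-b given a tie structure
#'
#' The largest tau-b attainable for a pair of vectors with the observed tie
#' counts:
#' \deqn{\tau_{max} = \frac{n_{tot} - n_{xtie} - n_{ytie} + n_{tie}}
#'   {\sqrt{(n_{tot} - n_{xtie})(n_{tot} - n_{ytie})}}}
#' where \eqn{n_{tie}} counts pairs tied in both margins.  Equals 1 when
#' ties are absent or fully shared.  Computed identically regardless of the
#' sign of the observed correlation.
#'
#' @inheritParams tauBFromCounts
#' @return tau-max in `(0, 1]`, or `NA` with a warning on a vanishing
#'   denominator.
#' @export
tauMax <- function(counts) {
  stopifnot(is(counts, "PairCounts"))
  dx <- counts@nTot - counts@nXtie
  dy <- counts@nTot - counts@nYtie
  if (dx <= 0 || dy <= 0) {
    .undefinedWarning("all values tied in x or in y")
    return(NA_real_)
  }
  (counts@nTot - counts@nXtie - counts@nYtie + counts@nTieCommon) /
    sqrt(dx * dy)
}

#' Pairwise completeness of two vectors
#'
#' Fraction of positions missing in *neither* vector:
#' \eqn{(n - N_{miss_i \cup miss_j}) / n}.  Multiplied with the correlation
#' it forms a composite metric sensitive to per-sample data quality.
#'
#' @param x,y numeric vectors of equal length.
#' @return Completeness in `[0, 1]`.
#' @examples
#' pairCompleteness(c(1, NA, 3, 4), c(1, 2, NA, 4))  # 0.5
#' @export
pairCompleteness <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 1) stop("need at least one position")
  1 - sum(is.na(x) | is.na(y)) / length(x)
}

.mkVariance <- function(n, xTies, yTies) {
  t <- xTies; u <- yTies
  vt <- sum(t * (t - 1) * (2 * t + 5))
  vu <- sum(u * (u - 1) * (2 * u + 5))
  v <- (n * (n - 1) * (2 * n + 5) - vt - vu) / 18 +
    sum(t * (t - 1)) * sum(u * (u - 1)) / (2 * n * (n - 1))
  if (n > 2)
    v <- v + sum(t * (t - 1) * (t - 2)) * sum(u * (u - 1) * (u - 2)) /
      (9 * n * (n - 1) * (n - 2))
  v
}

#' Mann-Kendall p-value for a pair census
#'
#' Normal-approximation p-value for S = concordant - discordant with the
#' tie-corrected variance of the Mann-Kendall statistic (tie-group terms
#' from the tied-value multiplicities in the census); no continuity
#' correction.
#'
#' @inheritParams tauBFromCounts
#' @param n number of points; defaults to the census value.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return p-value in `[0, 1]`; `NA` with a warning when the variance is
#'   not positive.
#' @examples
#' # n = 10, S = 45, no ties: Var(S) = 125
#' mannKendallPvalue(PairCounts(nConcordant = 45, nDiscordant = 0, n = 10))
#' @export
mannKendallPvalue <- function(counts, n = counts@n,
                              alternative = c("two.sided", "greater",
                                              "less")) {
  stopifnot(is(counts, "PairCounts"))
  alternative <- match.arg(alternative)
  if (n < 2) stop("need n >= 2")
  v <- .mkVariance(n, counts@xTies, counts@yTies)
  if (v <= 0) {
    .undefinedWarning("Mann-Kendall variance is not positive")
    return(NA_real_)
  }
  z <- counts@sStatistic / sqrt(v)
  switch(alternative,
         two.sided = min(1, 2 * pnorm(-abs(z))),
         greater = pnorm(z, lower.tail = FALSE),
         less = pnorm(z))
}

# sentinel strictly below every observed value in the two vectors,
# robust to negative data
.sentinel <- function(x, y) {
  v <- c(x, y)
  if (all(is.na(v))) return(0)
  mn <- min(v, na.rm = TRUE)
  mn - 1 - abs(mn) * 1e-6
}

# fast numeric core shared by iciKt() and the matrix engine; returns a
# named vector with NA statistics (and ok = 0) for degenerate input
.iciKtCore <- function(x, y, perspective = "global",
                       alternative = "two.sided") {
  nfeat <- length(x)
  completeness <- 1 - sum(is.na(x) | is.na(y)) / nfeat
  if (perspective == "local") {
    keep <- !(is.na(x) & is.na(y))
    x <- x[keep]; y <- y[keep]
  }
  n <- length(x)
  out <- c(tau = NA_real_, p_value = NA_real_, tau_max = NA_real_,
           completeness = completeness, s = NA_real_,
           n_effective = n, ok = 0)
  if (n < 2) return(out)
  nobs <- sum(!is.na(x) | !is.na(y))
  if (nobs == 0) return(out)   # nothing observed at all
  sentinel <- .sentinel(x, y)
  x[is.na(x)] <- sentinel
  y[is.na(y)] <- sentinel
  cen <- .kendallPairCensus(x, y)
  xtie <- sum(cen$x_ties * (cen$x_ties - 1) / 2)
  ytie <- sum(cen$y_ties * (cen$y_ties - 1) / 2)
  dx <- cen$n_tot - xtie
  dy <- cen$n_tot - ytie
  if (dx <= 0 || dy <= 0) return(out)
  s <- cen$con - cen$dis
  out["tau"] <- s / sqrt(dx * dy)
  out["tau_max"] <- (cen$n_tot - xtie - ytie + cen$ntie) / sqrt(dx * dy)
  out["s"] <- s
  v <- .mkVariance(n, cen$x_ties, cen$y_ties)
  out["p_value"] <- if (v > 0) {
    z <- s / sqrt(v)
    switch(alternative,
           two.sided = min(1, 2 * pnorm(-abs(z))),
           greater = pnorm(z, lower.tail = FALSE),
           less = pnorm(z))
  } else NA_real_
  out["ok"] <- 1
  out
}

#' Information-content-informed Kendall-tau of two vectors
#'
#' Computes the ICI-Kt correlation in O(n log n): every missing entry is
#' replaced by a sentinel strictly smaller than the minimum observed value
#' across both vectors, and tau-b is obtained by sorting plus mergesort
#' exchange counting with tie corrections.  The result is exactly equal to
#' the brute-force census [countPairsBruteforce()] fed through
#' [tauBFromCounts()], for either perspective.  Also returns the
#' Mann-Kendall p-value, the theoretical maximum tau ([tauMax()]) and the
#' pairwise completeness ([pairCompleteness()]).
#'
#' @inheritParams countPairsBruteforce
#' @param alternative sidedness of the Mann-Kendall p-value.
#' @return A list of class `"iciKt"` with elements `tau`, `p_value`,
#'   `tau_max`, `completeness`, `counts` (a [PairCounts-class] built from
#'   the sentinel-substituted data) and `n_effective` (points used after
#'   local removal).  Statistics are `NA` (with a warning) when the
#'   correlation is undefined: all values tied after sentinel substitution,
#'   or fewer than two points remaining under the local perspective.
#' @examples
#' iciKt(c(1, 2, NA), c(NA, 3, 2))$tau  # 1/3
#' @export
iciKt <- function(x, y, perspective = c("local", "global"),
                  alternative = c("two.sided", "greater", "less")) {
  perspective <- match.arg(perspective)
  alternative <- match.arg(alternative)
  .checkPair(x, y)
  if (perspective == "local" && sum(!(is.na(x) & is.na(y))) < 2)
    .undefinedWarning("fewer than two x-y points after removing jointly missing points")
  core <- .iciKtCore(x, y, perspective, alternative)
  if (!core[["ok"]] && core[["n_effective"]] >= 2)
    .undefinedWarning("all values tied in x or in y")
  counts <- NULL
  if (core[["n_effective"]] >= 2) {
    xs <- x; ys <- y
    if (perspective == "local") {
      keep <- !(is.na(x) & is.na(y))
      xs <- x[keep]; ys <- y[keep]
    }
    counts <- .fastPairCensus(xs, ys)
  }
  structure(list(
    tau = unname(core["tau"]),
    p_value = unname(core["p_value"]),
    tau_max = unname(core["tau_max"]),
    completeness = unname(core["completeness"]),
    counts = counts,
    n_effective = unname(core["n_effective"])),
    class = "iciKt")
}

# census via the fast path only (no O(n^2) work): reconstructs the
# PairCounts object from the mergesort census of sentinel-substituted data
.fastPairCensus <- function(x, y) {
  sentinel <- .sentinel(x, y)
  nmx <- is.na(x); nmy <- is.na(y)
  x[nmx] <- sentinel; y[nmy] <- sentinel
  cen <- .kendallPairCensus(x, y)
  xtie <- sum(cen$x_ties * (cen$x_ties - 1) / 2)
  ytie <- sum(cen$y_ties * (cen$y_ties - 1) / 2)
  new("PairCounts",
      nConcordant = cen$con, nDiscordant = cen$dis,
      nXtie = xtie, nYtie = ytie, nTieCommon = cen$ntie,
      nTot = cen$n_tot, sStatistic = cen$con - cen$dis,
      n = cen$n, xTies = cen$x_ties, yTies = cen$y_ties)
}

#' @export
print.iciKt <- function(x, ...) {
  cat("ICI-Kt correlation\n")
  cat(sprintf("  tau: %.6g  (tau-max %.6g, completeness %.4g)\n",
              x$tau, x$tau_max, x$completeness))
  cat(sprintf("  Mann-Kendall p-value: %.4g  (n used: %d)\n",
              x$p_value, as.integer(x$n_effective)))
  invisible(x)
}
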