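# Correlation-based sample outlier detection within sample groups, and the
# downstream significant-fraction evaluation harness.

#' Median within-group correlation per sample
#'
#' For each sample, the median of its correlations to the other samples of
#' the same group, skipping undefined (`NA`) cells.  Samples in groups with
#' fewer than two partners are excluded (`NA`) with a warning.
#'
#' @param set a [CorrelationMatrixSet-class] over samples.
#' @param groups named character vector (or two-column data.frame) mapping
#'   every sample to its group.
#' @return Named numeric vector of median correlations.
#' @export
medianGroupCorrelation <- function(set, groups) {
  stopifnot(is(set, "CorrelationMatrixSet"))
  tau <- tauMatrix(set)
  groups <- .resolveGroups(tau, groups)
  ids <- rownames(tau)
  out <- setNames(rep(NA_real_, length(ids)), ids)
  excluded <- character()
  for (s in ids) {
    partners <- setdiff(ids[groups == groups[s]], s)
    if (length(partners) < 2) {
      excluded <- c(excluded, s)
      next
    }
    vals <- tau[s, partners]
    vals <- vals[!is.na(vals)]
    if (length(vals)) out[s] <- median(vals)
  }
  if (length(excluded))
    warning("excluded samples with fewer than two group partners: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  out
}

#' Score and flag outlier samples
#'
#' Transforms median correlations into scores `log(1 - cor_median)` (low
#' correlation becomes a high score) and flags, within each group, samples
#' whose score exceeds the upper Tukey fence `Q3 + 1.5 * IQR` of the
#' group's scores.  Only the high end is flagged: an unusually *good*
#' correlation is never an outlier.  Quartiles use linear interpolation
#' (type 7); median correlations at 1 are clamped to `1 - 1e-15` before
#' the log (clamping cannot create a high-end outlier).
#'
#' @param medCors named numeric vector from [medianGroupCorrelation()].
#' @param groups group mapping as in [medianGroupCorrelation()].
#' @return A `data.frame` (one row per sample): `sample_id`, `group`,
#'   `median_correlation`, `score`, `fence`, `is_outlier`.
#' @examples
#' mc <- c(a = 0.95, b = 0.96, c = 0.94, d = 0.50)
#' flagOutliers(mc, setNames(rep("g", 4), names(mc)))
#' @export
flagOutliers <- function(medCors, groups) {
  if (is.data.frame(groups))
    groups <- setNames(as.character(groups[[2]]), as.character(groups[[1]]))
  groups <- groups[names(medCors)]
  score <- log(1 - pmin(medCors, 1 - 1e-15))
  fence <- rep(NA_real_, length(score))
  flag <- rep(FALSE, length(score))
  for (g in unique(groups)) {
    sel <- which(groups == g & !is.na(score))
    if (length(sel) < 2) next
    q <- quantile(score[sel], c(0.25, 0.75), type = 7)
    f <- q[2] + 1.5 * (q[2] - q[1])
    fence[sel] <- f
    flag[sel] <- score[sel] > f
  }
  data.frame(sample_id = names(medCors), group = unname(groups),
             median_correlation = unname(medCors), score = unname(score),
             fence = fence, is_outlier = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect outlier samples from a correlation set
#'
#' Convenience composition of [medianGroupCorrelation()] and
#' [flagOutliers()].
#'
#' @inheritParams medianGroupCorrelation
#' @return The outlier report `data.frame` of [flagOutliers()].
#' @export
detectOutliers <- function(set, groups) {
  med <- medianGroupCorrelation(set, groups)
  if (is.data.frame(groups))
    groups <- setNames(as.character(groups[[2]]), as.character(groups[[1]]))
  flagOutliers(med, groups)
}

#' Fraction of significantly different features across groups
#'
#' Per-feature one-way ANOVA F-test across sample groups (on the samples
#' remaining after removing `removed`), Benjamini-Hochberg adjustment, and
#' the fraction of features with adjusted p-value at or below `alpha`.
#' Used to evaluate outlier removal: a cleaner dataset yields more
#' significant features.  The classic equal-variance F-test is used as the
#' evaluation harness (moderated-variance statistics are out of scope);
#' features with missing values are tested on their present values, and
#' features that cannot be tested (fewer than two groups present, or no
#' residual degrees of freedom) count as non-significant.
#'
#' @inheritParams leftCensorshipTest
#' @param removed sample ids to drop before testing.
#' @param alpha adjusted p-value threshold (default 0.05).
#' @return The fraction of features (over all features) significant at
#'   `alpha`; `NA` with a warning when fewer than two groups retain two or
#'   more samples.
#' @export
significantFraction <- function(x, groups, removed = character(),
                                alpha = 0.05) {
  m <- if (is(x, "AbundanceMatrix")) abundanceValues(x) else as.matrix(x)
  groups <- .resolveGroups(m, groups)
  keep <- setdiff(colnames(m), removed)
  m <- m[, keep, drop = FALSE]
  groups <- groups[keep]
  sizes <- table(groups)
  if (sum(sizes >= 2) < 2) {
    warning("fewer than two groups with at least two samples remain; ",
            "significant fraction not applicable", call. = FALSE)
    return(NA_real_)
  }
  grp <- factor(groups)
  pvals <- apply(m, 1, function(v) {
    ok <- !is.na(v)
    g <- droplevels(grp[ok])
    if (nlevels(g) < 2 || sum(ok) <= nlevels(g)) return(NA_real_)
    tryCatch(oneway.test(v[ok] ~ g, var.equal = TRUE)$p.value,
             error = function(e) NA_real_)
  })
  padj <- p.adjust(pvals, method = "BH")
  sum(padj <= alpha, na.rm = TRUE) / nrow(m)
}
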