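# Is missingness consistent with left-censorship?  Binomial test on the
# rank position of present values of partially-missing features, and
# median-rank-versus-N-missing diagnostics.

.resolveGroups <- function(x, groups) {
  ids <- if (is(x, "AbundanceMatrix")) sampleIds(x) else colnames(x)
  if (is.data.frame(groups)) {
    if (ncol(groups) < 2)
      stop("groups data.frame needs columns sample_id and group")
    groups <- setNames(as.character(groups[[2]]), as.character(groups[[1]]))
  }
  if (is.null(names(groups)))
    stop("groups must be a named character vector (sample -> group)")
  if (any(!nzchar(groups)) || anyNA(groups))
    stop("empty group labels are not allowed")
  unknown <- setdiff(names(groups), ids)
  if (length(unknown))
    stop("samples not present in the matrix: ",
         paste(unknown, collapse = ", "))
  absent <- setdiff(ids, names(groups))
  if (length(absent))
    stop("samples without a group label: ", paste(absent, collapse = ", "))
  groups[ids]
}

#' Binomial test for left-censorship of missing values
#'
#' Within each sample group, the median of the present abundances is
#' computed per sample.  For every feature that is missing in at least one
#' sample of the group, each *present* value of that feature counts as a
#' success when it is less than or equal to its own sample's median, and a
#' failure otherwise.  Successes and failures are aggregated across groups
#' and tested against a null success probability of 0.5 with an exact
#' binomial test.  Under left-censorship the present values of
#' partially-missing features sit low in their samples, so the success
#' fraction exceeds 0.5; the default alternative is therefore one-sided.
#'
#' @param x an [AbundanceMatrix-class] or numeric feature x sample matrix
#'   with `NA` for missing values.
#' @param groups named character vector mapping every sample id to its
#'   group label (the combined subject-sample-factor string), or a
#'   two-column data.frame `(sample_id, group)`.
#' @param alternative `"greater"` (default, success probability > 0.5,
#'   i.e. left-censorship), `"two.sided"` or `"less"`.
#' @return A list of class `"leftCensorshipTest"` with `successes`,
#'   `failures`, `estimate` (success fraction) and `p.value`.  When no
#'   feature has both missing and present values within some group the test
#'   is not applicable: counts are zero and `p.value` is `NA`, with a
#'   warning.
#' @examples
#' m <- simLodCohort(nSamples = 6, nFeatures = 200, seed = 1)
#' cm <- censorCutoff(m, quantile(m, 0.1))
#' leftCensorshipTest(cm, setNames(rep("g1", 6), colnames(m)))
#' @export
leftCensorshipTest <- function(x, groups,
                               alternative = c("greater", "two.sided",
                                               "less")) {
  alternative <- match.arg(alternative)
  m <- if (is(x, "AbundanceMatrix")) abundanceValues(x) else as.matrix(x)
  groups <- .resolveGroups(m, groups)
  successes <- 0L; failures <- 0L
  for (g in unique(groups)) {
    sub <- m[, groups == g, drop = FALSE]
    med <- apply(sub, 2, median, na.rm = TRUE)
    nmiss <- rowSums(is.na(sub))
    eligible <- nmiss >= 1 & nmiss < ncol(sub)
    if (!any(eligible)) next
    sub <- sub[eligible, , drop = FALSE]
    below <- sweep(sub, 2, med, "<=")
    successes <- successes + sum(below, na.rm = TRUE)
    failures <- failures + sum(!below, na.rm = TRUE)
  }
  tot <- successes + failures
  if (tot == 0) {
    warning("no feature with both missing and present values within a group;",
            " left-censorship test not applicable", call. = FALSE)
    res <- list(successes = 0L, failures = 0L, estimate = NA_real_,
                p.value = NA_real_, alternative = alternative)
  } else {
    bt <- binom.test(successes, tot, p = 0.5, alternative = alternative)
    res <- list(successes = successes, failures = failures,
                estimate = successes / tot, p.value = bt$p.value,
                alternative = alternative)
  }
  class(res) <- "leftCensorshipTest"
  res
}

#' @export
print.leftCensorshipTest <- function(x, ...) {
  cat("Binomial test for left-censorship (null: success probability 0.5)\n")
  cat(sprintf("  successes: %d  failures: %d  estimate: %.4g\n",
              x$successes, x$failures, x$estimate))
  cat(sprintf("  p-value (%s): %.4g\n", x$alternative, x$p.value))
  invisible(x)
}

#' Batch left-censorship testing with multiplicity adjustment
#'
#' Runs [leftCensorshipTest()] over a list of datasets and adjusts the
#' p-values across datasets by Benjamini-Hochberg.
#'
#' @param matrices list of abundance matrices.
#' @param groupsList list of group mappings, one per matrix (a single
#'   mapping is recycled).
#' @param alternative passed to [leftCensorshipTest()].
#' @return A `data.frame` with one row per dataset: `successes`,
#'   `failures`, `estimate`, `p_value`, `p_adjusted`.
#' @export
leftCensorshipTestBatch <- function(matrices, groupsList,
                                    alternative = "greater") {
  if (is.character(groupsList) || is.data.frame(groupsList))
    groupsList <- list(groupsList)
  if (length(groupsList) == 1L)
    groupsList <- rep(groupsList, length(matrices))
  res <- mapply(function(m, g) {
    r <- suppressWarnings(leftCensorshipTest(m, g, alternative))
    c(r$successes, r$failures, r$estimate, r$p.value)
  }, matrices, groupsList)
  out <- data.frame(
    dataset = if (is.null(names(matrices)))
      seq_along(matrices) else names(matrices),
    successes = res[1, ], failures = res[2, ],
    estimate = res[3, ], p_value = res[4, ])
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}

#' Median rank versus number-of-missing summary
#'
#' Within each group, features are ranked per sample over the *present*
#' features (rank 1 = lowest abundance, average ranks for exact ties).  For
#' every feature the median rank across the samples where it is present and
#' the count of samples where it is missing are recorded; per missingness
#' level the median and the minimum of the median ranks are aggregated.
#' Under left-censorship, features missing more often rank lower when
#' observed, giving a monotonically decreasing rank-versus-missing trend.
#'
#' @inheritParams leftCensorshipTest
#' @return A list of class `"rankMissingSummary"`: `records` (one row per
#'   feature x group: `feature_id`, `group`, `median_rank`, `n_missing`)
#'   and `aggregates` (per group x `n_missing`: `median_median_rank`,
#'   `min_median_rank`).
#' @export
rankMissingSummary <- function(x, groups) {
  m <- if (is(x, "AbundanceMatrix")) abundanceValues(x) else as.matrix(x)
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("feature_%04d", seq_len(nrow(m)))
  groups <- .resolveGroups(m, groups)
  recs <- lapply(unique(groups), function(g) {
    sub <- m[, groups == g, drop = FALSE]
    if (ncol(sub) < 2)
      stop("group '", g, "' has fewer than two samples")
    rk <- apply(sub, 2, function(v) {
      r <- rep(NA_real_, length(v))
      r[!is.na(v)] <- rank(v[!is.na(v)], ties.method = "average")
      r
    })
    data.frame(
      feature_id = rownames(sub), group = g,
      median_rank = apply(rk, 1, median, na.rm = TRUE),
      n_missing = rowSums(is.na(sub)),
      row.names = NULL, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  present <- records[!is.na(records$median_rank), , drop = FALSE]
  aggregates <- do.call(rbind, lapply(
    split(present, list(present$group, present$n_missing), drop = TRUE),
    function(d) data.frame(
      group = d$group[1], n_missing = d$n_missing[1],
      median_median_rank = median(d$median_rank),
      min_median_rank = min(d$median_rank),
      row.names = NULL, stringsAsFactors = FALSE)))
  aggregates <- aggregates[order(aggregates$group, aggregates$n_missing), ]
  rownames(aggregates) <- NULL
  structure(list(records = records, aggregates = aggregates),
            class = "rankMissingSummary")
}

#' Correlation of median rank with missingness
#'
#' Kendall correlation of per-feature median rank with the number of
#' missing samples, and of the per-level minimum median rank with the
#' missingness level.  Strongly negative values indicate left-censorship;
#' values near zero indicate random missingness.
#'
#' @param summary a `"rankMissingSummary"` from [rankMissingSummary()].
#' @return Named numeric vector `c(median_rank = ..., min_median_rank =
#'   ...)`; `NA` (with a warning) when fewer than two distinct missingness
#'   levels exist or the ranks are constant.
#' @export
rankMissingCorrelation <- function(summary) {
  stopifnot(inherits(summary, "rankMissingSummary"))
  rec <- summary$records
  rec <- rec[!is.na(rec$median_rank), , drop = FALSE]
  agg <- summary$aggregates
  kcor <- function(a, b) {
    if (length(unique(b)) < 2 || length(unique(a)) < 2) return(NA_real_)
    cor(a, b, method = "kendall")
  }
  out <- c(median_rank = kcor(rec$median_rank, rec$n_missing),
           min_median_rank = kcor(agg$min_median_rank, agg$n_missing))
  if (anyNA(out))
    warning("degenerate rank/missingness input: correlation undefined",
            call. = FALSE)
  out
}
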