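# All-pairs correlation over an abundance matrix: ICI-Kt with optional
# tau-max scaling, completeness compositing, baseline comparison methods,
# and the long-format representation.

.vectorsAlong <- function(x, axis = c("samples", "features")) {
  axis <- match.arg(axis)
  m <- if (is(x, "AbundanceMatrix")) abundanceValues(x) else as.matrix(x)
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("feature_%04d", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("sample_%03d", seq_len(ncol(m)))
  if (axis == "samples") m else t(m)
}

#' All-pairs ICI-Kt correlation of an abundance matrix
#'
#' Computes the ICI-Kt correlation, Mann-Kendall p-value, theoretical
#' maximum tau and completeness for every unordered pair of samples (or
#' features).  Work is split into pair-index chunks and reassembled by
#' index, so results are identical for any worker count and evaluation
#' order.  Diagonal entries are computed, not assumed, so a sample's
#' self-completeness reflects its own missingness honestly.
#'
#' @param x an [AbundanceMatrix-class] or a numeric feature x sample matrix
#'   with `NA` for missing values.
#' @param axis correlate `"samples"` (columns, default) or `"features"`
#'   (rows).
#' @param perspective `"global"` (default here; every pair sees the same
#'   number of pair comparisons, jointly missing points count as shared
#'   ties) or `"local"` (jointly missing points dropped per pair).
#' @param scaleMax divide the whole tau matrix by the maximum off-diagonal
#'   tau-max of the set.  Defaults to `FALSE`: scaling changes the values
#'   returned for a dataset and makes correlations incomparable *between*
#'   datasets.
#' @param cores number of worker processes (forked via
#'   [parallel::mclapply]); the result does not depend on it.
#' @return A [CorrelationMatrixSet-class].  Undefined pairs propagate as
#'   `NA` cells with a single summarising warning.
#' @examples
#' m <- matrix(rlnorm(60), nrow = 20,
#'             dimnames = list(NULL, c("a", "b", "c")))
#' cs <- iciKtMatrix(m)
#' tauMatrix(cs)
#' @export
iciKtMatrix <- function(x, axis = c("samples", "features"),
                        perspective = c("global", "local"),
                        scaleMax = FALSE, cores = 1L) {
  axis <- match.arg(axis)
  perspective <- match.arg(perspective)
  m <- .vectorsAlong(x, axis)
  k <- ncol(m)
  if (k < 2) stop("need at least two vectors along the chosen axis")
  ids <- colnames(m)

  pairs <- cbind(rep(seq_len(k), times = k:1),
                 unlist(lapply(seq_len(k), function(i) i:k)))
  evalChunk <- function(idx) {
    vapply(idx, function(p) {
      .iciKtCore(m[, pairs[p, 1]], m[, pairs[p, 2]], perspective)
    }, numeric(7))
  }
  npair <- nrow(pairs)
  if (cores > 1L && .Platform$OS.type == "unix") {
    chunks <- split(seq_len(npair),
                    cut(seq_len(npair), breaks = cores * 4L, labels = FALSE))
    res <- do.call(cbind, parallel::mclapply(chunks, evalChunk,
                                             mc.cores = cores))
  } else {
    res <- evalChunk(seq_len(npair))
  }

  blank <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  tau <- pval <- tmax <- comp <- blank
  fill <- function(mat, v) {
    mat[pairs] <- v
    mat[pairs[, c(2, 1)]] <- v
    mat
  }
  tau <- fill(tau, res["tau", ])
  pval <- fill(pval, res["p_value", ])
  tmax <- fill(tmax, res["tau_max", ])
  comp <- fill(comp, res["completeness", ])

  nUndef <- sum(res["ok", ] == 0)
  if (nUndef > 0)
    warning(sprintf("%d undefined pair(s) propagated as NA cells", nUndef),
            call. = FALSE)

  scaled <- FALSE
  meta <- list(axis = axis, cores = as.integer(cores))
  if (scaleMax) {
    off <- tmax[upper.tri(tmax)]
    mx <- suppressWarnings(max(off, na.rm = TRUE))
    if (is.finite(mx) && mx > 0) {
      tau <- tau / mx
      scaled <- TRUE
      meta$maxTauMax <- mx
    }
  }
  new("CorrelationMatrixSet", tau = tau, pValue = pval, tauMax = tmax,
      completeness = comp, methodLabel = "icikt",
      perspective = perspective, scaled = scaled, metadata = meta)
}

#' Completeness-composited correlation
#'
#' Element-wise product of the correlation and completeness matrices
#' (`icikt_complete`): a composite metric that down-weights pairs with many
#' missing features.  Applied to the unscaled tau (completeness is a data
#' quality weight, tau-max scaling a dataset-level normalisation).
#'
#' @param set a [CorrelationMatrixSet-class].
#' @return A symmetric matrix with `|entry| <= |tau|` element-wise.
#' @export
compositeCorrelation <- function(set) {
  stopifnot(is(set, "CorrelationMatrixSet"))
  tauMatrix(set) * completenessMatrix(set)
}

.baselineMethods <- c("kt_base", "pearson_base", "pearson_base_nozero",
                      "pearson_log1p", "pearson_log")

#' Baseline correlation variants for comparison with ICI-Kt
#'
#' The conventional treatments of missing values that ICI-Kt is compared
#' against, all under pairwise-complete observation removal:
#' `kt_base` Kendall tau-b with `NA` kept as missing; `pearson_base`
#' Pearson with `NA` replaced by zero; `pearson_base_nozero` Pearson with
#' `NA` kept; `pearson_log1p` Pearson on `log(x + 1)`; `pearson_log`
#' Pearson on `log(x)` with non-finite values set to missing.
#'
#' @inheritParams iciKtMatrix
#' @param method one of the variants above.
#' @return A [CorrelationMatrixSet-class]; `pValue` and `tauMax` are `NA`
#'   (not produced by these baselines), completeness reflects the original
#'   missingness.  Pairs with fewer than two complete observations are `NA`.
#' @export
baselineCorrelation <- function(x, method = .baselineMethods,
                                axis = c("samples", "features")) {
  method <- match.arg(method)
  axis <- match.arg(axis)
  m <- .vectorsAlong(x, axis)
  if (ncol(m) < 2) stop("need at least two vectors along the chosen axis")
  mt <- switch(method,
    kt_base = m,
    pearson_base = { m[is.na(m)] <- 0; m },
    pearson_base_nozero = m,
    pearson_log1p = log(m + 1),
    pearson_log = { lm_ <- log(m); lm_[!is.finite(lm_)] <- NA_real_; lm_ })
  corMethod <- if (method == "kt_base") "kendall" else "pearson"
  cc <- suppressWarnings(
    cor(mt, use = "pairwise.complete.obs", method = corMethod))
  ids <- colnames(m)
  dimnames(cc) <- list(ids, ids)
  blank <- matrix(NA_real_, ncol(m), ncol(m), dimnames = list(ids, ids))
  comp <- blank
  miss <- is.na(m)
  nf <- nrow(m)
  comp[] <- 1 - (crossprod(miss, !miss) + crossprod(!miss, miss) +
                 crossprod(miss, miss)) / nf
  new("CorrelationMatrixSet", tau = cc, pValue = blank, tauMax = blank,
      completeness = comp, methodLabel = method, perspective = "local",
      scaled = FALSE, metadata = list(axis = axis))
}

#' Long-format view of a correlation set
#'
#' One row per unordered pair with columns `id_a`, `id_b`, `tau`,
#' `p_value`, `tau_max`, `completeness`.  The round trip through
#' [correlationSetFromLong()] is lossless.
#'
#' @param set a [CorrelationMatrixSet-class].
#' @param diagonal include the diagonal entries as rows.
#' @return A `data.frame`.
#' @export
correlationLong <- function(set, diagonal = TRUE) {
  stopifnot(is(set, "CorrelationMatrixSet"))
  tau <- tauMatrix(set)
  ids <- rownames(tau)
  keep <- upper.tri(tau, diag = diagonal)
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
    tau = tau[idx], p_value = pValueMatrix(set)[idx],
    tau_max = tauMaxMatrix(set)[idx],
    completeness = completenessMatrix(set)[idx],
    stringsAsFactors = FALSE)
}

#' Rebuild a correlation set from its long format
#'
#' @param df a `data.frame` as produced by [correlationLong()] with the
#'   diagonal included.
#' @param methodLabel,perspective,scaled metadata restored onto the set.
#' @return A [CorrelationMatrixSet-class].
#' @export
correlationSetFromLong <- function(df, methodLabel = "icikt",
                                   perspective = "global", scaled = FALSE) {
  ids <- unique(c(df$id_a, df$id_b))
  k <- length(ids)
  blank <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  mats <- list(tau = blank, p_value = blank, tau_max = blank,
               completeness = blank)
  ia <- match(df$id_a, ids); ib <- match(df$id_b, ids)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    m[cbind(ia, ib)] <- df[[nm]]
    m[cbind(ib, ia)] <- df[[nm]]
    mats[[nm]] <- m
  }
  new("CorrelationMatrixSet", tau = mats$tau, pValue = mats$p_value,
      tauMax = mats$tau_max, completeness = mats$completeness,
      methodLabel = methodLabel, perspective = perspective,
      scaled = scaled, metadata = list())
}
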