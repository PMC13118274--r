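#' @useDynLib kendallICI, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats median quantile cor pnorm binom.test p.adjust rlnorm
#'   rnorm runif oneway.test setNames
#' @importFrom utils read.table write.table combn packageVersion
NULL

#' Pair census of a vector pair
#'
#' Exact integer census of all unordered point pairs of a vector pair under
#' the information-content-informed (ICI) concordance rules: concordant and
#' discordant counts, tie counts in each margin, jointly tied pairs, and the
#' tied-group multiplicities needed for the tie-corrected Mann-Kendall
#' variance.  All counts are stored as doubles but hold exact integers
#' (exact up to n(n-1)/2 < 2^53).
#'
#' @slot nConcordant concordant pair count.
#' @slot nDiscordant discordant pair count.
#' @slot nXtie pairs tied in x (including missing-vs-missing in x).
#' @slot nYtie pairs tied in y.
#' @slot nTieCommon pairs tied in both x and y.
#' @slot nTot total pair count, n(n-1)/2.
#' @slot sStatistic Mann-Kendall S = nConcordant - nDiscordant.
#' @slot n number of x-y points in the census.
#' @slot xTies,yTies tied-group sizes (>= 2) in x and y, missing values
#'   counted as one shared tied group.
#'
#' @seealso [countPairsBruteforce()], [tauBFromCounts()], [tauMax()],
#'   [mannKendallPvalue()]
#' @export
setClass("PairCounts",
  representation(
    nConcordant = "numeric", nDiscordant = "numeric",
    nXtie = "numeric", nYtie = "numeric", nTieCommon = "numeric",
    nTot = "numeric", sStatistic = "numeric", n = "numeric",
    xTies = "numeric", yTies = "numeric"))

setValidity("PairCounts", function(object) {
  msg <- NULL
  cnt <- c(object@nConcordant, object@nDiscordant, object@nXtie,
           object@nYtie, object@nTieCommon, object@nTot)
  if (any(cnt < 0)) msg <- c(msg, "all counts must be non-negative")
  if (object@nTieCommon > min(object@nXtie, object@nYtie) + 1e-9)
    msg <- c(msg, "nTieCommon cannot exceed min(nXtie, nYtie)")
  # pairs tied in x or y = nXtie + nYtie - nTieCommon
  census <- object@nConcordant + object@nDiscordant +
    object@nXtie + object@nYtie - object@nTieCommon
  if (abs(census - object@nTot) > 1e-9)
    msg <- c(msg, "concordant + discordant + tied-in-x-or-y must equal nTot")
  if (abs(object@sStatistic -
          (object@nConcordant - object@nDiscordant)) > 1e-9)
    msg <- c(msg, "sStatistic must equal nConcordant - nDiscordant")
  if (abs(object@nTot - object@n * (object@n - 1) / 2) > 1e-9)
    msg <- c(msg, "nTot must equal n(n-1)/2")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PairCounts object
#'
#' Usually produced by [countPairsBruteforce()] or [iciKt()]; the
#' constructor is exported so closed-form tie configurations can be built
#' directly (e.g. to evaluate [tauBFromCounts()] or [mannKendallPvalue()]
#' for a known census).
#'
#' @param nConcordant,nDiscordant concordant and discordant pair counts.
#' @param n number of x-y points.
#' @param xTies,yTies tied-group sizes (each >= 2) in x and y.
#' @param nTieCommon pairs tied in both x and y.
#' @return A [PairCounts-class] object.
#' @examples
#' pc <- PairCounts(nConcordant = 3, nDiscordant = 0, n = 3)
#' tauBFromCounts(pc)
#' @export
PairCounts <- function(nConcordant, nDiscordant, n,
                       xTies = numeric(), yTies = numeric(),
                       nTieCommon = 0) {
  xTies <- as.numeric(xTies[xTies >= 2])
  yTies <- as.numeric(yTies[yTies >= 2])
  new("PairCounts",
      nConcordant = as.numeric(nConcordant),
      nDiscordant = as.numeric(nDiscordant),
      nXtie = sum(xTies * (xTies - 1) / 2),
      nYtie = sum(yTies * (yTies - 1) / 2),
      nTieCommon = as.numeric(nTieCommon),
      nTot = n * (n - 1) / 2,
      sStatistic = as.numeric(nConcordant) - as.numeric(nDiscordant),
      n = as.numeric(n),
      xTies = xTies, yTies = yTies)
}

setMethod("show", "PairCounts", function(object) {
  cat("PairCounts census of", object@n, "points (",
      object@nTot, "pairs )\n")
  cat("  concordant:", object@nConcordant,
      " discordant:", object@nDiscordant,
      " S:", object@sStatistic, "\n")
  cat("  ties: x", object@nXtie, "| y", object@nYtie,
      "| common", object@nTieCommon, "\n")
})

#' Abundance matrix with an explicit missingness mask
#'
#' Feature-by-sample numeric matrix (rows are features such as metabolites,
#' columns are samples) carrying an explicit logical missingness mask.
#' Masked cells hold `NA` in the value matrix and carry no numeric meaning;
#' under left-censorship they are interpreted as below the limit of
#' detection.
#'
#' @slot values numeric feature x sample matrix; masked cells are `NA`.
#' @slot missingMask logical matrix of the same shape, `TRUE` where the
#'   measurement is missing.
#'
#' @seealso [readAbundanceMatrix()], [iciKtMatrix()]
#' @export
setClass("AbundanceMatrix",
  representation(values = "matrix", missingMask = "matrix"))

setValidity("AbundanceMatrix", function(object) {
  v <- object@values; m <- object@missingMask
  msg <- NULL
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (!is.logical(m)) msg <- c(msg, "missingMask must be logical")
  if (!identical(dim(v), dim(m)))
    msg <- c(msg, "values and missingMask must have identical dimensions")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry feature (row) and sample (column) names")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate feature ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate sample ids")
  }
  if (any(m != is.na(v)))
    msg <- c(msg, "masked cells (and only masked cells) must be NA in values")
  if (is.null(msg)) TRUE else msg
})

#' Construct an AbundanceMatrix
#'
#' @param values numeric feature x sample matrix.  Missing measurements may
#'   be encoded as `NA`; they are absorbed into the mask.
#' @param missingMask optional logical matrix marking missing cells; defaults
#'   to `is.na(values)`.  Cells marked missing are set to `NA`.
#' @return An [AbundanceMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 2, NA, 4), 2, 2,
#'             dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' am <- AbundanceMatrix(m)
#' missingMask(am)
#' @export
AbundanceMatrix <- function(values, missingMask = is.na(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("feature_%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("sample_%03d", seq_len(ncol(values)))
  missingMask <- missingMask | is.na(values)
  dimnames(missingMask) <- dimnames(values)
  values[missingMask] <- NA_real_
  new("AbundanceMatrix", values = values, missingMask = missingMask)
}

setMethod("show", "AbundanceMatrix", function(object) {
  cat("AbundanceMatrix:", nrow(object@values), "features x",
      ncol(object@values), "samples\n")
  cat(sprintf("  missing cells: %d (%.1f%%)\n",
              sum(object@missingMask),
              100 * mean(object@missingMask)))
})

setMethod("dim", "AbundanceMatrix", function(x) dim(x@values))

#' @rdname AbundanceMatrix
#' @param x,object an `AbundanceMatrix`.
#' @export
setGeneric("abundanceValues", function(x) standardGeneric("abundanceValues"))

#' @rdname AbundanceMatrix
#' @export
setMethod("abundanceValues", "AbundanceMatrix", function(x) x@values)

#' @rdname AbundanceMatrix
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname AbundanceMatrix
#' @export
setMethod("missingMask", "AbundanceMatrix", function(x) x@missingMask)

#' @rdname AbundanceMatrix
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname AbundanceMatrix
#' @export
setMethod("featureIds", "AbundanceMatrix", function(x) rownames(x@values))

#' @rdname AbundanceMatrix
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname AbundanceMatrix
#' @export
setMethod("sampleIds", "AbundanceMatrix", function(x) colnames(x@values))

#' Set of all-pairs correlation matrices
#'
#' The four symmetric matrices produced by an all-pairs correlation run over
#' samples (or features): the correlation itself, its Mann-Kendall p-value,
#' the theoretical maximum correlation attainable given the tie structure of
#' each pair, and the pairwise completeness.  Baseline (non-ICI) methods fill
#' only the correlation and completeness; undefined cells are `NA`.
#'
#' @slot tau,pValue,tauMax,completeness symmetric numeric matrices sharing
#'   dimnames.
#' @slot methodLabel correlation method identifier (e.g. `"icikt"`).
#' @slot perspective `"local"` or `"global"` handling of jointly missing
#'   points (meaningful for ICI-Kt only).
#' @slot scaled whether `tau` has been divided by the maximum off-diagonal
#'   tau-max of the set.
#' @slot metadata list of run details (e.g. `maxTauMax` when scaled).
#'
#' @seealso [iciKtMatrix()], [baselineCorrelation()], [correlationLong()]
#' @export
setClass("CorrelationMatrixSet",
  representation(
    tau = "matrix", pValue = "matrix", tauMax = "matrix",
    completeness = "matrix", methodLabel = "character",
    perspective = "character", scaled = "logical", metadata = "list"))

setValidity("CorrelationMatrixSet", function(object) {
  msg <- NULL
  dims <- dim(object@tau)
  for (slotname in c("pValue", "tauMax", "completeness")) {
    m <- slot(object, slotname)
    if (!identical(dim(m), dims))
      msg <- c(msg, sprintf("%s dimension differs from tau", slotname))
    if (!identical(dimnames(m), dimnames(object@tau)))
      msg <- c(msg, sprintf("%s dimnames differ from tau", slotname))
  }
  if (dims[1] != dims[2]) msg <- c(msg, "matrices must be square")
  if (is.null(dimnames(object@tau)[[1]]))
    msg <- c(msg, "matrices must carry axis labels")
  for (slotname in c("tau", "pValue", "tauMax", "completeness")) {
    m <- slot(object, slotname)
    if (any(abs(m - t(m)) > 1e-12, na.rm = TRUE) ||
        any(is.na(m) != is.na(t(m))))
      msg <- c(msg, sprintf("%s must be symmetric", slotname))
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CorrelationMatrixSet", function(object) {
  k <- nrow(object@tau)
  off <- object@tau[upper.tri(object@tau)]
  cat(sprintf("CorrelationMatrixSet: %d x %d [%s, %s%s]\n",
              k, k, object@methodLabel, object@perspective,
              if (object@scaled) ", scaled" else ""))
  if (length(off))
    cat(sprintf("  off-diagonal tau: median %.3f, range [%.3f, %.3f], %d NA\n",
                median(off, na.rm = TRUE), suppressWarnings(min(off, na.rm = TRUE)),
                suppressWarnings(max(off, na.rm = TRUE)), sum(is.na(off))))
})

#' @rdname CorrelationMatrixSet-class
#' @param x a `CorrelationMatrixSet`.
#' @export
setGeneric("tauMatrix", function(x) standardGeneric("tauMatrix"))

#' @rdname CorrelationMatrixSet-class
#' @export
setMethod("tauMatrix", "CorrelationMatrixSet", function(x) x@tau)

#' @rdname CorrelationMatrixSet-class
#' @export
setGeneric("pValueMatrix", function(x) standardGeneric("pValueMatrix"))

#' @rdname CorrelationMatrixSet-class
#' @export
setMethod("pValueMatrix", "CorrelationMatrixSet", function(x) x@pValue)

#' @rdname CorrelationMatrixSet-class
#' @export
setGeneric("tauMaxMatrix", function(x) standardGeneric("tauMaxMatrix"))

#' @rdname CorrelationMatrixSet-class
#' @export
setMethod("tauMaxMatrix", "CorrelationMatrixSet", function(x) x@tauMax)

#' @rdname CorrelationMatrixSet-class
#' @export
setGeneric("completenessMatrix",
           function(x) standardGeneric("completenessMatrix"))

#' @rdname CorrelationMatrixSet-class
#' @export
setMethod("completenessMatrix", "CorrelationMatrixSet",
          function(x) x@completeness)

#' @rdname CorrelationMatrixSet-class
#' @export
setGeneric("methodLabel", function(x) standardGeneric("methodLabel"))

#' @rdname CorrelationMatrixSet-class
#' @export
setMethod("methodLabel", "CorrelationMatrixSet", function(x) x@methodLabel)
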