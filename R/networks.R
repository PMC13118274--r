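# Feature-feature networks: shrinkage-regularised partial correlations,
# tail-quantile edge selection, and the annotation partitioning ratio Q.

#' Partial correlations from a correlation matrix
#'
#' Standardised negative elements of the inverse correlation matrix:
#' \eqn{p_{ij} = -\Omega_{ij} / \sqrt{\Omega_{ii}\Omega_{jj}}}, the
#' correlation between two features after removing the linear effect of all
#' others.  With many more features than samples the sample correlation
#' matrix is singular, so the matrix is shrunk toward the identity,
#' \eqn{(1-\lambda) C + \lambda I}, with the smallest \eqn{\lambda} that
#' lifts the minimum eigenvalue to `minEigen`; the chosen intensity is
#' recorded in the `"shrinkage"` attribute of the result.  Undefined cells
#' are imputed to zero for the inversion (with a message).
#'
#' @param corr square symmetric correlation matrix (e.g.
#'   `tauMatrix(iciKtMatrix(x, axis = "features"))`).
#' @param minEigen eigenvalue floor for the shrunk matrix (default 0.01).
#' @return Symmetric partial-correlation matrix with unit diagonal and
#'   attribute `"shrinkage"`.
#' @export
partialCorrelations <- function(corr, minEigen = 0.01) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("corr must be a square matrix")
  if (any(abs(corr - t(corr)) > 1e-8, na.rm = TRUE))
    stop("corr must be symmetric")
  nNA <- sum(is.na(corr))
  if (nNA > 0) {
    message(nNA, " undefined correlation cell(s) imputed to 0 for inversion")
    corr[is.na(corr)] <- 0
  }
  diag(corr) <- 1
  corr <- (corr + t(corr)) / 2
  ev <- eigen(corr, symmetric = TRUE)
  lmin <- min(ev$values)
  lambda <- if (lmin >= minEigen) 0 else (minEigen - lmin) / (1 - lmin)
  d <- (1 - lambda) * ev$values + lambda
  omega <- ev$vectors %*% (t(ev$vectors) / d)
  s <- sqrt(diag(omega))
  pc <- -omega / tcrossprod(s)
  diag(pc) <- 1
  pc <- (pc + t(pc)) / 2
  dimnames(pc) <- dimnames(corr)
  attr(pc, "shrinkage") <- lambda
  pc
}

#' Select network edges from the tails of a partial-correlation matrix
#'
#' Keeps the off-diagonal entries beyond the empirical `tailFraction` and
#' `1 - tailFraction` quantiles (a total of twice `tailFraction` of the
#' distribution), inclusive at the thresholds (type-7 quantiles), then
#' drops non-positive weights.
#'
#' @param pcorr symmetric matrix (typically from [partialCorrelations()]).
#' @param tailFraction fraction taken from each tail (default 0.025).
#' @return A `data.frame` edge list of class `"weightedEdgeList"` with
#'   columns `feature_a`, `feature_b` (canonical `a < b` ordering) and
#'   `weight` (> 0), plus attributes `nodes` (the node universe) and
#'   `thresholds`.
#' @export
selectEdges <- function(pcorr, tailFraction = 0.025) {
  if (!is.matrix(pcorr) || nrow(pcorr) != ncol(pcorr))
    stop("pcorr must be a square matrix")
  if (tailFraction <= 0 || tailFraction >= 0.5)
    stop("tailFraction must be in (0, 0.5)")
  ids <- rownames(pcorr)
  if (is.null(ids)) ids <- sprintf("feature_%04d", seq_len(nrow(pcorr)))
  ut <- which(upper.tri(pcorr), arr.ind = TRUE)
  vals <- pcorr[ut]
  fin <- is.finite(vals)
  if (sum(fin) < 1 / tailFraction)
    warning("fewer than 1/tailFraction off-diagonal entries; ",
            "tail quantiles are poorly determined", call. = FALSE)
  lo <- quantile(vals[fin], tailFraction, type = 7, names = FALSE)
  hi <- quantile(vals[fin], 1 - tailFraction, type = 7, names = FALSE)
  sel <- fin & (vals <= lo | vals >= hi)
  ia <- ids[ut[sel, 1]]; ib <- ids[ut[sel, 2]]
  edges <- data.frame(
    feature_a = pmin(ia, ib), feature_b = pmax(ia, ib),
    weight = vals[sel], stringsAsFactors = FALSE)
  edges <- edges[edges$weight > 0, , drop = FALSE]
  edges <- edges[order(edges$feature_a, edges$feature_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, nodes = ids, thresholds = c(lower = lo, upper = hi),
            class = c("weightedEdgeList", "data.frame"))
}

#' Annotation partitioning ratio of a weighted network
#'
#' Scores how well positive-weight edges fall within annotation sets rather
#' than between them:
#' \deqn{Q = \sum_i \left( \frac{within_i}{annotated}
#'   - \left(\frac{outer_i}{annotated}\right)^2 \right)}
#' where `annotated` sums the weights of edges with at least one annotated
#' endpoint, `within_i` the edges with both endpoints in annotation *i*,
#' and `outer_i` the edges leaving annotation *i* for a node of a different
#' annotation.  For disjoint single-label annotations Q ranges over
#' `[-..., 1]` with 1 for a fully partitioned network; overlapping
#' annotation sets widen the range.
#'
#' @param edges edge list from [selectEdges()], or any `data.frame` with
#'   columns `feature_a`, `feature_b`, `weight` (weights > 0).
#' @param annotations named list mapping annotation id to a character
#'   vector of feature ids (features may carry several annotations), e.g.
#'   from [readGmt()].
#' @param crossCounting `"both"` (default) counts a crossing edge i-j once
#'   from each side (it appears in `outer_i` and `outer_j`); `"once"`
#'   counts it only for the lexicographically first endpoint's annotation.
#' @return A list of class `"partitionResult"`: `q_ratio`, `annotated`
#'   (total annotated edge weight), and `perAnnotation` (`data.frame` with
#'   `within_sum` and `outer_sum`); `NA` q-ratio with a warning when no
#'   edge touches an annotated node.
#' @export
partitionRatio <- function(edges, annotations,
                           crossCounting = c("both", "once")) {
  crossCounting <- match.arg(crossCounting)
  stopifnot(is.data.frame(edges),
            all(c("feature_a", "feature_b", "weight") %in% names(edges)))
  if (any(edges$weight <= 0)) stop("edge weights must be positive")
  if (!length(annotations) || is.null(names(annotations)))
    stop("annotations must be a non-empty named list")
  annotated_nodes <- unique(unlist(annotations))
  aIn <- edges$feature_a %in% annotated_nodes
  bIn <- edges$feature_b %in% annotated_nodes
  annotated <- sum(edges$weight[aIn | bIn])
  if (annotated == 0) {
    warning("no edge touches an annotated node; Q undefined", call. = FALSE)
    return(structure(list(q_ratio = NA_real_, annotated = 0,
                          perAnnotation = NULL),
                     class = "partitionResult"))
  }
  per <- lapply(names(annotations), function(id) {
    memb <- annotations[[id]]
    ina <- edges$feature_a %in% memb
    inb <- edges$feature_b %in% memb
    within <- sum(edges$weight[ina & inb])
    othera <- edges$feature_a %in% setdiff(annotated_nodes, memb)
    otherb <- edges$feature_b %in% setdiff(annotated_nodes, memb)
    fromA <- ina & !inb & otherb   # a starts in i, b annotated elsewhere
    fromB <- inb & !ina & othera
    outer <- if (crossCounting == "both")
      sum(edges$weight[fromA | fromB])
    else
      sum(edges$weight[fromA])
    data.frame(annotation = id, within_sum = within, outer_sum = outer,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  q <- sum(per$within_sum / annotated - (per$outer_sum / annotated)^2)
  structure(list(q_ratio = q, annotated = annotated, perAnnotation = per,
                 crossCounting = crossCounting),
            class = "partitionResult")
}

#' @export
print.partitionResult <- function(x, ...) {
  cat(sprintf("Partitioning ratio Q = %.4g over %d annotation(s), ",
              x$q_ratio,
              if (is.null(x$perAnnotation)) 0 else nrow(x$perAnnotation)))
  cat(sprintf("annotated edge weight = %.4g\n", x$annotated))
  invisible(x)
}

#' Read a GMT-style annotation file
#'
#' Tab-separated lines: annotation id, description, then member feature
#' ids.
#'
#' @param path file path.
#' @return Named list of feature-id vectors, with descriptions in the
#'   `"descriptions"` attribute.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad))
    stop("GMT line(s) without members: ", paste(which(bad), collapse = ", "))
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate annotation ids in GMT file")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, "", 2L), ids)
  sets
}

#' Write annotations in GMT format
#'
#' @param annotations named list of feature-id vectors.
#' @param path output file path.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
writeGmt <- function(annotations, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- rep("", length(annotations))
  lines <- vapply(seq_along(annotations), function(i) {
    paste(c(names(annotations)[i], descriptions[i], annotations[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
}
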