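# Readers and writers for the plain-text formats used around the
# correlation engine: abundance matrices (TSV/CSV), sample grouping tables,
# and long-format correlation output.

.sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a feature-by-sample abundance matrix
#'
#' Rectangular TSV or CSV (delimiter sniffed from the header line): first
#' column feature ids, header row sample ids.  Cells matching one of the
#' `missingEncodings` become missing; any other non-numeric cell is a parse
#' error naming its row and column.  Some repositories encode missingness
#' as zero: `zeroAsMissing` converts exact zeros to missing.
#'
#' @param path input file.
#' @param missingEncodings character values treated as missing.
#' @param zeroAsMissing treat exact zeros as missing values.
#' @param transpose set when the file is sample x feature.
#' @param sep field delimiter; sniffed from the header when `NULL`.
#' @return An [AbundanceMatrix-class].
#' @export
readAbundanceMatrix <- function(path, missingEncodings = c("", "NA", "NaN"),
                                zeroAsMissing = FALSE, transpose = FALSE,
                                sep = NULL) {
  if (is.null(sep)) sep <- .sniffSep(path)
  df <- read.table(path, sep = sep, header = TRUE, colClasses = "character",
                   check.names = FALSE, quote = "\"", comment.char = "",
                   stringsAsFactors = FALSE, na.strings = character())
  if (ncol(df) < 2) stop("expected a feature-id column plus sample columns")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(names(df)[-1]))
    stop("duplicate sample id(s): ",
         paste(unique(names(df)[-1][duplicated(names(df)[-1])]),
               collapse = ", "))
  cells <- as.matrix(df[, -1, drop = FALSE])
  vals <- matrix(NA_real_, nrow(cells), ncol(cells),
                 dimnames = list(ids, colnames(cells)))
  missing <- matrix(FALSE, nrow(cells), ncol(cells))
  for (j in seq_len(ncol(cells))) {
    raw <- trimws(cells[, j])
    isMiss <- raw %in% missingEncodings
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!isMiss & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                   raw[bad[1]], ids[bad[1]], colnames(cells)[j]))
    vals[, j] <- num
    missing[, j] <- isMiss
  }
  if (zeroAsMissing) missing <- missing | (!is.na(vals) & vals == 0)
  vals[missing] <- NA_real_
  if (transpose) {
    vals <- t(vals)
  }
  AbundanceMatrix(vals)
}

#' Write an abundance matrix as TSV
#'
#' Inverse of [readAbundanceMatrix()]: feature ids in the first column,
#' missing cells written as `missingAs`.  The read-write-read round trip is
#' lossless for values and mask.
#'
#' @param x an [AbundanceMatrix-class] or numeric matrix.
#' @param path output file.
#' @param missingAs encoding written for missing cells (default `"NA"`).
#' @export
writeAbundanceMatrix <- function(x, path, missingAs = "NA") {
  m <- if (is(x, "AbundanceMatrix")) abundanceValues(x) else as.matrix(x)
  out <- cbind(feature_id = rownames(m),
               as.data.frame(m, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = missingAs)
}

#' Read a sample grouping table
#'
#' Two-column TSV/CSV with header: sample id and group label (the combined
#' subject-sample-factor string, preserved verbatim).
#'
#' @param path input file.
#' @param matrix optional [AbundanceMatrix-class] (or matrix) to validate
#'   against: unknown or unlabelled samples are errors.
#' @return Named character vector mapping sample id to group.
#' @export
readSampleGroups <- function(path, matrix = NULL) {
  sep <- .sniffSep(path)
  df <- read.table(path, sep = sep, header = TRUE, colClasses = "character",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected columns: sample_id, group")
  if (anyDuplicated(df[[1]]))
    stop("duplicate sample id(s) in groups table")
  groups <- setNames(df[[2]], df[[1]])
  if (any(!nzchar(groups))) stop("empty group label(s) in groups table")
  if (!is.null(matrix)) groups <- .resolveGroups(matrix, groups)
  groups
}

#' Write a long-format correlation table as TSV
#'
#' @param x a [CorrelationMatrixSet-class] (converted via
#'   [correlationLong()]) or an already-long `data.frame`.
#' @param path output file.
#' @param diagonal include diagonal entries when converting a set.
#' @export
writeCorrelationLong <- function(x, path, diagonal = TRUE) {
  df <- if (is(x, "CorrelationMatrixSet")) correlationLong(x, diagonal) else x
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
}
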