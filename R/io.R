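## Delimited-text readers and writers. The canonical interchange format
## is a rectangular table with the first row holding variable labels and
## the first column holding sample labels; a transpose flag switches
## between variables-as-columns and variables-as-rows sources.

.sepForPath <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a labelled data matrix from delimited text
#'
#' Reads a CSV/TSV table whose first row holds variable labels and first
#' column holds sample labels. With \code{transpose = TRUE} the table is
#' transposed after reading, switching between the two analysis
#' orientations (e.g. genes-as-variables versus cells-as-variables).
#'
#' @param path file path; the delimiter defaults to \code{","} for
#'   \code{.csv} and tab otherwise.
#' @param transpose logical.
#' @param sep optional explicit field separator.
#' @return a \code{\link{DataMatrix}}.
#' @export
readDataMatrix <- function(path, transpose = FALSE, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sepForPath(path, sep)
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           fill = FALSE)
  mat <- as.matrix(tab)
  if (!is.numeric(mat))
    stop("non-numeric cells in ", path)
  if (anyNA(mat)) stop("missing values in ", path,
                       "; impute or filter before loading")
  if (transpose) mat <- t(mat)
  DataMatrix(mat, transposed = transpose)
}

#' Write a data matrix to delimited text
#'
#' Writes the labelled matrix in the same layout \code{readDataMatrix}
#' expects, so fixtures round-trip.
#'
#' @param x a \code{\link{DataMatrix}}.
#' @param path output path (\code{.csv} switches to comma separation).
#' @param sep optional explicit separator.
#' @return invisibly, \code{path}.
#' @export
writeDataMatrix <- function(x, path, sep = NULL) {
  stopifnot(is(x, "DataMatrix"))
  sep <- .sepForPath(path, sep)
  df <- data.frame(sample = sampleLabels(x), x@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- ""
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a discrete (binned) matrix as integer codes
#'
#' @param x a \code{\link{DiscreteMatrix}}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writeDiscreteMatrix <- function(x, path) {
  stopifnot(is(x, "DiscreteMatrix"))
  df <- data.frame(sample = rownames(x@codes), x@codes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- ""
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a landscape as TSV
#'
#' Columns: degree, face (variable labels joined by \code{";"}), and the
#' value in bits.
#'
#' @param landscape an \code{\link{InfoLandscape}}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writeLandscape <- function(landscape, path) {
  stopifnot(is(landscape, "InfoLandscape"))
  labels <- landscape@metadata$varLabels
  face <- vapply(landscape@keys, function(k)
    paste(labels[.keyToFace(k)], collapse = ";"), character(1),
    USE.NAMES = FALSE)
  df <- data.frame(degree = landscape@degrees, face = face,
                   value_bits = landscape@values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize information paths to JSON
#'
#' @param paths list of \code{\link{InfoPath}}.
#' @param path output JSON path.
#' @return invisibly, \code{path}.
#' @export
writePaths <- function(paths, path) {
  out <- lapply(paths, function(p)
    list(direction = p@direction, variables = p@vars, values = p@values,
         stop_reason = p@stopReason))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
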