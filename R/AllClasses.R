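#' @import methods
NULL

#' DataMatrix: labelled samples-by-variables measurements
#'
#' Container for an \eqn{m \times n} real-valued measurement matrix with
#' sample labels on rows and variable labels on columns. Depending on the
#' analysis, "variables" may be genes (samples are cells) or cells (samples
#' are genes); the \code{transposed} flag records whether the source table
#' was transposed on loading.
#'
#' @slot values numeric matrix, \eqn{m \times n}, with dimnames.
#' @slot transposed logical scalar; \code{TRUE} if the source file held
#'   variables on rows and was transposed on import.
#' @export
setClass("DataMatrix",
         representation(values = "matrix", transposed = "logical"))

setValidity("DataMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (nrow(v) < 2L) return("at least two samples (rows) are required")
  if (ncol(v) < 1L) return("at least one variable (column) is required")
  if (anyNA(v) || any(!is.finite(v)))
    return("values must be finite and non-missing")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry sample (row) and variable (column) labels")
  if (anyDuplicated(rownames(v))) return("duplicated sample labels")
  if (anyDuplicated(colnames(v))) return("duplicated variable labels")
  if (length(object@transposed) != 1L) return("transposed must be a scalar")
  TRUE
})

#' Construct a DataMatrix
#'
#' @param values numeric matrix (samples in rows, variables in columns).
#' @param sampleLabels,variableLabels optional character labels; defaults
#'   are taken from \code{dimnames(values)} or generated.
#' @param transposed logical; set by \code{\link{readDataMatrix}} when the
#'   source table was transposed.
#' @return a \code{DataMatrix} object.
#' @examples
#' x <- DataMatrix(matrix(rnorm(20), 5, 4))
#' nSamples(x); nVariables(x)
#' @export
DataMatrix <- function(values, sampleLabels = NULL, variableLabels = NULL,
                       transposed = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sampleLabels))
    sampleLabels <- rownames(values) %||% paste0("s", seq_len(nrow(values)))
  if (is.null(variableLabels))
    variableLabels <- colnames(values) %||% paste0("v", seq_len(ncol(values)))
  dimnames(values) <- list(sampleLabels, variableLabels)
  new("DataMatrix", values = values, transposed = isTRUE(transposed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' BinningScheme: per-variable equal-width graining
#'
#' Records, for each variable, the number of bins and the interval bounds
#' (the minimum and maximum measured values) used to discretize it.
#'
#' @slot nBins integer vector of bin counts \eqn{N_j \ge 1}.
#' @slot lo,hi numeric vectors of interval bounds in data units.
#' @slot varLabels character vector of variable labels.
#' @export
setClass("BinningScheme",
         representation(nBins = "integer", lo = "numeric", hi = "numeric",
                        varLabels = "character"))

setValidity("BinningScheme", function(object) {
  n <- length(object@nBins)
  if (length(object@lo) != n || length(object@hi) != n ||
      length(object@varLabels) != n)
    return("nBins, lo, hi and varLabels must have equal length")
  if (any(object@nBins < 1L)) return("all bin counts must be >= 1")
  if (any(object@lo > object@hi)) return("lo must not exceed hi")
  if (anyNA(object@lo) || anyNA(object@hi)) return("non-finite bounds")
  TRUE
})

#' DiscreteMatrix: binned integer codes
#'
#' The result of discretizing a \code{DataMatrix}: an \eqn{m \times n}
#' integer matrix with entry \eqn{c_{ij} \in \{0, \dots, N_j - 1\}},
#' together with the \code{BinningScheme} that produced it.
#'
#' @slot codes integer matrix of bin codes with dimnames.
#' @slot scheme the \code{BinningScheme} used.
#' @export
setClass("DiscreteMatrix",
         representation(codes = "matrix", scheme = "BinningScheme"))

setValidity("DiscreteMatrix", function(object) {
  codes <- object@codes
  if (!is.integer(codes)) return("codes must be an integer matrix")
  if (ncol(codes) != length(object@scheme@nBins))
    return("codes and scheme disagree on the number of variables")
  if (anyNA(codes)) return("missing codes")
  for (j in seq_len(ncol(codes))) {
    if (any(codes[, j] < 0L) || any(codes[, j] >= object@scheme@nBins[j]))
      return(sprintf("codes of variable %d outside its alphabet", j))
  }
  if (is.null(rownames(codes)) || is.null(colnames(codes)))
    return("codes must carry labels")
  TRUE
})

#' JointDist: sparse joint probability mass on a product alphabet
#'
#' A probability mass function over the product of finite alphabets of an
#' ordered subset of variables, stored sparsely: only atoms with positive
#' mass are kept.
#'
#' @slot vars integer indices of the variables (in the ambient numbering).
#' @slot sizes integer alphabet sizes, one per variable in \code{vars}.
#' @slot atoms integer matrix; row \eqn{i} is the code tuple of atom
#'   \eqn{i}, entries in \eqn{\{0, \dots, \mathrm{sizes}_j - 1\}}.
#' @slot probs numeric positive masses summing to one.
#' @export
setClass("JointDist",
         representation(vars = "integer", sizes = "integer",
                        atoms = "matrix", probs = "numeric"))

setValidity("JointDist", function(object) {
  k <- length(object@vars)
  if (k == 0L) return("at least one variable required")
  if (length(object@sizes) != k) return("sizes must match vars")
  if (anyDuplicated(object@vars)) return("duplicated variable indices")
  if (ncol(object@atoms) != k) return("atoms must have one column per variable")
  if (nrow(object@atoms) != length(object@probs))
    return("atoms and probs must align")
  if (any(object@probs <= 0)) return("all stored masses must be positive")
  if (abs(sum(object@probs) - 1) > 1e-9)
    return("masses must sum to one")
  for (j in seq_len(k)) {
    if (any(object@atoms[, j] < 0L) || any(object@atoms[, j] >= object@sizes[j]))
      return("atom codes outside the alphabet")
  }
  if (anyDuplicated(.rowKeys(object@atoms))) return("duplicated atoms")
  TRUE
})

#' Construct a JointDist
#'
#' @param atoms integer matrix of code tuples (rows are atoms).
#' @param probs numeric masses; zero-mass rows are dropped, remaining mass
#'   must sum to one.
#' @param vars integer variable indices (default \code{1:ncol(atoms)}).
#' @param sizes integer alphabet sizes (default: observed max code + 1).
#' @return a \code{JointDist}.
#' @examples
#' ## fair coin pair
#' JointDist(rbind(c(0,0), c(0,1), c(1,0), c(1,1)), rep(1/4, 4))
#' @export
JointDist <- function(atoms, probs, vars = NULL, sizes = NULL) {
  atoms <- as.matrix(atoms)
  storage.mode(atoms) <- "integer"
  keep <- probs > 0
  atoms <- atoms[keep, , drop = FALSE]
  probs <- probs[keep]
  if (is.null(vars)) vars <- seq_len(ncol(atoms))
  if (is.null(sizes)) sizes <- apply(atoms, 2L, max) + 1L
  new("JointDist", vars = as.integer(vars), sizes = as.integer(sizes),
      atoms = atoms, probs = as.numeric(probs))
}

#' InfoLandscape: measure values over the lattice of faces
#'
#' Holds the value of one information measure (joint entropy \code{"H"},
#' mutual information \code{"I"}, or total correlation \code{"G"}) on every
#' face (variable subset) of the simplicial lattice up to degree
#' \code{kmax}.
#'
#' @slot measure one of \code{"H"}, \code{"I"}, \code{"G"}.
#' @slot n number of variables; \code{kmax} dimension cap.
#' @slot kmax integer dimension cap.
#' @slot keys face keys (sorted indices joined by \code{";"}).
#' @slot degrees integer face degrees parallel to \code{keys}.
#' @slot values numeric measure values in bits, parallel to \code{keys}.
#' @slot metadata list (sample size \code{m}, graining \code{N},
#'   undersampling dimension \code{ku} when known, variable labels).
#' @export
setClass("InfoLandscape",
         representation(measure = "character", n = "integer", kmax = "integer",
                        keys = "character", degrees = "integer",
                        values = "numeric", metadata = "list"))

setValidity("InfoLandscape", function(object) {
  if (!object@measure %in% c("H", "I", "G")) return("unknown measure")
  if (length(object@keys) != length(object@values) ||
      length(object@keys) != length(object@degrees))
    return("keys, degrees and values must align")
  if (anyDuplicated(object@keys)) return("duplicated faces")
  TRUE
})

#' InfoPath: an information path along the lattice
#'
#' An ordered sequence of variables \eqn{\sigma_1, \dots, \sigma_k} and the
#' measure values of its prefix faces, produced by
#' \code{\link{extremalPaths}}.
#'
#' @slot vars integer variable indices in visiting order.
#' @slot values numeric per-step measure values (bits).
#' @slot direction \code{"max"} or \code{"min"}.
#' @slot stopReason one of \code{"first-minimum"}, \code{"kmax-reached"},
#'   \code{"exhausted"}.
#' @export
setClass("InfoPath",
         representation(vars = "integer", values = "numeric",
                        direction = "character", stopReason = "character"))

setValidity("InfoPath", function(object) {
  if (anyDuplicated(object@vars)) return("path revisits a variable")
  if (length(object@vars) != length(object@values))
    return("vars and values must align")
  if (!object@direction %in% c("max", "min")) return("bad direction")
  if (!object@stopReason %in% c("first-minimum", "kmax-reached", "exhausted"))
    return("bad stopReason")
  TRUE
})

#' UndersamplingReport: per-degree entropy saturation and ku
#'
#' Produced by \code{\link{undersamplingDimension}}. A degree-\eqn{k} face
#' is saturated when its empirical joint entropy equals the hard ceiling
#' \eqn{\log_2 m} imposed by the sample size. \code{ku} is one less than
#' the first degree at which the saturated fraction exceeds \code{pU}.
#'
#' @slot ku integer undersampling dimension.
#' @slot saturation numeric fraction of saturated faces per degree.
#' @slot pU numeric threshold (default 0.05).
#' @slot m,n integer sample and variable counts; \code{kmax} the scanned cap.
#' @slot kmax integer highest degree scanned.
#' @export
setClass("UndersamplingReport",
         representation(ku = "integer", saturation = "numeric", pU = "numeric",
                        m = "integer", n = "integer", kmax = "integer"))

#' NullDistribution: pooled shuffle null for one degree
#'
#' @slot degree integer k.
#' @slot values numeric pooled shuffled measure values
#'   (\code{nShuffles} x number of degree-k faces).
#' @slot nShuffles integer number of shuffles.
#' @slot lower,upper numeric significance cutoffs (empirical quantiles);
#'   \code{lower} is \code{-Inf} for the one-sided degree-2 test.
#' @slot level numeric total significance level.
#' @slot sided character, \code{"one"} or \code{"two"}.
#' @export
setClass("NullDistribution",
         representation(degree = "integer", values = "numeric",
                        nShuffles = "integer", lower = "numeric",
                        upper = "numeric", level = "numeric",
                        sided = "character"))

#' DependenceReport: shuffle-test significance per face
#'
#' @slot table data.frame with columns \code{face}, \code{degree},
#'   \code{observed}, \code{lower}, \code{upper}, \code{significant},
#'   \code{side}.
#' @slot nulls list of \code{NullDistribution}, one per tested degree.
#' @slot params list of test parameters (nShuffles, p2, pk, seed).
#' @export
setClass("DependenceReport",
         representation(table = "data.frame", nulls = "list", params = "list"))

## ---- show methods -------------------------------------------------------

setMethod("show", "DataMatrix", function(object) {
  cat(sprintf("DataMatrix: %d samples x %d variables%s\n",
              nrow(object@values), ncol(object@values),
              if (object@transposed) " (transposed on import)" else ""))
  cat("  variables:", paste(utils::head(colnames(object@values), 6L),
                            collapse = ", "),
      if (ncol(object@values) > 6L) "..." else "", "\n")
})

setMethod("show", "BinningScheme", function(object) {
  cat(sprintf("BinningScheme: %d variables, bins %s\n",
              length(object@nBins),
              paste(unique(object@nBins), collapse = "/")))
})

setMethod("show", "DiscreteMatrix", function(object) {
  cat(sprintf("DiscreteMatrix: %d samples x %d variables, alphabets %s\n",
              nrow(object@codes), ncol(object@codes),
              paste(unique(object@scheme@nBins), collapse = "/")))
})

setMethod("show", "JointDist", function(object) {
  cat(sprintf("JointDist on variables {%s}: %d atoms over %s states\n",
              paste(object@vars, collapse = ","), nrow(object@atoms),
              prod(as.numeric(object@sizes))))
})

setMethod("show", "InfoLandscape", function(object) {
  cat(sprintf("InfoLandscape (%s): n = %d, kmax = %d, %d faces\n",
              object@measure, object@n, object@kmax, length(object@keys)))
})

setMethod("show", "InfoPath", function(object) {
  cat(sprintf("InfoPath (%s): %s | values %s | stop: %s\n",
              object@direction, paste(object@vars, collapse = " -> "),
              paste(sprintf("%.3f", object@values), collapse = ", "),
              object@stopReason))
})

setMethod("show", "UndersamplingReport", function(object) {
  cat(sprintf("UndersamplingReport: ku = %d (pU = %g, m = %d, n = %d)\n",
              object@ku, object@pU, object@m, object@n))
  cat("  saturated fraction by degree:",
      paste(sprintf("%.3f", object@saturation), collapse = " "), "\n")
})

setMethod("show", "DependenceReport", function(object) {
  cat(sprintf("DependenceReport: %d faces tested, %d significant\n",
              nrow(object@table), sum(object@table$significant)))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for infoLattice containers
#'
#' Small accessor functions exposing slot contents without direct slot
#' access: dimensions and labels of data containers, code matrices,
#' probability tables, landscape tables and report tables.
#'
#' @param x an infoLattice object.
#' @return the requested component; see individual functions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
nSamples <- function(x) {
  if (is(x, "DataMatrix")) nrow(x@values)
  else if (is(x, "DiscreteMatrix")) nrow(x@codes)
  else stop("no sample dimension for this object")
}

#' @rdname accessors
#' @export
nVariables <- function(x) {
  if (is(x, "DataMatrix")) ncol(x@values)
  else if (is(x, "DiscreteMatrix")) ncol(x@codes)
  else if (is(x, "JointDist")) length(x@vars)
  else if (is(x, "InfoLandscape")) x@n
  else stop("no variable dimension for this object")
}

#' @rdname accessors
#' @export
sampleLabels <- function(x) {
  if (is(x, "DataMatrix")) rownames(x@values)
  else if (is(x, "DiscreteMatrix")) rownames(x@codes)
  else stop("no sample labels for this object")
}

#' @rdname accessors
#' @export
variableLabels <- function(x) {
  if (is(x, "DataMatrix")) colnames(x@values)
  else if (is(x, "DiscreteMatrix")) colnames(x@codes)
  else if (is(x, "BinningScheme")) x@varLabels
  else stop("no variable labels for this object")
}

#' @rdname accessors
#' @export
dataValues <- function(x) {
  stopifnot(is(x, "DataMatrix"))
  x@values
}

#' @rdname accessors
#' @export
codes <- function(x) {
  stopifnot(is(x, "DiscreteMatrix"))
  x@codes
}

#' @rdname accessors
#' @export
binningScheme <- function(x) {
  stopifnot(is(x, "DiscreteMatrix"))
  x@scheme
}

#' @rdname accessors
#' @export
binCounts <- function(x) {
  if (is(x, "BinningScheme")) x@nBins
  else if (is(x, "DiscreteMatrix")) x@scheme@nBins
  else stop("no bin counts for this object")
}

#' @rdname accessors
#' @export
probTable <- function(x) {
  stopifnot(is(x, "JointDist"))
  data.frame(atom = .rowKeys(x@atoms), prob = x@probs,
             stringsAsFactors = FALSE)
}

#' Tabulate a landscape as a data frame
#'
#' @param x an \code{InfoLandscape}.
#' @return data.frame with columns \code{degree}, \code{face} (semicolon
#'   joined indices) and \code{value} (bits).
#' @export
landscapeTable <- function(x) {
  stopifnot(is(x, "InfoLandscape"))
  data.frame(degree = x@degrees, face = x@keys, value = x@values,
             stringsAsFactors = FALSE)
}

#' Look up one face of a landscape
#'
#' @param x an \code{InfoLandscape}.
#' @param face integer vector of variable indices.
#' @return the measure value in bits.
#' @export
faceValue <- function(x, face) {
  stopifnot(is(x, "InfoLandscape"))
  key <- .faceKey(face)
  i <- match(key, x@keys)
  if (is.na(i)) stop("face {", key, "} not present in the landscape")
  x@values[i]
}

#' @rdname accessors
#' @export
pathVariables <- function(x) {
  stopifnot(is(x, "InfoPath"))
  x@vars
}

#' @rdname accessors
#' @export
pathValues <- function(x) {
  stopifnot(is(x, "InfoPath"))
  x@values
}

#' @rdname accessors
#' @export
undersamplingK <- function(x) {
  stopifnot(is(x, "UndersamplingReport"))
  x@ku
}

#' @rdname accessors
#' @export
saturationFractions <- function(x) {
  stopifnot(is(x, "UndersamplingReport"))
  x@saturation
}

#' @rdname accessors
#' @export
dependenceTable <- function(x) {
  stopifnot(is(x, "DependenceReport"))
  x@table
}

#' @rdname accessors
#' @export
nullDistributions <- function(x) {
  stopifnot(is(x, "DependenceReport"))
  x@nulls
}
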