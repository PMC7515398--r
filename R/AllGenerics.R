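#' Generics for information measures
#'
#' Information measures are defined on \code{\link{JointDist}} objects and,
#' by locality (a measure on a subset of variables depends only on the
#' marginal law on that subset), on \code{\link{DiscreteMatrix}} objects,
#' where the empirical joint on the requested subset is counted first.
#'
#' @param x a \code{JointDist} or \code{DiscreteMatrix}.
#' @param ... passed to methods.
#' @name infoGenerics
NULL

#' @rdname infoGenerics
#' @export
setGeneric("shannonEntropy", function(x, ...) standardGeneric("shannonEntropy"))

#' @rdname infoGenerics
#' @export
setGeneric("jointEntropy", function(x, subset, ...)
  standardGeneric("jointEntropy"))

#' @rdname infoGenerics
#' @export
setGeneric("mutualInfo", function(x, subset, ...) standardGeneric("mutualInfo"))

#' @rdname infoGenerics
#' @export
setGeneric("totalCorrelation", function(x, subset, ...)
  standardGeneric("totalCorrelation"))

#' @rdname infoGenerics
#' @export
setGeneric("marginalize", function(x, subset, ...)
  standardGeneric("marginalize"))

#' @rdname infoGenerics
#' @export
setGeneric("independenceCheck", function(x, ...)
  standardGeneric("independenceCheck"))
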