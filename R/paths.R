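## Extremal information paths on the simplicial lattice.
##
## A path adds one variable at a time; by the chain relation, the slope of
## the step from a prefix face F to F + {v} is
## I_{k+1} - I_k = -(conditional mutual information of the step), so a
## path keeps decreasing exactly while positive conditional mutual
## information is available. The first-minimum stopping rule ends a path
## when no candidate step has positive conditional mutual information
## (a change of sign of the conditional mutual information).

## Mutable cache of face -> Ik over the search, backed by the H table.
.ikCache <- function(codes, kmaxNeeded) {
  henv <- new.env(parent = emptyenv(), size = 2048L)
  ienv <- new.env(parent = emptyenv(), size = 2048L)
  hOf <- function(face) {
    key <- .faceKey(face)
    if (!exists(key, envir = henv, inherits = FALSE))
      assign(key, .faceEntropy(codes, face), envir = henv)
    get(key, envir = henv, inherits = FALSE)
  }
  iOf <- function(face) {
    key <- .faceKey(face)
    if (!exists(key, envir = ienv, inherits = FALSE)) {
      total <- 0
      for (tset in .allSubsets(face))
        total <- total + (-1)^(length(tset) - 1) * hOf(tset)
      assign(key, total, envir = ienv)
    }
    get(key, envir = ienv, inherits = FALSE)
  }
  list(h = hOf, i = iOf)
}

.mkPath <- function(vars, values, direction, stopReason) {
  new("InfoPath", vars = as.integer(vars), values = as.numeric(values),
      direction = direction, stopReason = stopReason)
}

## Rank paths: longer first; among equal lengths, larger terminal value
## first for direction = "max", smaller first for "min".
.rankPaths <- function(paths, direction) {
  if (length(paths) == 0L) return(paths)
  len <- vapply(paths, function(p) length(p@vars), integer(1))
  term <- vapply(paths, function(p) p@values[length(p@values)], numeric(1))
  if (direction == "min") term <- -term
  paths[order(-len, -term)]
}

## Drop paths whose support set duplicates an earlier (better ranked) one.
.dedupPaths <- function(paths) {
  seen <- character(0)
  keep <- logical(length(paths))
  for (i in seq_along(paths)) {
    key <- .faceKey(paths[[i]]@vars)
    if (!key %in% seen) {
      seen <- c(seen, key)
      keep[i] <- TRUE
    }
  }
  paths[keep]
}

.greedyPaths <- function(iOf, n, direction, kmax, beamWidth) {
  out <- list()
  for (start in seq_len(n)) {
    ## each beam entry: list(vars, values)
    beams <- list(list(vars = start, values = iOf(start)))
    finished <- list()
    while (length(beams) > 0L) {
      nextBeams <- list()
      for (b in beams) {
        k <- length(b$vars)
        if (k >= kmax) {
          finished[[length(finished) + 1L]] <-
            .mkPath(b$vars, b$values, direction, "kmax-reached")
          next
        }
        cand <- setdiff(seq_len(n), b$vars)
        iNext <- vapply(cand, function(v) iOf(c(b$vars, v)), numeric(1))
        cur <- b$values[k]
        ## viable steps strictly decrease I (positive conditional MI)
        viable <- which(iNext < cur)
        if (length(viable) == 0L) {
          finished[[length(finished) + 1L]] <-
            .mkPath(b$vars, b$values, direction, "first-minimum")
          next
        }
        ord <- if (direction == "max")
          viable[order(-iNext[viable], cand[viable])]
        else
          viable[order(iNext[viable], cand[viable])]
        take <- utils::head(ord, beamWidth)
        for (j in take) {
          nextBeams[[length(nextBeams) + 1L]] <-
            list(vars = c(b$vars, cand[j]), values = c(b$values, iNext[j]))
        }
      }
      if (length(nextBeams) > beamWidth) {
        term <- vapply(nextBeams, function(b) b$values[length(b$values)],
                       numeric(1))
        if (direction == "min") term <- -term
        nextBeams <- nextBeams[utils::head(order(-term), beamWidth)]
      }
      beams <- nextBeams
    }
    out <- c(out, finished)
  }
  out
}

.exhaustivePaths <- function(iOf, n, direction, kmax) {
  out <- list()
  recur <- function(vars, values) {
    k <- length(vars)
    if (k >= kmax) {
      out[[length(out) + 1L]] <<- .mkPath(vars, values, direction,
                                          "kmax-reached")
      return(invisible())
    }
    cand <- setdiff(seq_len(n), vars)
    iNext <- vapply(cand, function(v) iOf(c(vars, v)), numeric(1))
    viable <- which(iNext < values[k])
    if (length(viable) == 0L) {
      out[[length(out) + 1L]] <<- .mkPath(vars, values, direction,
                                          "first-minimum")
      return(invisible())
    }
    for (j in viable) recur(c(vars, cand[j]), c(values, iNext[j]))
    invisible()
  }
  for (start in seq_len(n)) recur(start, iOf(start))
  out
}

#' Extremal information paths
#'
#' Searches the lattice for the longest information paths: nested chains
#' of faces, grown one variable at a time, whose \eqn{I_k} values strictly
#' decrease (each step consumes positive conditional mutual information)
#' and that end at the first minimum. For \code{direction = "max"} each
#' step picks the candidate keeping \eqn{I_{k+1}} largest (minimal
#' conditional mutual information); for \code{"min"} the candidate driving
#' \eqn{I_{k+1}} lowest (these reach the synergistic, negative-\eqn{I}
#' region). Candidate ties are broken by the lowest variable index.
#'
#' The default greedy search (one beam per starting variable) is
#' \eqn{O(n^2 k_{max})} face evaluations; \code{search = "exhaustive"}
#' enumerates every admissible path and is intended for \eqn{n \le 12}.
#' Paths that are permutations of the same face set are deduplicated,
#' keeping the best ranked; ranking is by length, then terminal value.
#'
#' @param x a \code{\link{DiscreteMatrix}}.
#' @param direction \code{"max"} or \code{"min"}.
#' @param kmax dimension cap on path length; the undersampling dimension
#'   \code{ku} is the recommended cap.
#' @param search \code{"greedy"} (default) or \code{"exhaustive"}.
#' @param beamWidth beam width for the greedy search (default 1).
#' @return list of \code{\link{InfoPath}} objects, ranked.
#' @examples
#' dm <- discretize(plantedModuleSamples(6, 400, module = 1:3,
#'                                       copyNoise = 0.05, seed = 7), N = 3)
#' extremalPaths(dm, "max", kmax = 5)[[1]]
#' @export
extremalPaths <- function(x, direction = c("max", "min"), kmax = NULL,
                          search = c("greedy", "exhaustive"), beamWidth = 1L) {
  stopifnot(is(x, "DiscreteMatrix"))
  direction <- match.arg(direction)
  search <- match.arg(search)
  n <- nVariables(x)
  if (n < 1L || nSamples(x) < 2L) stop("empty or degenerate data")
  if (is.null(kmax)) kmax <- n
  kmax <- as.integer(kmax)
  if (kmax < 1L || kmax > n) stop("kmax must lie in [1, n]")
  if (search == "exhaustive" && n > 12L)
    stop("exhaustive search is limited to n <= 12")
  cache <- .ikCache(x@codes, kmax)
  paths <- if (search == "greedy")
    .greedyPaths(cache$i, n, direction, kmax, as.integer(beamWidth))
  else
    .exhaustivePaths(cache$i, n, direction, kmax)
  .dedupPaths(.rankPaths(paths, direction))
}

#' Group longest paths into disjoint components
#'
#' Scans a ranked path list in order and keeps every path whose support is
#' disjoint from all previously kept ones; each kept path seeds one
#' component. This recovers separated blocks of variables (for example
#' two sub-populations) from the leading extremal paths.
#'
#' @param paths list of \code{\link{InfoPath}} as returned by
#'   \code{\link{extremalPaths}}.
#' @return list of integer vectors (one support set per component).
#' @export
pathComponents <- function(paths) {
  comps <- list()
  used <- integer(0)
  for (p in paths) {
    if (length(intersect(p@vars, used)) == 0L) {
      comps[[length(comps) + 1L]] <- sort(p@vars)
      used <- c(used, p@vars)
    }
  }
  comps
}
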