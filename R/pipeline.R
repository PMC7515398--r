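## Full-pipeline orchestration: discretize, undersampling scan,
## landscapes, extremal paths, dependence test, with reproducible
## configuration and logging.

#' Build an analysis configuration
#'
#' Collects every tunable of the pipeline in one list so that a run is
#' fully determined by (input, config, seed). The configuration is
#' serialized into every output bundle.
#'
#' @param input path to a delimited data matrix (ignored when \code{data}
#'   is given).
#' @param data optionally, a \code{\link{DataMatrix}} directly.
#' @param transpose transpose the input table on load.
#' @param N graining (scalar or per-variable bin counts), default 9.
#' @param kmax dimension cap for landscapes and paths.
#' @param pU undersampling threshold (default 0.05).
#' @param nShuffles,p2,pk dependence-test parameters (defaults 17,
#'   0.05, 0.1).
#' @param search,beamWidth path search mode (\code{"greedy"} or
#'   \code{"exhaustive"}) and beam width.
#' @param seed integer RNG seed for shuffles.
#' @param outDir output directory.
#' @return a list of class \code{"analysisConfig"}.
#' @export
analysisConfig <- function(input = NULL, data = NULL, transpose = FALSE,
                           N = 9L, kmax = 3L, pU = 0.05, nShuffles = 17L,
                           p2 = 0.05, pk = 0.1, search = "greedy",
                           beamWidth = 1L, seed = 1L, outDir = tempfile("run")) {
  if (is.null(input) && is.null(data))
    stop("either input (a file path) or data (a DataMatrix) is required")
  cfg <- list(input = input, data = data, transpose = transpose, N = N,
              kmax = as.integer(kmax), pU = pU,
              nShuffles = as.integer(nShuffles), p2 = p2, pk = pk,
              search = search, beamWidth = as.integer(beamWidth),
              seed = as.integer(seed), outDir = outDir)
  class(cfg) <- "analysisConfig"
  cfg
}

.configFingerprint <- function(cfg) {
  flat <- cfg[setdiff(names(cfg), c("data", "outDir"))]
  txt <- paste(deparse(flat), collapse = "")
  ## cheap stable fingerprint: md5 of the serialized scalar settings
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' Reads (or takes) the data matrix, discretizes it, estimates the
#' undersampling dimension, computes the H/I/G landscapes up to
#' \code{min(kmax, ku)}, extracts maximal and minimal information paths,
#' runs the shuffle dependence test, and writes every result with a run
#' log (configuration fingerprint and seed) to \code{outDir}. Identical
#' (input, config, seed) produce identical outputs.
#'
#' @param config an \code{\link{analysisConfig}}.
#' @return invisibly, a list with all computed objects
#'   (\code{discrete}, \code{ku}, \code{landscapes}, \code{pathsMax},
#'   \code{pathsMin}, \code{dependence}, \code{files}).
#' @export
runAnalysis <- function(config) {
  stopifnot(inherits(config, "analysisConfig"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("[", what, "] ", conditionMessage(e), call. = FALSE))
  }
  x <- stage("load", {
    if (!is.null(config$data)) config$data
    else readDataMatrix(config$input, transpose = config$transpose)
  })
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  fp <- file.path
  out <- config$outDir
  dm <- stage("discretize", discretize(x, N = config$N))
  files <- character(0)
  files["discrete"] <- writeDiscreteMatrix(dm, fp(out, "discrete.tsv"))
  kur <- stage("undersampling",
               undersamplingDimension(dm, pU = config$pU,
                                      kmax = min(config$kmax, nVariables(x))))
  kEff <- max(1L, min(config$kmax, undersamplingK(kur)))
  jsonlite::write_json(
    list(ku = undersamplingK(kur), saturation = saturationFractions(kur),
         pU = kur@pU, m = kur@m, n = kur@n, seed = config$seed),
    fp(out, "ku.json"), auto_unbox = TRUE, digits = NA)
  files["ku"] <- fp(out, "ku.json")
  landscapes <- list()
  for (meas in c("H", "I", "G")) {
    ls <- stage(paste0("landscape-", meas),
                computeLandscape(dm, meas, kmax = kEff,
                                 ku = undersamplingK(kur)))
    landscapes[[meas]] <- ls
    f <- fp(out, sprintf("landscape_%s.tsv", meas))
    writeLandscape(ls, f)
    files[paste0("landscape", meas)] <- f
  }
  pathsMax <- stage("paths", extremalPaths(dm, "max", kmax = kEff,
                                           search = config$search,
                                           beamWidth = config$beamWidth))
  pathsMin <- stage("paths", extremalPaths(dm, "min", kmax = kEff,
                                           search = config$search,
                                           beamWidth = config$beamWidth))
  files["pathsMax"] <- writePaths(pathsMax, fp(out, "paths_max.json"))
  files["pathsMin"] <- writePaths(pathsMin, fp(out, "paths_min.json"))
  dep <- stage("dependence",
               dependenceTest(dm, kRange = 2:max(2L, kEff),
                              nShuffles = config$nShuffles, p2 = config$p2,
                              pk = config$pk, seed = config$seed))
  utils::write.table(dependenceTable(dep), fp(out, "deptest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  files["dependence"] <- fp(out, "deptest.tsv")
  jsonlite::write_json(
    list(fingerprint = .configFingerprint(config), seed = config$seed,
         transpose = config$transpose, N = config$N, kmax = config$kmax,
         kEffective = kEff, pU = config$pU, nShuffles = config$nShuffles,
         p2 = config$p2, pk = config$pk, search = config$search,
         beamWidth = config$beamWidth, m = nSamples(x), n = nVariables(x)),
    fp(out, "run.json"), auto_unbox = TRUE, digits = NA)
  files["run"] <- fp(out, "run.json")
  invisible(list(discrete = dm, ku = kur, landscapes = landscapes,
                 pathsMax = pathsMax, pathsMin = pathsMin, dependence = dep,
                 files = files))
}
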