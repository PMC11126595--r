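## Report assembly: the four workflow commands (stats, predict, evaluate,
## simulate) as plain functions writing UTF-8 files.  A thin command-line
## wrapper around them ships in inst/exec/biplink.R; logs go to standard
## error, data only to files.

.toolProvenance <- function(extra = list()) {
  c(list(tool = "biplink",
         version = as.character(utils::packageVersion("biplink"))), extra)
}

.logMsg <- function(...) message(...)   # message() already targets stderr

#' Write the descriptive-statistics report of an edge list
#'
#' Reads a bipartite edge list, computes the network summary, the per-node
#' degree table and the degree extremes, and writes them as
#' \code{stats.json}, \code{stats.tsv}, \code{degrees.tsv} and
#' \code{degree_extremes.tsv} under \code{outDir}.  The JSON embeds both the
#' full-precision values and the display-rounded ones (density to 5 decimals,
#' average degree to the nearest integer), plus provenance.
#'
#' @param input path to a delimited edge list (see [readEdgeTable()]).
#' @param outDir output directory (created if missing).
#' @param delimiter edge-list delimiter, \code{NULL} to auto-detect.
#' @param header does the edge list carry a header row?
#' @param top how many nodes per degree-extremes list (default 10).
#' @return named vector of the files written, invisibly.
#' @export
cmdStats <- function(input, outDir, delimiter = NULL, header = FALSE, top = 10L) {
  net <- readEdgeTable(input, delimiter = delimiter, header = header)
  s <- networkSummary(net)
  ex <- degreeExtremes(net, k = top)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  jsonPath <- file.path(outDir, "stats.json")
  jsonlite::write_json(c(.toolProvenance(list(input = input, top = top)),
                         .displayStats(s)),
                       jsonPath, auto_unbox = TRUE, digits = NA)
  tsvPath <- file.path(outDir, "stats.tsv")
  d <- .displayStats(s)
  utils::write.table(
    data.frame(property = names(d), value = unlist(d, use.names = FALSE)),
    tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  degPath <- file.path(outDir, "degrees.tsv")
  deg <- rbind(data.frame(part = "A", node = names(s@degreeA),
                          degree = as.numeric(s@degreeA), stringsAsFactors = FALSE),
               data.frame(part = "B", node = names(s@degreeB),
                          degree = as.numeric(s@degreeB), stringsAsFactors = FALSE))
  utils::write.table(deg, degPath, sep = "\t", quote = FALSE, row.names = FALSE)
  exPath <- file.path(outDir, "degree_extremes.tsv")
  utils::write.table(ex, exPath, sep = "\t", quote = FALSE, row.names = FALSE)
  .logMsg("stats: ", nrow(deg), " nodes, ", numEdges(net), " edges -> ", outDir)
  invisible(c(json = jsonPath, tsv = tsvPath, degrees = degPath,
              extremes = exPath))
}

#' Write the ranked-prediction report of an edge list
#'
#' Reads an edge list, ranks the candidate non-edges under one scoring
#' method, and writes the top \code{topK} (default 20) as a TSV with a
#' provenance header.  \code{topK = 0} writes an empty table (header only)
#' with a warning in the log.
#'
#' @inheritParams cmdStats
#' @param method one of [scoreMethods()].
#' @param topK prediction-list cut.
#' @return the file written, invisibly.
#' @export
cmdPredict <- function(input, outDir, method = "CN", topK = 20L,
                       delimiter = NULL, header = FALSE) {
  .checkMethod(method)
  net <- readEdgeTable(input, delimiter = delimiter, header = header)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(outDir, paste0("predictions_", method, ".tsv"))
  if (topK == 0L) {
    .logMsg("predict: topK = 0, writing an empty prediction table")
    preds <- data.frame(x = character(0), y = character(0),
                        method = character(0), score = numeric(0),
                        rank = integer(0), stringsAsFactors = FALSE)
  } else {
    preds <- rankCandidates(net, method, topK = topK)
  }
  writeRankedPredictions(preds, path,
                         provenance = .toolProvenance(
                           list(input = input, method = method, topK = topK)))
  .logMsg("predict: ", nrow(preds), " ", method, " predictions -> ", path)
  invisible(path)
}

#' Run the cross-validated evaluation and write its reports
#'
#' Reads an edge list, runs [evaluateLinkPrediction()] and writes the full
#' JSON report, the per-method summary TSV and the long-format TSV under
#' \code{outDir}; the best method is printed to the log.
#'
#' @inheritParams cmdStats
#' @inheritParams evaluateLinkPrediction
#' @return named vector of the files written, invisibly.
#' @export
cmdEvaluate <- function(input, outDir, methods = scoreMethods(), k = 10L,
                        n = NULL, l = NULL, seed = 1L,
                        delimiter = NULL, header = FALSE) {
  net <- readEdgeTable(input, delimiter = delimiter, header = header)
  report <- evaluateLinkPrediction(net, methods = methods, k = k, n = n,
                                   l = l, seed = seed)
  files <- writeEvaluationReport(report, outDir)
  .logMsg("evaluate: best method by mean AUC is ", report@best)
  invisible(files)
}

#' Generate a synthetic edge list with a provenance sidecar
#'
#' Runs [generateBipartite()] and writes the edge list plus a
#' \code{key = value} sidecar recording the fully resolved configuration and
#' seed; re-running from the sidecar (\code{configFile}) reproduces the edge
#' list byte-for-byte.
#'
#' @param out path of the edge list to write.
#' @param nA,nB,targetDensity,skew,blocks,withinBlockOdds,seed generator
#'   parameters, see [generateBipartite()].
#' @param configFile optional sidecar written by a previous run; when given,
#'   its values replace the other arguments.
#' @return named vector with the edge-list and sidecar paths, invisibly.
#' @export
cmdSimulate <- function(out, nA = 64L, nB = 388L, targetDensity = 0.08899,
                        skew = 0, blocks = 0L, withinBlockOdds = 1, seed = 1L,
                        configFile = NULL) {
  if (!is.null(configFile)) {
    cfg <- readGeneratorConfig(configFile)
    nA <- cfg$nA; nB <- cfg$nB; targetDensity <- cfg$targetDensity
    skew <- cfg$skew; blocks <- cfg$blocks
    withinBlockOdds <- cfg$withinBlockOdds; seed <- cfg$seed
  }
  net <- generateBipartite(nA, nB, targetDensity, skew = skew, blocks = blocks,
                           withinBlockOdds = withinBlockOdds, seed = seed)
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  writeEdgeTable(net, out)
  sidecar <- paste0(out, ".config")
  writeGeneratorConfig(list(nA = nA, nB = nB, targetDensity = targetDensity,
                            skew = skew, blocks = blocks,
                            withinBlockOdds = withinBlockOdds, seed = seed),
                       sidecar)
  .logMsg("simulate: ", numEdges(net), " edges -> ", out)
  invisible(c(edges = out, config = sidecar))
}
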