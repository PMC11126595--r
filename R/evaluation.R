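## k-fold edge-holdout cross-validation with the sampled-pair AUC and
## precision-at-L.
##
## AUC: out of n random comparisons between a held-out true edge and a true
## non-edge (both scored on the training network), AUC = (n' + 0.5 n'')/n
## where n' counts strict wins for the held-out edge and n'' counts ties.
## Precision: rank all candidate non-edges of the training network, inspect
## the top L, count how many are held-out test edges.

## seed plumbing: one user seed per run; components draw from derived
## substreams so e.g. changing the AUC sample count never changes the folds
.deriveSeed <- function(seed, stream) {
  ((seed %% 2147483647) * 48271 + stream * 7919) %% 2147483647
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Partition a network's edges into k disjoint test folds
#'
#' Draws a uniformly random partition of the edge set into \code{k} disjoint
#' subsets whose sizes differ by at most one; each subset serves once as the
#' held-out test set of a cross-validation round.  Fully determined by
#' \code{seed}.
#'
#' @param net a \code{BipartiteNetwork}.
#' @param k fold count (default 10).
#' @param seed RNG seed.
#' @return a \linkS4class{FoldPlan}.
#' @export
makeFolds <- function(net, k = 10L, seed = 1L) {
  k <- as.integer(k)
  m <- numEdges(net)
  if (k < 2L) stop("k must be >= 2")
  if (m < k) stop("infeasible split: ", m, " edges cannot fill ", k, " folds")
  e <- edgeTable(net)
  sizes <- rep(m %/% k, k) + (seq_len(k) <= m %% k)
  f <- integer(m)
  .withSeed(.deriveSeed(seed, 1L), {
    f[sample.int(m)] <- rep(seq_len(k), times = sizes)
  })
  e$fold <- f
  methods::new("FoldPlan", k = k, seed = as.numeric(seed), edges = e)
}

#' @rdname makeFolds
#' @param plan a \code{FoldPlan}.
#' @param i fold index in 1..k.
#' @return \code{foldTestEdges} returns the data.frame of edges (columns
#'   \code{a}, \code{b}) held out in fold \code{i}.
#' @export
foldTestEdges <- function(plan, i) {
  stopifnot(methods::is(plan, "FoldPlan"), i >= 1L, i <= plan@k)
  e <- plan@edges[plan@edges$fold == i, c("a", "b"), drop = FALSE]
  rownames(e) <- NULL
  e
}

setMethod("show", "FoldPlan", function(object) {
  cat("FoldPlan:", nrow(object@edges), "edges in", object@k,
      "folds (seed", object@seed, ")\n")
})

#' Training network after removing held-out edges
#'
#' Returns the network with \code{heldOut} edges removed and every node
#' retained (a node left with no edges stays in its part as an isolated
#' node).  A held-out pair that is not an edge of \code{net} is an error.
#'
#' @param net a \code{BipartiteNetwork}.
#' @param heldOut data.frame of edges (columns \code{a}, \code{b}).
#' @return a \code{BipartiteNetwork} with the same node sets.
#' @export
trainingNetwork <- function(net, heldOut) {
  e <- edgeTable(net)
  if (is.null(heldOut) || nrow(heldOut) == 0L)
    return(BipartiteNetwork(e, partA = partA(net), partB = partB(net)))
  hc <- .pairCode(net, .trimIds(heldOut[[1L]]), .trimIds(heldOut[[2L]]))
  ec <- .pairCode(net, e$a, e$b)
  if (!all(hc %in% ec)) stop("held-out pair is not an edge of the network")
  keep <- !(ec %in% hc)
  BipartiteNetwork(if (any(keep)) e[keep, , drop = FALSE] else NULL,
                   partA = partA(net), partB = partB(net))
}

## uniform draw of `n` true non-edge pair codes (with replacement);
## `forbidden` = codes of the original network's edges (train + test)
.sampleNonEdges <- function(nA, nB, forbidden, n) {
  total <- as.numeric(nA) * as.numeric(nB)
  free <- total - length(unique(forbidden))
  if (free <= 0) stop("sampling impossible: no true non-edges available")
  if (total <= 2^20) {
    universe <- setdiff(seq_len(total), forbidden)   # 1-based pair codes
    universe[sample.int(length(universe), n, replace = TRUE)]
  } else {
    out <- numeric(0)
    while (length(out) < n) {
      batch <- ceiling((n - length(out)) / max(free / total, 1e-6)) + 16L
      ia <- sample.int(nA, batch, replace = TRUE)
      ib <- sample.int(nB, batch, replace = TRUE)
      code <- (ia - 1) * nB + ib
      out <- c(out, code[!(code %in% forbidden)])
    }
    out[seq_len(n)]
  }
}

.scorePairsAnyMethod <- function(train, ia, ib, method, logBase) {
  if (is.function(method)) {
    method(train, partA(train)[ia], partB(train)[ib])
  } else {
    .checkMethod(method)
    ctx <- .scoringContext(train, logBase)
    .scoreIndexPairs(ctx, ia, ib, method)
  }
}

## relative tie tolerance for floating-point score comparison
.scoreTies <- function(s1, s2) {
  tol <- 1e-9 * pmax(1, abs(s1), abs(s2))
  list(win = s1 > s2 + tol, tie = abs(s1 - s2) <= tol)
}

#' Sampled-pair AUC of a scoring method
#'
#' Draws \code{n} independent comparison pairs -- one uniform held-out test
#' edge against one uniform true non-edge (a cross-part pair absent from both
#' the training network and the test set) -- scores both on the training
#' network, and tallies strict wins \code{n'} and ties \code{n''} for the test
#' edge: \code{AUC = (n' + 0.5 n'')/n}.  Both draws are with replacement and
#' the result is fully determined by \code{seed}.
#'
#' @param train the training \code{BipartiteNetwork} (test edges removed).
#' @param testEdges data.frame of held-out edges (columns \code{a}, \code{b});
#'   must be non-edges of \code{train}.
#' @param method one of [scoreMethods()], or a function
#'   \code{f(net, x, y)} returning numeric scores (useful for testing the
#'   AUC algebra with synthetic scorers).
#' @param n number of comparison pairs.
#' @param seed RNG seed.
#' @param logBase Adamic/Adar log base.
#' @return an \linkS4class{AUCResult}.
#' @export
aucSampled <- function(train, testEdges, method = "CN", n = 10L * nrow(testEdges),
                       seed = 1L, logBase = exp(1)) {
  if (is.null(testEdges) || nrow(testEdges) == 0L) stop("empty test set")
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  tc <- .pairCode(train, .trimIds(testEdges[[1L]]), .trimIds(testEdges[[2L]]))
  trc <- .edgeCodes(train)
  if (any(tc %in% trc)) stop("test edge present in training network")
  nA <- length(partA(train)); nB <- length(partB(train))
  forbidden <- c(trc, tc)
  drawn <- .withSeed(seed, {
    ti <- sample.int(length(tc), n, replace = TRUE)
    nc <- .sampleNonEdges(nA, nB, forbidden, n)
    list(ti = ti, nc = nc)
  })
  iaT <- (tc[drawn$ti] - 1) %/% nB + 1; ibT <- (tc[drawn$ti] - 1) %% nB + 1
  iaN <- (drawn$nc - 1) %/% nB + 1; ibN <- (drawn$nc - 1) %% nB + 1
  st <- .scorePairsAnyMethod(train, iaT, ibT, method, logBase)
  sn <- .scorePairsAnyMethod(train, iaN, ibN, method, logBase)
  cmp <- .scoreTies(st, sn)
  nWin <- sum(cmp$win); nTie <- sum(cmp$tie)
  methods::new("AUCResult", n = as.numeric(n), nWin = as.numeric(nWin),
               nTie = as.numeric(nTie), auc = (nWin + 0.5 * nTie) / n)
}

setMethod("show", "AUCResult", function(object) {
  cat(sprintf("AUCResult: auc = %.4f  (n = %d, wins = %d, ties = %d)\n",
              object@auc, as.integer(object@n), as.integer(object@nWin),
              as.integer(object@nTie)))
})

#' Precision among the top-L ranked candidates
#'
#' Ranks every candidate non-edge of the training network (held-out test
#' edges are zero entries of the training adjacency, hence candidates), takes
#' the top \code{l}, and reports the fraction that are held-out test edges.
#' Deterministic given the lexicographic tie rule.
#'
#' @inheritParams aucSampled
#' @param l how many top predictions to inspect (default: the test-set size,
#'   the usual precision-at-L convention for edge holdout).
#' @return a \linkS4class{PrecisionResult}.
#' @export
precisionAt <- function(train, testEdges, method = "CN", l = nrow(testEdges),
                        logBase = exp(1)) {
  if (is.null(testEdges) || nrow(testEdges) == 0L) stop("empty test set")
  l <- as.integer(l)
  if (l < 1L) stop("undefined precision: l must be >= 1")
  tc <- .pairCode(train, .trimIds(testEdges[[1L]]), .trimIds(testEdges[[2L]]))
  if (any(tc %in% .edgeCodes(train)))
    stop("test edge present in training network")
  nA <- length(partA(train)); nB <- length(partB(train))
  nCand <- as.numeric(nA) * as.numeric(nB) - numEdges(train)
  if (l > nCand) stop("l exceeds the number of candidate non-edges (", nCand, ")")
  if (is.function(method)) {
    universe <- setdiff(seq_len(nA * nB), .edgeCodes(train))
    ia <- (universe - 1) %/% nB + 1; ib <- (universe - 1) %% nB + 1
    a <- partA(train)[ia]; b <- partB(train)[ib]
    sc <- method(train, a, b)
    keep <- utils::head(order(-sc, a, b, method = "radix"), l)
    top <- universe[keep]
  } else {
    ranked <- rankCandidates(train, method, topK = l, logBase = logBase)
    top <- .pairCode(train, ranked$x, ranked$y)
  }
  hits <- sum(top %in% tc)
  methods::new("PrecisionResult", l = as.numeric(l), hits = as.numeric(hits),
               precision = hits / l)
}

setMethod("show", "PrecisionResult", function(object) {
  cat(sprintf("PrecisionResult: precision = %.4f  (hits = %d of l = %d)\n",
              object@precision, as.integer(object@hits), as.integer(object@l)))
})

#' Cross-validated comparison of scoring methods
#'
#' Runs the full edge-holdout protocol: the edge set is split into \code{k}
#' disjoint test folds; for every fold and method the held-out edges are
#' removed, the sampled-pair AUC and the precision-at-L are computed on the
#' training network, and per-method means and standard deviations across
#' folds (plus pooled tallies over all folds) are reported.  The best method
#' is the one with the highest mean AUC (ties: higher mean precision, then
#' method-name order).  Fully determined by \code{seed}.
#'
#' @param net a \code{BipartiteNetwork}.
#' @param methods character vector of methods to compare.
#' @param k fold count.
#' @param n AUC comparison pairs per fold (default 10 x the fold's test size).
#' @param l precision cut per fold (default the fold's test size).
#' @param seed RNG seed.
#' @param logBase Adamic/Adar log base.
#' @return an \linkS4class{EvaluationReport}.
#' @export
evaluateLinkPrediction <- function(net, methods = scoreMethods(), k = 10L,
                                   n = NULL, l = NULL, seed = 1L,
                                   logBase = exp(1)) {
  for (m in methods) .checkMethod(m)
  plan <- makeFolds(net, k, seed)
  rows <- list()
  for (i in seq_len(plan@k)) {
    test <- foldTestEdges(plan, i)
    train <- trainingNetwork(net, test)
    ni <- if (is.null(n)) 10L * nrow(test) else as.integer(n)
    li <- if (is.null(l)) nrow(test) else as.integer(l)
    for (j in seq_along(methods)) {
      aucSeed <- .deriveSeed(seed, 1000L + i * 101L + j)
      a <- aucSampled(train, test, methods[j], n = ni, seed = aucSeed,
                      logBase = logBase)
      p <- precisionAt(train, test, methods[j], l = li, logBase = logBase)
      rows[[length(rows) + 1L]] <- data.frame(
        method = methods[j], fold = i, testSize = nrow(test),
        n = a@n, nWin = a@nWin, nTie = a@nTie, auc = a@auc,
        l = p@l, hits = p@hits, precision = p@precision,
        stringsAsFactors = FALSE)
    }
  }
  perFold <- do.call(rbind, rows)
  sm <- lapply(methods, function(m) {
    d <- perFold[perFold$method == m, , drop = FALSE]
    data.frame(method = m,
               meanAUC = mean(d$auc), sdAUC = stats::sd(d$auc),
               meanPrecision = mean(d$precision),
               sdPrecision = stats::sd(d$precision),
               pooledAUC = sum(d$nWin + 0.5 * d$nTie) / sum(d$n),
               pooledPrecision = sum(d$hits) / sum(d$l),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, sm)
  ord <- order(-summary$meanAUC, -summary$meanPrecision, summary$method,
               method = "radix")
  best <- summary$method[ord[1L]]
  methods::new("EvaluationReport", perFold = perFold, summary = summary,
               best = best,
               provenance = list(seed = as.numeric(seed), k = as.numeric(k),
                                 n = if (is.null(n)) "10x test size" else as.numeric(n),
                                 l = if (is.null(l)) "test size" else as.numeric(l),
                                 methods = methods, logBase = logBase,
                                 nA = length(partA(net)), nB = length(partB(net)),
                                 m = numEdges(net)))
}

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (", object@provenance$k, "-fold, seed ",
      object@provenance$seed, ")\n", sep = "")
  print(object@summary, row.names = FALSE, digits = 4)
  cat("best method by mean AUC:", object@best, "\n")
})

#' Serialize an evaluation report
#'
#' \code{reportToJSON} renders the full report (provenance, per-fold detail,
#' per-method summary, best method) as a JSON string; identical runs give
#' byte-identical JSON.  \code{writeEvaluationReport} writes the JSON plus a
#' summary TSV and a plot-ready long-format TSV.
#'
#' @param report an \code{EvaluationReport}.
#' @return \code{reportToJSON}: a JSON character scalar.
#' @export
reportToJSON <- function(report) {
  as.character(jsonlite::toJSON(
    list(provenance = report@provenance, perFold = report@perFold,
         summary = report@summary, best = report@best),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"))
}

#' @rdname reportToJSON
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return \code{writeEvaluationReport}: named vector of the files written,
#'   invisibly.
#' @export
writeEvaluationReport <- function(report, dir, prefix = "evaluation") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonPath <- file.path(dir, paste0(prefix, ".json"))
  writeLines(reportToJSON(report), jsonPath, useBytes = TRUE)
  tsvPath <- file.path(dir, paste0(prefix, "_summary.tsv"))
  utils::write.table(report@summary, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  longPath <- file.path(dir, paste0(prefix, "_long.tsv"))
  pf <- report@perFold
  long <- rbind(
    data.frame(method = pf$method, fold = pf$fold, metric = "auc",
               value = pf$auc, stringsAsFactors = FALSE),
    data.frame(method = pf$method, fold = pf$fold, metric = "precision",
               value = pf$precision, stringsAsFactors = FALSE))
  utils::write.table(long, longPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json = jsonPath, summary = tsvPath, long = longPath))
}
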