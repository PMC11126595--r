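## Balanced two-sided neighbourhood scores for bipartite link prediction.
##
## For a cross-part pair (x, y) with x in part A and y in part B, each
## one-sided overlap compares the neighbour set of one endpoint with the
## neighbours-of-neighbours set of the other:
##   CN = (|G(x) n G(G(y))| + |G(y) n G(G(x))|) / 2
##   JC = CN / |G(x) u G(y)|            (parts disjoint => |G(x)| + |G(y)|)
##   AA = (sum_{z in G(y) n G(G(x))} 1/log|G(z)|
##         + sum_{z in G(x) n G(G(y))} 1/log|G(z)|) / 2
##   PA = |G(x)| * |G(y)|
## Contributors z with degree <= 1 are skipped in AA (log 1 = 0).

#' The available scoring methods
#'
#' @return the closed set of method names: CN (common neighbours), JC
#'   (Jaccard), AA (Adamic/Adar), PA (preferential attachment).
#' @export
scoreMethods <- function() c("CN", "JC", "AA", "PA")

.checkMethod <- function(method) {
  if (!(is.character(method) && length(method) == 1L &&
        method %in% scoreMethods()))
    stop("unknown method; must be one of ", paste(scoreMethods(), collapse = ", "))
  method
}

## adjacency lists + degree/weight vectors shared by the scorers
.scoringContext <- function(net, logBase = exp(1)) {
  A <- net@adjacency
  nA <- nrow(A); nB <- ncol(A)
  j <- rep(seq_len(nB), diff(A@p))
  i <- A@i + 1L
  adjA <- split(j, factor(i, levels = seq_len(nA)))   # per row: B columns
  adjB <- split(i, factor(j, levels = seq_len(nB)))   # per col: A rows
  degA <- lengths(adjA); degB <- lengths(adjB)
  lb <- log(logBase)
  wA <- ifelse(degA > 1, lb / log(degA), 0)
  wB <- ifelse(degB > 1, lb / log(degB), 0)
  list(A = A, nA = nA, nB = nB, adjA = adjA, adjB = adjB,
       degA = degA, degB = degB, wA = wA, wB = wB)
}

## element-wise orientation resolution: each pair must join part A to part B,
## in either argument order
.resolvePairs <- function(net, x, y) {
  A <- net@adjacency
  n <- max(length(x), length(y))
  x <- rep_len(as.character(x), n); y <- rep_len(as.character(y), n)
  ra <- rownames(A); cb <- colnames(A)
  xa <- match(x, ra); xb <- match(x, cb)
  ya <- match(y, ra); yb <- match(y, cb)
  unknown <- (is.na(xa) & is.na(xb)) | (is.na(ya) & is.na(yb))
  if (any(unknown)) {
    k <- which(unknown)[1L]
    bad <- if (is.na(xa[k]) && is.na(xb[k])) x[k] else y[k]
    stop("unknown node: ", bad)
  }
  direct <- !is.na(xa) & !is.na(yb)
  swapped <- !is.na(xb) & !is.na(ya)
  if (any(!direct & !swapped))
    stop("same-part pair: both endpoints belong to the same part (",
         x[which(!direct & !swapped)[1L]], ", ",
         y[which(!direct & !swapped)[1L]], ")")
  list(ia = ifelse(direct, xa, ya), ib = ifelse(direct, yb, xb))
}

## score index pairs (ia, ib) under one method; workhorse shared by the
## user-facing scorers and the evaluation module
.scoreIndexPairs <- function(ctx, ia, ib, method) {
  if (method == "PA") return(as.numeric(ctx$degA[ia] * ctx$degB[ib]))
  ## second-neighbour caches for the unique endpoints involved
  ua <- unique(ia); ub <- unique(ib)
  nnA <- vector("list", ctx$nA)   # for a in A: reachable A rows (two hops)
  for (a in ua)   # as.integer: an empty union must stay integer(0), not NULL
    nnA[[a]] <- unique(as.integer(unlist(ctx$adjB[ctx$adjA[[a]]], use.names = FALSE)))
  nnB <- vector("list", ctx$nB)   # for b in B: reachable B cols (two hops)
  for (b in ub)
    nnB[[b]] <- unique(as.integer(unlist(ctx$adjA[ctx$adjB[[b]]], use.names = FALSE)))
  scoreOne <- function(a, b) {
    ga <- ctx$adjA[[a]]; gb <- ctx$adjB[[b]]
    inB <- ga[ga %in% nnB[[b]]]   # G(x) n G(G(y)), subset of B
    inA <- gb[gb %in% nnA[[a]]]   # G(y) n G(G(x)), subset of A
    switch(method,
      CN = (length(inB) + length(inA)) / 2,
      JC = {
        cn <- (length(inB) + length(inA)) / 2
        den <- ctx$degA[[a]] + ctx$degB[[b]]
        if (den == 0) 0 else cn / den
      },
      AA = (sum(ctx$wA[inA]) + sum(ctx$wB[inB])) / 2)
  }
  ## compute each distinct pair once
  code <- (ia - 1) * ctx$nB + ib
  uc <- !duplicated(code)
  vals <- mapply(scoreOne, ia[uc], ib[uc])
  as.numeric(vals)[match(code, code[uc])]
}

#' Score cross-part node pairs
#'
#' Computes the balanced two-sided similarity score of one or more cross-part
#' pairs under the chosen method.  Arguments are vectorized and
#' order-agnostic: each pair may be given as (part-A node, part-B node) or the
#' reverse; a same-part pair or an unknown node is an error.  Existing edges
#' may be scored (the evaluation protocol scores held-out true edges against
#' the training network).
#'
#' @param net a \code{BipartiteNetwork}.
#' @param x,y node identifiers (equal length, or either of length 1).
#' @param method one of [scoreMethods()].
#' @param logBase logarithm base for the Adamic/Adar weights (default natural
#'   log, the usual Adamic/Adar convention); contributors of degree <= 1 are
#'   skipped.
#' @return a numeric vector of non-negative scores.
#' @examples
#' toy <- BipartiteNetwork(data.frame(
#'   a = c("p1", "p1", "p2", "p2", "p3"),
#'   b = c("d1", "d2", "d1", "d3", "d2")))
#' linkScore(toy, "p3", "d1", "CN")   # 1
#' linkScore(toy, "p3", "d1", "AA")   # 1/log(2)
#' @export
linkScore <- function(net, x, y, method = "CN", logBase = exp(1)) {
  .checkMethod(method)
  p <- .resolvePairs(net, x, y)
  ctx <- .scoringContext(net, logBase)
  .scoreIndexPairs(ctx, p$ia, p$ib, method)
}

#' Literal reference scorer
#'
#' A deliberately naive evaluation of the scoring formulas, set by set on
#' character identifiers with no indexing or caching: the neighbour and
#' neighbour-of-neighbour sets are materialized with [neighborSet()] /
#' [secondNeighborSet()] and combined with \code{intersect}/\code{union}.
#' Exists as an independent reference for testing the fast scorers; returns
#' the same value as [linkScore()] on every input.
#'
#' @inheritParams linkScore
#' @param x,y single node identifiers (one cross-part pair).
#' @return a single non-negative score.
#' @export
bruteForceScore <- function(net, x, y, method = "CN", logBase = exp(1)) {
  .checkMethod(method)
  p <- .resolvePairs(net, x, y)
  a <- partA(net)[p$ia[1L]]; b <- partB(net)[p$ib[1L]]
  ga <- neighborSet(net, a); gb <- neighborSet(net, b)
  gga <- secondNeighborSet(net, a); ggb <- secondNeighborSet(net, b)
  deg <- function(z) length(neighborSet(net, z))
  aaTerm <- function(z) {
    d <- deg(z)
    if (d <= 1) 0 else 1 / log(d, base = logBase)
  }
  switch(method,
    CN = (length(intersect(ga, ggb)) + length(intersect(gb, gga))) / 2,
    JC = {
      cn <- (length(intersect(ga, ggb)) + length(intersect(gb, gga))) / 2
      den <- length(union(ga, gb))
      if (den == 0) 0 else cn / den
    },
    AA = (sum(vapply(intersect(gb, gga), aaTerm, 0)) +
          sum(vapply(intersect(ga, ggb), aaTerm, 0))) / 2,
    PA = length(ga) * length(gb))
}

## dense score block for part-B columns `cols` via sparse products:
##   S1[x, y] = |G(x) n G(G(y))| = (A  Ppat)[x, y]
##   S2[x, y] = |G(y) n G(G(x))| = (Qpat A)[x, y]
## with Ppat/Qpat the 0/1 patterns of t(A)A and A t(A); Adamic/Adar inserts
## the 1/log-degree diagonal before the pattern product.
.blockScores <- function(net, method, cols, ctx, pp) {
  A <- net@adjacency
  switch(method,
    CN = as.matrix(A %*% pp$P[, cols, drop = FALSE] +
                   pp$Q %*% A[, cols, drop = FALSE]) / 2,
    JC = {
      cn <- as.matrix(A %*% pp$P[, cols, drop = FALSE] +
                      pp$Q %*% A[, cols, drop = FALSE]) / 2
      den <- outer(ctx$degA, ctx$degB[cols], `+`)
      out <- cn / den
      out[den == 0] <- 0
      out
    },
    AA = as.matrix(A %*% (pp$WB %*% pp$P[, cols, drop = FALSE]) +
                   pp$Q %*% (pp$WA %*% A[, cols, drop = FALSE])) / 2,
    PA = outer(as.numeric(ctx$degA), as.numeric(ctx$degB[cols])))
}

.patternProducts <- function(net, ctx, method) {
  A <- net@adjacency
  pp <- list()
  if (method != "PA") {
    P <- methods::as(Matrix::crossprod(A), "generalMatrix")   # B x B
    P@x[] <- 1
    Q <- methods::as(Matrix::tcrossprod(A), "generalMatrix")  # A x A
    Q@x[] <- 1
    pp$P <- P; pp$Q <- Q
    if (method == "AA") {
      pp$WA <- Matrix::Diagonal(x = ctx$wA)
      pp$WB <- Matrix::Diagonal(x = ctx$wB)
    }
  }
  pp
}

#' Rank candidate non-edges
#'
#' Scores candidate cross-part non-edges under one method and returns them
#' ranked by descending score, ties broken lexicographically by (x, y) so the
#' list is deterministic.  By default every zero entry of the cross-part
#' adjacency is a candidate; candidates are processed in column blocks with a
#' bounded running top-\code{topK} pool, so the full scored list is never held
#' in memory at once.  Passing an existing edge in \code{candidates} is an
#' error.
#'
#' @inheritParams linkScore
#' @param topK how many predictions to keep (\code{Inf} for all).
#' @param candidates optional data.frame of pairs (columns \code{a},
#'   \code{b}) to score instead of all non-edges.
#' @param chunkSize number of part-B columns scored per block in the default
#'   full enumeration.
#' @return a data.frame with columns \code{x} (part A), \code{y} (part B),
#'   \code{method}, \code{score}, \code{rank}.
#' @export
rankCandidates <- function(net, method = "CN", topK = Inf, candidates = NULL,
                           logBase = exp(1), chunkSize = 512L) {
  .checkMethod(method)
  ctx <- .scoringContext(net, logBase)
  ra <- partA(net); cb <- partB(net)
  if (!is.null(candidates)) {
    p <- .resolvePairs(net, candidates[[1L]], candidates[[2L]])
    code <- (p$ia - 1) * ctx$nB + p$ib
    if (anyDuplicated(code)) stop("duplicate candidate pair")
    if (any(code %in% .edgeCodes(net)))
      stop("candidate is an existing edge of the network")
    sc <- .scoreIndexPairs(ctx, p$ia, p$ib, method)
    ord <- order(-sc, ra[p$ia], cb[p$ib], method = "radix")
    keep <- utils::head(ord, if (is.finite(topK)) topK else length(ord))
    out <- data.frame(x = ra[p$ia[keep]], y = cb[p$ib[keep]],
                      method = method, score = sc[keep],
                      stringsAsFactors = FALSE)
  } else {
    pp <- .patternProducts(net, ctx, method)
    A <- net@adjacency
    kEff <- if (is.finite(topK)) as.integer(topK) else NA_integer_
    pool <- data.frame(x = character(0), y = character(0),
                       score = numeric(0), stringsAsFactors = FALSE)
    for (start in seq(1L, ctx$nB, by = chunkSize)) {
      cols <- start:min(start + chunkSize - 1L, ctx$nB)
      S <- .blockScores(net, method, cols, ctx, pp)
      S[as.matrix(A[, cols, drop = FALSE] != 0)] <- NA   # drop existing edges
      keep <- which(!is.na(S))
      if (!length(keep)) next
      chunk <- data.frame(x = ra[(keep - 1L) %% ctx$nA + 1L],
                          y = cb[cols[(keep - 1L) %/% ctx$nA + 1L]],
                          score = as.numeric(S[keep]),
                          stringsAsFactors = FALSE)
      pool <- rbind(pool, chunk)
      ord <- order(-pool$score, pool$x, pool$y, method = "radix")
      if (!is.na(kEff)) ord <- utils::head(ord, kEff)
      pool <- pool[ord, , drop = FALSE]
    }
    out <- data.frame(x = pool$x, y = pool$y, method = method,
                      score = pool$score, stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  if (nrow(out)) out$rank <- seq_len(nrow(out)) else out$rank <- integer(0)
  out
}

#' Write ranked predictions
#'
#' Serializes a ranked-prediction table to TSV (columns x, y, method, score,
#' rank) with \code{#}-prefixed provenance header lines, or to JSON;
#' round-trip safe via [readRankedPredictions()].
#'
#' @param predictions a data.frame from [rankCandidates()].
#' @param path output path.
#' @param format "tsv" or "json".
#' @param provenance optional named list recorded in the header (TSV) or
#'   alongside the table (JSON).
#' @return \code{path}, invisibly.
#' @export
writeRankedPredictions <- function(predictions, path, format = c("tsv", "json"),
                                   provenance = list()) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(provenance = provenance, predictions = predictions),
                         path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    hdr <- if (length(provenance))
      paste0("# ", names(provenance), " = ",
             vapply(provenance, function(v) paste(format(v, digits = 17), collapse = ","), ""))
    else character(0)
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(paste("x", "y", "method", "score", "rank", sep = "\t"), con)
    if (nrow(predictions))
      writeLines(paste(predictions$x, predictions$y, predictions$method,
                       format(predictions$score, digits = 17, trim = TRUE),
                       predictions$rank, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeRankedPredictions
#' @export
readRankedPredictions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  df$score <- as.numeric(df$score)
  df
}
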