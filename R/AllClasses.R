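#' @import methods
#' @importFrom Matrix sparseMatrix crossprod tcrossprod rowSums colSums Diagonal
#' @importClassesFrom Matrix dgCMatrix
NULL

#' BipartiteNetwork: a two-mode association network
#'
#' An S4 container for a bipartite (two-mode) network: two disjoint node sets
#' (part A, e.g. probiotics, and part B, e.g. diseases) and a set of
#' cross-part edges.  Internally the network is a sparse binary adjacency
#' matrix with part-A nodes on the rows and part-B nodes on the columns, so
#' isolated (degree-0) nodes are representable and within-part edges are
#' impossible by construction.  Node identifiers are opaque, whitespace-trimmed,
#' non-empty strings, unique within their part and disjoint across parts;
#' both parts are kept in sorted (C-locale) order so that the object is a
#' canonical function of its node and edge sets, independent of input row
#' order.
#'
#' @slot adjacency a \code{\link[Matrix]{dgCMatrix}} with entries in \{0, 1\};
#'   \code{rownames} are the part-A identifiers and \code{colnames} the
#'   part-B identifiers.
#'
#' @seealso [BipartiteNetwork()] for construction, [readEdgeTable()] for I/O,
#'   [neighborSet()], [networkSummary()].
#' @export
setClass("BipartiteNetwork", representation(adjacency = "dgCMatrix"))

setValidity("BipartiteNetwork", function(object) {
  A <- object@adjacency
  ra <- rownames(A); cb <- colnames(A)
  msgs <- character(0)
  # a 0-extent dimension legitimately has no names (an empty part)
  if ((is.null(ra) && nrow(A) > 0L) || (is.null(cb) && ncol(A) > 0L))
    return("adjacency must carry row and column names (node identifiers)")
  if (anyNA(ra) || anyNA(cb) || any(!nzchar(trimws(c(ra, cb)))))
    msgs <- c(msgs, "node identifiers must be non-empty strings")
  if (anyDuplicated(ra)) msgs <- c(msgs, "duplicate identifiers in part A")
  if (anyDuplicated(cb)) msgs <- c(msgs, "duplicate identifiers in part B")
  if (length(intersect(ra, cb)) > 0L)
    msgs <- c(msgs, "part A and part B must be disjoint node sets")
  if (length(A@x) && any(A@x != 1))
    msgs <- c(msgs, "adjacency entries must be 0/1 (no duplicate edges)")
  if (length(msgs)) msgs else TRUE
})

#' NetworkStats: descriptive statistics of a bipartite network
#'
#' Holds the counts and derived quantities reported for a two-mode network:
#' part sizes, edge count, average degree per part, number of possible
#' cross-part pairs, density (edges / possible pairs), and the full per-node
#' degree tables.  All values are stored at full precision; display rounding
#' (density to 5 decimals, average degrees to the nearest integer) happens
#' only in \code{show} and in the serialized report.
#'
#' @slot nA,nB part sizes.
#' @slot m edge count.
#' @slot avgDegreeA,avgDegreeB m/nA and m/nB, full precision.
#' @slot possiblePairs nA * nB.
#' @slot density m / possiblePairs.
#' @slot degreeA,degreeB named numeric vectors of per-node degrees (may be
#'   empty when the object was derived from counts alone).
#' @export
setClass("NetworkStats", representation(
  nA = "numeric", nB = "numeric", m = "numeric",
  avgDegreeA = "numeric", avgDegreeB = "numeric",
  possiblePairs = "numeric", density = "numeric",
  degreeA = "numeric", degreeB = "numeric"))

setValidity("NetworkStats", function(object) {
  msgs <- character(0)
  if (object@density < 0 || object@density > 1)
    msgs <- c(msgs, "density must lie in [0, 1]")
  if (object@possiblePairs != object@nA * object@nB)
    msgs <- c(msgs, "possiblePairs must equal nA * nB")
  if (length(object@degreeA) && !isTRUE(all.equal(sum(object@degreeA), object@m)))
    msgs <- c(msgs, "part-A degrees must sum to m")
  if (length(object@degreeB) && !isTRUE(all.equal(sum(object@degreeB), object@m)))
    msgs <- c(msgs, "part-B degrees must sum to m")
  if (length(msgs)) msgs else TRUE
})

#' FoldPlan: a k-fold partition of a network's edge set
#'
#' The cross-validation plan: every edge of the network is assigned to exactly
#' one of \code{k} pairwise-disjoint test folds whose sizes differ by at most
#' one.  The plan is a deterministic function of \code{(network, k, seed)}.
#'
#' @slot k fold count.
#' @slot seed the RNG seed the plan was drawn with.
#' @slot edges a data.frame with columns \code{a}, \code{b}, \code{fold}.
#' @export
setClass("FoldPlan", representation(k = "integer", seed = "numeric",
                                    edges = "data.frame"))

setValidity("FoldPlan", function(object) {
  msgs <- character(0)
  e <- object@edges
  if (!all(c("a", "b", "fold") %in% names(e)))
    return("edges must have columns a, b, fold")
  if (anyDuplicated(paste(e$a, e$b, sep = "\r")))
    msgs <- c(msgs, "an edge may belong to only one fold")
  if (nrow(e)) {
    if (!all(e$fold %in% seq_len(object@k)))
      msgs <- c(msgs, "fold labels must lie in 1..k")
    sz <- tabulate(e$fold, nbins = object@k)
    if (diff(range(sz)) > 1L)
      msgs <- c(msgs, "fold sizes must differ by at most 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' AUCResult: sampled-pair AUC tallies
#'
#' The result of the sampled-pair AUC: out of \code{n} random comparisons
#' between a held-out true edge and a true non-edge, the edge strictly
#' outscored the non-edge \code{nWin} times and tied \code{nTie} times;
#' \code{auc = (nWin + 0.5 * nTie) / n}.
#'
#' @slot n number of sampled comparison pairs.
#' @slot nWin strict wins for the held-out edge.
#' @slot nTie score ties.
#' @slot auc (nWin + 0.5 nTie)/n.
#' @export
setClass("AUCResult", representation(n = "numeric", nWin = "numeric",
                                     nTie = "numeric", auc = "numeric"))

setValidity("AUCResult", function(object) {
  msgs <- character(0)
  if (object@nWin + object@nTie > object@n)
    msgs <- c(msgs, "nWin + nTie cannot exceed n")
  if (object@auc < 0 || object@auc > 1) msgs <- c(msgs, "auc must lie in [0, 1]")
  if (!isTRUE(all.equal(object@auc, (object@nWin + 0.5 * object@nTie) / object@n)))
    msgs <- c(msgs, "auc must equal (nWin + 0.5 nTie)/n")
  if (length(msgs)) msgs else TRUE
})

#' PrecisionResult: precision among the top-L ranked predictions
#'
#' @slot l number of top-ranked candidate predictions inspected.
#' @slot hits how many of them are held-out test edges.
#' @slot precision hits / l.
#' @export
setClass("PrecisionResult", representation(l = "numeric", hits = "numeric",
                                           precision = "numeric"))

setValidity("PrecisionResult", function(object) {
  msgs <- character(0)
  if (object@hits > object@l) msgs <- c(msgs, "hits cannot exceed l")
  if (object@precision < 0 || object@precision > 1)
    msgs <- c(msgs, "precision must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' EvaluationReport: cross-validated comparison of scoring methods
#'
#' Per-(method, fold) AUC and precision results, per-method summaries (mean and
#' standard deviation across folds, plus pooled tallies over all folds), the
#' best method under the mean-AUC criterion, and full provenance (seed, k, n,
#' methods) so any report is regenerable.
#'
#' @slot perFold data.frame, one row per (method, fold).
#' @slot summary data.frame, one row per method.
#' @slot best name of the winning method (highest mean AUC; ties broken by
#'   higher mean precision, then method-name order).
#' @slot provenance list of the resolved evaluation parameters.
#' @export
setClass("EvaluationReport", representation(perFold = "data.frame",
                                            summary = "data.frame",
                                            best = "character",
                                            provenance = "list"))
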