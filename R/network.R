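## Construction and basic algebra of the bipartite network object.

.trimIds <- function(x) trimws(as.character(x))

.sortIds <- function(x) sort(unique(x), method = "radix")

#' Construct a bipartite network
#'
#' Builds a \linkS4class{BipartiteNetwork} from an edge table and, optionally,
#' extra node identifiers so that isolated nodes can be represented.
#' Identifiers are whitespace-trimmed; duplicate edges are collapsed (with a
#' message reporting how many rows were dropped); an identifier appearing in
#' both parts is an error.  The result is canonical: node order within each
#' part is sorted, so the same node and edge sets always yield an identical
#' object regardless of input row order.
#'
#' @param edges a two-column data.frame or matrix (column 1 = part-A id,
#'   column 2 = part-B id), or \code{NULL} for an edgeless network.
#' @param partA,partB character vectors of additional node identifiers to
#'   include in each part (isolated unless they also appear in \code{edges}).
#' @return a \code{BipartiteNetwork}.
#' @examples
#' toy <- BipartiteNetwork(data.frame(
#'   a = c("p1", "p1", "p2", "p2", "p3"),
#'   b = c("d1", "d2", "d1", "d3", "d2")))
#' toy
#' @export
BipartiteNetwork <- function(edges = NULL, partA = character(0), partB = character(0)) {
  partA <- .trimIds(partA); partB <- .trimIds(partB)
  if (!is.null(edges)) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) < 2L) stop("edge table must have two columns")
    ea <- .trimIds(edges[[1L]]); eb <- .trimIds(edges[[2L]])
    if (any(!nzchar(ea)) || any(!nzchar(eb)))
      stop("empty node identifier in edge table")
    partA <- c(partA, ea); partB <- c(partB, eb)
  } else {
    ea <- eb <- character(0)
  }
  if (any(!nzchar(partA)) || any(!nzchar(partB)))
    stop("empty node identifier")
  both <- intersect(partA, partB)
  if (length(both))
    stop("part-conflict: identifier(s) appear in both parts: ",
         paste(utils::head(both, 5L), collapse = ", "))
  ra <- .sortIds(partA); cb <- .sortIds(partB)
  key <- paste(ea, eb, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate edge row(s) collapsed")
    ea <- ea[!dup]; eb <- eb[!dup]
  }
  A <- Matrix::sparseMatrix(i = match(ea, ra), j = match(eb, cb),
                            x = rep(1, length(ea)),
                            dims = c(length(ra), length(cb)),
                            dimnames = list(ra, cb))
  ## sparseMatrix() with numeric x yields a dgCMatrix directly
  methods::new("BipartiteNetwork", adjacency = A)
}

#' @rdname BipartiteNetwork-class
#' @aliases partA partB numEdges edgeTable
#' @export
setMethod("partA", "BipartiteNetwork", function(x) rownames(x@adjacency))

#' @rdname BipartiteNetwork-class
#' @export
setMethod("partB", "BipartiteNetwork", function(x) colnames(x@adjacency))

#' @rdname BipartiteNetwork-class
#' @export
setMethod("numEdges", "BipartiteNetwork", function(x) length(x@adjacency@x))

#' @rdname BipartiteNetwork-class
#' @export
setMethod("edgeTable", "BipartiteNetwork", function(x) {
  A <- x@adjacency
  if (!length(A@x))
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  j <- rep(seq_len(ncol(A)), diff(A@p))
  df <- data.frame(a = rownames(A)[A@i + 1L], b = colnames(A)[j],
                   stringsAsFactors = FALSE)
  df <- df[order(df$a, df$b, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
})

setMethod("show", "BipartiteNetwork", function(object) {
  cat("BipartiteNetwork:", length(partA(object)), "part-A nodes,",
      length(partB(object)), "part-B nodes,", numEdges(object), "edges\n")
})

## part lookup: 1 = part A, 2 = part B, NA = unknown
.whichPart <- function(x, node) {
  if (node %in% rownames(x@adjacency)) 1L
  else if (node %in% colnames(x@adjacency)) 2L
  else NA_integer_
}

.checkNode <- function(x, node) {
  if (length(node) != 1L || is.na(node)) stop("node must be a single identifier")
  p <- .whichPart(x, node)
  if (is.na(p)) stop("unknown node: ", node)
  p
}

#' @rdname neighborSet
#' @export
setMethod("neighborSet", "BipartiteNetwork", function(x, node) {
  p <- .checkNode(x, node)
  A <- x@adjacency
  if (p == 1L) colnames(A)[A[node, ] != 0] else rownames(A)[A[, node] != 0]
})

#' @rdname neighborSet
#' @export
setMethod("secondNeighborSet", "BipartiteNetwork", function(x, node) {
  nb <- neighborSet(x, node)
  if (!length(nb)) return(character(0))
  A <- x@adjacency
  p <- .whichPart(x, node)
  if (p == 1L) {
    hit <- Matrix::rowSums(A[, nb, drop = FALSE]) > 0
    .sortIds(rownames(A)[hit])
  } else {
    hit <- Matrix::colSums(A[nb, , drop = FALSE]) > 0
    .sortIds(colnames(A)[hit])
  }
})

#' Induced star (ego) subnetwork of a node
#'
#' Returns the subnetwork consisting of \code{node}, its neighbours, and the
#' edges between them -- the data behind per-entity association plots.  An
#' isolated node yields a single-node, edgeless network.
#'
#' @param x a \code{BipartiteNetwork}.
#' @param node a node identifier from either part.
#' @return a \code{BipartiteNetwork}.
#' @export
setMethod("egoSubnetwork", "BipartiteNetwork", function(x, node) {
  p <- .checkNode(x, node)
  nb <- neighborSet(x, node)
  if (p == 1L) {
    edges <- if (length(nb)) data.frame(a = node, b = nb) else NULL
    BipartiteNetwork(edges, partA = node, partB = nb)
  } else {
    edges <- if (length(nb)) data.frame(a = nb, b = node) else NULL
    BipartiteNetwork(edges, partA = nb, partB = node)
  }
})

## integer pair codes for fast membership tests; nA*nB assumed < 2^53
.pairCode <- function(x, a, b) {
  ia <- match(a, rownames(x@adjacency))
  ib <- match(b, colnames(x@adjacency))
  if (anyNA(ia)) stop("unknown part-A node: ", a[which(is.na(ia))[1L]])
  if (anyNA(ib)) stop("unknown part-B node: ", b[which(is.na(ib))[1L]])
  (ia - 1) * ncol(x@adjacency) + ib
}

.edgeCodes <- function(x) {
  e <- edgeTable(x)
  if (!nrow(e)) numeric(0) else .pairCode(x, e$a, e$b)
}
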