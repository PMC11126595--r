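#' @rdname BipartiteNetwork-class
#' @param x,object a \code{BipartiteNetwork}.
#' @export
setGeneric("partA", function(x) standardGeneric("partA"))

#' @rdname BipartiteNetwork-class
#' @export
setGeneric("partB", function(x) standardGeneric("partB"))

#' @rdname BipartiteNetwork-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname BipartiteNetwork-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Neighbour set of a node
#'
#' \code{neighborSet} returns the direct neighbours of \code{node} (a subset of
#' the opposite part); \code{secondNeighborSet} returns the
#' neighbours-of-neighbours set, i.e. the union of the neighbour sets of the
#' node's neighbours, which lies in the node's own part.  The node itself is
#' retained in its second-neighbour set whenever it is reachable in two hops.
#'
#' @param x a \code{BipartiteNetwork}.
#' @param node a single node identifier from either part.
#' @return a sorted character vector of node identifiers (possibly empty for
#'   isolated nodes).
#' @examples
#' net <- BipartiteNetwork(data.frame(
#'   a = c("p1", "p1", "p2", "p2", "p3"),
#'   b = c("d1", "d2", "d1", "d3", "d2")))
#' neighborSet(net, "p1")
#' secondNeighborSet(net, "d1")
#' @export
setGeneric("neighborSet", function(x, node) standardGeneric("neighborSet"))

#' @rdname neighborSet
#' @export
setGeneric("secondNeighborSet", function(x, node) standardGeneric("secondNeighborSet"))

#' @rdname networkSummary
#' @export
setGeneric("networkSummary", function(x) standardGeneric("networkSummary"))

#' @rdname degreeExtremes
#' @export
setGeneric("degreeExtremes", function(x, k = 10L) standardGeneric("degreeExtremes"))

#' @rdname egoSubnetwork
#' @export
setGeneric("egoSubnetwork", function(x, node) standardGeneric("egoSubnetwork"))
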