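## Descriptive statistics: part sizes, average degrees, density,
## degree tables and degree extremes.

.newNetworkStats <- function(nA, nB, m, degreeA = numeric(0), degreeB = numeric(0)) {
  if (nA == 0 || nB == 0)
    stop("density undefined: a part is empty (nA=", nA, ", nB=", nB, ")")
  pp <- as.numeric(nA) * as.numeric(nB)
  methods::new("NetworkStats",
               nA = as.numeric(nA), nB = as.numeric(nB), m = as.numeric(m),
               avgDegreeA = m / nA, avgDegreeB = m / nB,
               possiblePairs = pp, density = m / pp,
               degreeA = degreeA, degreeB = degreeB)
}

#' Summarize a bipartite network
#'
#' Computes the descriptive statistics of a two-mode network: part sizes, edge
#' count, average degree of each part, the number of possible cross-part pairs
#' \code{nA * nB}, the density (edges divided by possible pairs), and the
#' per-node degree tables.  Errors if either part is empty (density undefined).
#'
#' @param x a \code{BipartiteNetwork}.
#' @return a \linkS4class{NetworkStats}.
#' @examples
#' toy <- BipartiteNetwork(data.frame(
#'   a = c("p1", "p1", "p2", "p2", "p3"),
#'   b = c("d1", "d2", "d1", "d3", "d2")))
#' networkSummary(toy)
#' @export
setMethod("networkSummary", "BipartiteNetwork", function(x) {
  A <- x@adjacency
  dA <- Matrix::rowSums(A); dB <- Matrix::colSums(A)
  .newNetworkStats(nrow(A), ncol(A), numEdges(x), degreeA = dA, degreeB = dB)
})

#' Network statistics from counts alone
#'
#' Derives the possible-pair count, density and average degrees from the bare
#' counts (part sizes and edge count), without a concrete network.  Useful for
#' checking the arithmetic of a published summary table.
#'
#' @param nA,nB part sizes.
#' @param m edge count.
#' @return a \linkS4class{NetworkStats} with empty degree tables.
#' @examples
#' statsFromCounts(640, 3884, 221216)
#' @export
statsFromCounts <- function(nA, nB, m) .newNetworkStats(nA, nB, m)

## display conventions: density to 5 decimals, average degree to nearest integer
.displayStats <- function(s) list(
  n_a = s@nA, n_b = s@nB, m = s@m,
  possible_pairs = s@possiblePairs,
  density = s@density,
  density_display = round(s@density, 5),
  avg_degree_a = s@avgDegreeA,
  avg_degree_b = s@avgDegreeB,
  avg_degree_a_display = round(s@avgDegreeA),
  avg_degree_b_display = round(s@avgDegreeB))

setMethod("show", "NetworkStats", function(object) {
  d <- .displayStats(object)
  cat("NetworkStats\n")
  cat(sprintf("  part A: %d nodes, average degree %d\n", as.integer(d$n_a),
              as.integer(d$avg_degree_a_display)))
  cat(sprintf("  part B: %d nodes, average degree %d\n", as.integer(d$n_b),
              as.integer(d$avg_degree_b_display)))
  cat(sprintf("  edges: %d of %d possible pairs (density %.5f)\n",
              as.integer(d$m), as.integer(d$possible_pairs), d$density))
})

#' Highest- and lowest-degree nodes per part
#'
#' Returns, for each part, the \code{k} nodes with the most and with the
#' fewest connections.  Ties are broken lexicographically by node identifier
#' so the tables are deterministic; \code{k} larger than a part returns the
#' whole part.
#'
#' @param x a \code{BipartiteNetwork}.
#' @param k how many nodes per (part, end) list.
#' @return a data.frame with columns \code{part} ("A"/"B"), \code{end}
#'   ("top"/"bottom"), \code{rank}, \code{node}, \code{degree}.
#' @export
setMethod("degreeExtremes", "BipartiteNetwork", function(x, k = 10L) {
  if (k < 1L) stop("k must be >= 1")
  A <- x@adjacency
  one <- function(deg, nm, part) {
    kk <- min(k, length(deg))
    top <- order(-deg, nm, method = "radix")[seq_len(kk)]
    bot <- order(deg, nm, method = "radix")[seq_len(kk)]
    rbind(
      data.frame(part = part, end = "top", rank = seq_len(kk),
                 node = nm[top], degree = deg[top], stringsAsFactors = FALSE),
      data.frame(part = part, end = "bottom", rank = seq_len(kk),
                 node = nm[bot], degree = deg[bot], stringsAsFactors = FALSE))
  }
  out <- rbind(one(Matrix::rowSums(A), rownames(A), "A"),
               one(Matrix::colSums(A), colnames(A), "B"))
  rownames(out) <- NULL
  out
})
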