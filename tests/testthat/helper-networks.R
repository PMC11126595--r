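# Fixtures and independent oracles shared across the suite.

# the worked 5-edge example: p1-d1, p1-d2, p2-d1, p2-d3, p3-d2
toyNetwork <- function() {
  BipartiteNetwork(data.frame(
    a = c("p1", "p1", "p2", "p2", "p3"),
    b = c("d1", "d2", "d1", "d3", "d2"),
    stringsAsFactors = FALSE))
}

toyNonEdges <- function() {
  data.frame(a = c("p1", "p2", "p3", "p3"),
             b = c("d3", "d2", "d1", "d3"), stringsAsFactors = FALSE)
}

# a small random bipartite network, independent of the package generator:
# plain Bernoulli coin flips over the pair grid
randomSmallNetwork <- function(nA, nB, density, seed) {
  set.seed(seed)
  ra <- sprintf("x%02d", seq_len(nA))
  cb <- sprintf("y%02d", seq_len(nB))
  hit <- which(matrix(runif(nA * nB), nA, nB) < density)
  edges <- if (length(hit))
    data.frame(a = ra[(hit - 1L) %% nA + 1L], b = cb[(hit - 1L) %/% nA + 1L],
               stringsAsFactors = FALSE)
  else NULL
  suppressMessages(BipartiteNetwork(edges, partA = ra, partB = cb))
}

# two-hop oracle: neighbours-of-neighbours by literal breadth-first expansion
oracleSecondNeighbors <- function(net, node) {
  out <- character(0)
  for (z in neighborSet(net, node)) out <- union(out, neighborSet(net, z))
  sort(out, method = "radix")
}

# exhaustive all-pairs AUC: every (held-out test edge, true non-edge)
# comparison, scored with the literal reference scorer
oracleExhaustiveAUC <- function(train, testEdges, method) {
  nonEdges <- allNonEdges(train)
  te <- paste(testEdges[[1]], testEdges[[2]], sep = "\r")
  ne <- nonEdges[!(paste(nonEdges$a, nonEdges$b, sep = "\r") %in% te), ]
  st <- mapply(function(a, b) bruteForceScore(train, a, b, method),
               testEdges[[1]], testEdges[[2]])
  sn <- mapply(function(a, b) bruteForceScore(train, a, b, method),
               ne$a, ne$b)
  d <- outer(st, sn, `-`)
  tol <- 1e-9
  (sum(d > tol) + 0.5 * sum(abs(d) <= tol)) / length(d)
}

allNonEdges <- function(net) {
  ra <- partA(net); cb <- partB(net)
  all <- expand.grid(a = ra, b = cb, stringsAsFactors = FALSE)
  e <- edgeTable(net)
  keep <- !(paste(all$a, all$b, sep = "\r") %in% paste(e$a, e$b, sep = "\r"))
  all[keep, , drop = FALSE]
}
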