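test_that("construction gives the expected parts, edges and neighbour sets", {
  toy <- toyNetwork()
  expect_setequal(partA(toy), c("p1", "p2", "p3"))
  expect_setequal(partB(toy), c("d1", "d2", "d3"))
  expect_equal(numEdges(toy), 5L)
  expect_equal(neighborSet(toy, "p1"), c("d1", "d2"))
  expect_equal(neighborSet(toy, "p3"), "d2")
  expect_equal(neighborSet(toy, "d2"), c("p1", "p3"))
  expect_error(neighborSet(toy, "nope"), "unknown node")
})

test_that("duplicate rows collapse and row order never changes the object", {
  rows <- data.frame(a = c("p1", "p1", "p2", "p2", "p3"),
                     b = c("d1", "d2", "d1", "d3", "d2"))
  dup <- rbind(rows, rows[1, ])
  expect_message(netDup <- BipartiteNetwork(dup), "1 duplicate")
  expect_equal(numEdges(netDup), 5L)
  shuffled <- rows[c(4, 1, 5, 3, 2), ]
  expect_identical(edgeTable(BipartiteNetwork(shuffled)),
                   edgeTable(BipartiteNetwork(rows)))
})

test_that("an identifier in both columns is a part conflict", {
  expect_error(BipartiteNetwork(data.frame(a = c("p1", "d1"), b = c("d1", "p2"))),
               "part-conflict")
})

test_that("edge-list parsing detects dialects and flags malformed rows", {
  toy <- toyNetwork()
  f <- withr::local_tempfile(fileext = ".csv")
  writeEdgeTable(toy, f)
  expect_identical(edgeTable(readEdgeTable(f)), edgeTable(toy))
  ftab <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeTable(toy, ftab, delimiter = "\t")
  expect_identical(edgeTable(readEdgeTable(ftab)), edgeTable(toy))

  bad <- withr::local_tempfile()
  writeLines(c("p1,d1", "p2,d2,oops"), bad)
  expect_error(readEdgeTable(bad), "line 2")
  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_error(readEdgeTable(empty), "no data rows")

  hdr <- withr::local_tempfile()
  writeLines(c("probiotic,disease", "p1,d1", "p2,d2"), hdr)
  expect_equal(numEdges(readEdgeTable(hdr, header = TRUE)), 2L)
})

test_that("second neighbours match a literal two-hop expansion and stay in-part", {
  toy <- toyNetwork()
  expect_equal(secondNeighborSet(toy, "d1"), c("d1", "d2", "d3"))
  expect_equal(secondNeighborSet(toy, "p3"), c("p1", "p3"))
  iso <- BipartiteNetwork(edgeTable(toy), partA = "q", partB = character(0))
  expect_equal(neighborSet(iso, "q"), character(0))
  expect_equal(secondNeighborSet(iso, "q"), character(0))

  for (seed in 1:5) {
    net <- randomSmallNetwork(12, 15, 0.2, seed)
    for (node in c(sample(partA(net), 4), sample(partB(net), 4))) {
      expect_identical(secondNeighborSet(net, node),
                       oracleSecondNeighbors(net, node))
    }
    expect_true(all(unlist(lapply(partA(net), function(a)
      neighborSet(net, a) %in% partB(net)))))
  }
})

test_that("degree sums equal the edge count on loaded and generated networks", {
  for (net in list(toyNetwork(), randomSmallNetwork(10, 20, 0.15, 3),
                   generateBipartite(25, 30, 0.1, skew = 0.5, seed = 9))) {
    s <- networkSummary(net)
    expect_equal(sum(s@degreeA), s@m)
    expect_equal(sum(s@degreeB), s@m)
    expect_equal(s@density * s@possiblePairs, s@m)
  }
})

test_that("summary arithmetic matches hand counts and printed-table rounding", {
  s <- networkSummary(toyNetwork())
  expect_equal(s@nA, 3); expect_equal(s@nB, 3); expect_equal(s@m, 5)
  expect_equal(s@density, 5 / 9)

  big <- statsFromCounts(640, 3884, 221216)
  expect_equal(big@possiblePairs, 2485760)
  expect_equal(round(big@density, 5), 0.08899)
  expect_equal(round(big@avgDegreeA), 346)
  expect_equal(round(big@avgDegreeB), 57)
  expect_equal(big@avgDegreeA, 221216 / 640, tolerance = 1e-12)

  expect_error(statsFromCounts(0, 5, 0), "density undefined")
})

test_that("degree extremes use the lexicographic tie rule and cover whole parts", {
  toy <- toyNetwork()
  ex <- degreeExtremes(toy, 1)
  topA <- ex[ex$part == "A" & ex$end == "top", ]
  expect_equal(topA$node, "p1")   # p1 and p2 both have degree 2; p1 wins the tie
  expect_equal(topA$degree, 2)
  ex3 <- degreeExtremes(toy, 3)
  botB <- ex3[ex3$part == "B" & ex3$end == "bottom", ]
  expect_equal(botB$degree[1], 1)
  expect_setequal(ex3[ex3$part == "B" & ex3$end == "top", "node"],
                  c("d1", "d2", "d3"))
  expect_error(degreeExtremes(toy, 0), "k must be")
})

test_that("ego subnetworks are the induced star of the node", {
  toy <- toyNetwork()
  ego <- egoSubnetwork(toy, "p1")
  expect_setequal(partA(ego), "p1")
  expect_setequal(partB(ego), c("d1", "d2"))
  expect_equal(numEdges(ego), 2L)
  egoB <- egoSubnetwork(toy, "d2")
  expect_setequal(partA(egoB), c("p1", "p3"))
  expect_equal(numEdges(egoB), 2L)
  iso <- BipartiteNetwork(edgeTable(toy), partA = c("q"))
  egoIso <- egoSubnetwork(iso, "q")
  expect_equal(length(partA(egoIso)) + length(partB(egoIso)), 1L)
  expect_equal(numEdges(egoIso), 0L)
})

test_that("neighbour structure agrees with an igraph reconstruction", {
  skip_if_not_installed("igraph")
  net <- randomSmallNetwork(15, 18, 0.2, 42)
  e <- edgeTable(net)
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = c(partA(net), partB(net)))
  for (node in sample(c(partA(net), partB(net)), 8)) {
    expect_setequal(neighborSet(net, node),
                    igraph::neighbors(g, node)$name)
    two <- setdiff(igraph::ego(g, 2, node)[[1]]$name,
                   igraph::ego(g, 1, node)[[1]]$name)
    mine <- secondNeighborSet(net, node)
    # the igraph 2-ball excludes the centre and 1-ball; ours keeps the centre
    expect_setequal(setdiff(mine, node), two)
  }
})
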