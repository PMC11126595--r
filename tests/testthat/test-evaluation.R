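test_that("fold plans partition the edges into near-equal seeded folds", {
  net <- randomSmallNetwork(15, 20, 0.34, 1)   # ~100 edges
  m <- numEdges(net)
  plan <- makeFolds(net, 10, seed = 7)
  sz <- table(plan@edges$fold)
  expect_equal(length(sz), 10L)
  expect_lte(diff(range(sz)), 1L)
  expect_equal(sum(sz), m)
  # every edge in exactly one fold
  all_test <- do.call(rbind, lapply(1:10, foldTestEdges, plan = plan))
  expect_equal(nrow(all_test), m)
  expect_identical(
    sort(paste(all_test$a, all_test$b)),
    sort(paste(edgeTable(net)$a, edgeTable(net)$b)))
  # determinism and seed sensitivity
  expect_identical(makeFolds(net, 10, seed = 7)@edges, plan@edges)
  expect_false(identical(makeFolds(net, 10, seed = 8)@edges, plan@edges))
  expect_error(makeFolds(randomSmallNetwork(3, 3, 0.3, 2), 10),
               "infeasible split")
  expect_error(makeFolds(net, 1), "k must be")
})

test_that("exact fold sizes follow the remainder rule", {
  netA <- randomSmallNetwork(10, 10, 1, 1)        # complete: 100 edges
  expect_true(all(table(makeFolds(netA, 10, 1)@edges$fold) == 10))
  net <- randomSmallNetwork(40, 40, 0.2, 3)
  k <- 7
  sz <- table(makeFolds(net, k, 5)@edges$fold)
  m <- numEdges(net)
  expect_equal(sort(as.integer(sz)),
               sort(rep(m %/% k, k) + (seq_len(k) <= m %% k)))
})

test_that("training networks keep every node and drop exactly the held-out edges", {
  toy <- toyNetwork()
  tr <- trainingNetwork(toy, data.frame(a = "p3", b = "d2"))
  expect_setequal(partA(tr), partA(toy))          # p3 retained though isolated
  expect_equal(neighborSet(tr, "p3"), character(0))
  expect_equal(numEdges(tr), 4L)
  expect_identical(edgeTable(trainingNetwork(toy, NULL)), edgeTable(toy))
  empty <- trainingNetwork(toy, edgeTable(toy))
  expect_equal(numEdges(empty), 0L)
  expect_setequal(partB(empty), partB(toy))
  expect_error(trainingNetwork(toy, data.frame(a = "p3", b = "d1")),
               "not an edge")
})

test_that("the AUC identity holds and degenerate scorers give 1, 0.5 and 0", {
  net <- randomSmallNetwork(12, 15, 0.25, 4)
  plan <- makeFolds(net, 5, seed = 2)
  test <- foldTestEdges(plan, 1)
  train <- trainingNetwork(net, test)
  testKey <- paste(test$a, test$b)
  perfect <- function(net, x, y) as.numeric(paste(x, y) %in% testKey)
  constant <- function(net, x, y) rep(0.5, length(x))
  inverted <- function(net, x, y) -as.numeric(paste(x, y) %in% testKey)
  for (n in c(1L, 37L, 400L)) {
    expect_equal(aucSampled(train, test, perfect, n = n, seed = 3)@auc, 1.0)
    expect_equal(aucSampled(train, test, constant, n = n, seed = 3)@auc, 0.5)
    expect_equal(aucSampled(train, test, inverted, n = n, seed = 3)@auc, 0.0)
  }
  r <- aucSampled(train, test, "CN", n = 300, seed = 9)
  expect_equal(r@auc, (r@nWin + 0.5 * r@nTie) / r@n)
  expect_lte(r@nWin + r@nTie, r@n)
  expect_identical(aucSampled(train, test, "CN", n = 300, seed = 9)@auc, r@auc)
  expect_error(aucSampled(train, test, "CN", n = 0, seed = 1), "n must be")
  expect_error(aucSampled(train, edgeTable(train)[1, ], "CN", n = 5, seed = 1),
               "present in training")
})

test_that("AUC sampling fails cleanly when no true non-edge exists", {
  full <- randomSmallNetwork(4, 4, 1, 1)    # complete bipartite graph
  test <- edgeTable(full)[1:4, ]
  train <- trainingNetwork(full, test)
  expect_error(aucSampled(train, test, "CN", n = 10, seed = 1),
               "sampling impossible")
})

test_that("sampled AUC converges to the exhaustive all-pairs value", {
  net <- generateBipartite(25, 25, 0.15, blocks = 3, withinBlockOdds = 15,
                           seed = 21)
  plan <- makeFolds(net, 5, seed = 6)
  test <- foldTestEdges(plan, 1)
  train <- trainingNetwork(net, test)
  exact <- oracleExhaustiveAUC(train, test, "CN")
  n <- 20000L
  sampled <- aucSampled(train, test, "CN", n = n, seed = 13)@auc
  expect_lt(abs(sampled - exact), 3 * sqrt(0.25 / n))
})

test_that("precision@L rewards perfect rankings and respects the tie rule", {
  net <- randomSmallNetwork(12, 15, 0.25, 8)
  plan <- makeFolds(net, 5, seed = 3)
  test <- foldTestEdges(plan, 1)
  train <- trainingNetwork(net, test)
  testKey <- paste(test$a, test$b)
  perfect <- function(net, x, y) as.numeric(paste(x, y) %in% testKey)
  expect_equal(precisionAt(train, test, perfect)@precision, 1.0)

  # constant scorer: the first l lexicographic candidates decide the hits
  flat <- function(net, x, y) rep(1, length(x))
  ne <- allNonEdges(train)
  ne <- ne[order(ne$a, ne$b, method = "radix"), ]
  l <- nrow(test)
  expected <- sum(paste(ne$a, ne$b)[seq_len(l)] %in% testKey) / l
  expect_equal(precisionAt(train, test, flat)@precision, expected)

  expect_error(precisionAt(train, test, "CN", l = 0), "undefined precision")
  expect_error(precisionAt(train, test, "CN", l = 1e6), "exceeds")
})

test_that("precision via ranked lists matches a literal re-ranking", {
  toy <- toyNetwork()
  test <- data.frame(a = "p3", b = "d2")
  train <- trainingNetwork(toy, test)
  # literal ranking of the 5 non-edges of the 4-edge training network
  ne <- allNonEdges(train)
  sc <- mapply(function(a, b) bruteForceScore(train, a, b, "CN"), ne$a, ne$b)
  topPair <- ne[order(-sc, ne$a, ne$b, method = "radix")[1], ]
  expected <- as.numeric(topPair$a == "p3" & topPair$b == "d2")
  expect_equal(precisionAt(train, test, "CN", l = 1)@precision, expected)
})

test_that("full evaluation runs are complete and byte-identical under one seed", {
  net <- generateBipartite(20, 30, 0.15, blocks = 3, withinBlockOdds = 15,
                           seed = 5)
  rep1 <- evaluateLinkPrediction(net, methods = c("CN", "PA"), k = 5, seed = 11)
  expect_equal(nrow(rep1@perFold), 5L * 2L)
  expect_equal(sum(rep1@perFold$testSize[rep1@perFold$method == "CN"]),
               numEdges(net))
  rep2 <- evaluateLinkPrediction(net, methods = c("CN", "PA"), k = 5, seed = 11)
  expect_identical(reportToJSON(rep1), reportToJSON(rep2))
  # summaries recompute from the per-fold values
  cn <- rep1@perFold[rep1@perFold$method == "CN", ]
  expect_equal(rep1@summary$meanAUC[rep1@summary$method == "CN"], mean(cn$auc))
  expect_equal(rep1@summary$pooledAUC[rep1@summary$method == "CN"],
               sum(cn$nWin + 0.5 * cn$nTie) / sum(cn$n))
})

test_that("changing the AUC sample count does not change the folds", {
  net <- generateBipartite(20, 30, 0.15, seed = 5)
  r1 <- evaluateLinkPrediction(net, methods = "CN", k = 5, n = 50, seed = 11)
  r2 <- evaluateLinkPrediction(net, methods = "CN", k = 5, n = 200, seed = 11)
  expect_equal(r1@perFold$testSize, r2@perFold$testSize)
  expect_equal(r1@perFold$l, r2@perFold$l)
  expect_equal(r1@perFold$hits, r2@perFold$hits)   # precision path unchanged
})
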