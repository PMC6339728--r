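test_that("the transition operator is D^-1 A with zero rows for isolates", {
  net <- edgelistToNetwork(rbind(c("A", "B"), c("B", "C"), c("Z", "Z")))
  W <- transitionOperator(net)
  expect_equal(W["B", c("A", "C")], c(A = 0.5, C = 0.5))
  expect_equal(unname(W["A", "B"]), 1)
  expect_equal(sum(W["Z", ]), 0)  # isolated node: zero row
  deg <- nodeDegrees(net)
  expect_equal(unname(Matrix::rowSums(W)[deg > 0]),
               rep(1, sum(deg > 0)))
  # dense oracle: elementwise division of adjacency by row sums
  net30 <- randomTestGraph(30, 90, seed = 13)
  A <- as.matrix(adjacencyMatrix(net30))
  expected <- A / ifelse(rowSums(A) > 0, rowSums(A), 1)
  expect_equal(as.matrix(transitionOperator(net30)), expected,
               tolerance = 1e-14)
})

test_that("the worked two-node diffusion gives (35/54, 19/54)", {
  net <- edgelistToNetwork(rbind(c("A", "B")))
  seed <- buildSeed("KDP", "A", character(), net)
  sv <- grScores(net, seed)
  expect_equal(scores(sv), c(A = 35 / 54, B = 19 / 54), tolerance = 1e-14)
  # alpha = 0: the operator is the identity, scores equal p0
  sv0 <- grScores(net, seed, diffusionConfig(alpha = 0))
  expect_equal(scores(sv0), c(A = 1, B = 0))
})

test_that("iterative diffusion equals the dense matrix-power oracle", {
  for (s in 1:15) {
    net <- randomTestGraph(sample(5:50, 1), sample(10:100, 1),
                           seed = 300 + s)
    set.seed(400 + s)
    seedMem <- sample(networkNodes(net), sample(1:4, 1))
    cfg <- diffusionConfig(alpha = runif(1, 0.1, 1),
                           nIter = sample(1:5, 1))
    seed <- buildSeed("KDP", seedMem, character(), net)
    got <- scores(grScores(net, seed, cfg))
    want <- denseGrOracle(net, seedMem, cfg$alpha, cfg$nIter)
    expect_lt(max(abs(got - want[names(got)])), 1e-10)
  }
})

test_that("diffusion conserves mass, stays non-negative, and is linear", {
  net <- randomTestGraph(40, 120, seed = 17, minDegreeOne = TRUE)
  nodes <- networkNodes(net)
  set.seed(18)
  s1 <- sample(nodes, 5)
  s2 <- sample(setdiff(nodes, s1), 4)
  g1 <- scores(grScores(net, buildSeed("KDP", s1, character(), net)))
  g2 <- scores(grScores(net, buildSeed("KDP", s2, character(), net)))
  g12 <- scores(grScores(net, buildSeed("KDP", c(s1, s2), character(), net)))
  expect_equal(sum(g1), 5, tolerance = 1e-12)         # mass conservation
  expect_equal(sum(g12), 9, tolerance = 1e-12)
  expect_true(all(g1 >= 0))
  expect_equal(g12, g1 + g2, tolerance = 1e-12)       # linearity
  # monotonicity: enlarging the seed never decreases any score
  expect_true(all(g12 - g1 > -1e-14))
})

test_that("a single diffusion step matches the hand formula on a star", {
  # star: center C with 5 leaves; seed = two leaves (degree 1 each)
  el <- cbind("C", paste0("L", 1:5))
  net <- edgelistToNetwork(el)
  seed <- buildSeed("KDP", c("L1", "L2"), character(), net)
  alpha <- 0.5
  sv <- grScores(net, seed, diffusionConfig(alpha = alpha, nIter = 1L))
  # non-seed node score = alpha * sum over seed neighbors of 1/degree
  expect_equal(unname(scores(sv)["C"]), alpha * (1 / 1 + 1 / 1))
  expect_equal(unname(scores(sv)["L3"]), 0)
  # and LR agrees with the neighbor count
  expect_equal(unname(scores(lrScores(net, seed))["C"]), 2)
})

test_that("LR counts seed members among direct neighbors", {
  tri <- edgelistToNetwork(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  sv <- lrScores(tri, buildSeed("KDP", "A", character(), tri))
  expect_equal(scores(sv), c(A = 0, B = 1, C = 1))
  # brute-force double loop oracle on a random graph
  net <- randomTestGraph(100, 400, seed = 23)
  nodes <- networkNodes(net)
  set.seed(24)
  seedMem <- sample(nodes, 10)
  got <- scores(lrScores(net, buildSeed("KDP", seedMem, character(), net)))
  el <- networkEdges(net)
  keys <- c(paste(el[, 1], el[, 2]), paste(el[, 2], el[, 1]))
  for (v in sample(nodes, 25)) {
    cnt <- sum(vapply(seedMem, function(k) paste(v, k) %in% keys, TRUE))
    expect_equal(unname(got[v]), cnt)
  }
})

test_that("empty seeds score zero with a warning rather than failing", {
  net <- edgelistToNetwork(rbind(c("A", "B")))
  seed <- buildSeed("KDP", "A", character(), net)
  empty <- holdoutSeed(seed, "A")
  expect_warning(sv <- grScores(net, empty), "empty seed")
  expect_equal(unname(scores(sv)), c(0, 0))
})

test_that("ranking is deterministic with lexicographic tie-breaks", {
  sv <- methods::new("ScoreVector",
                     scores = c(B = 0.2, A = 0.2, C = 0.5),
                     method = "GR", seedKind = "KDP")
  r <- rankProteins(sv)
  expect_identical(r$protein, c("C", "A", "B"))
  expect_identical(r$rank, 1:3)
  expect_identical(nrow(rankProteins(sv, exclude = c("A", "B", "C"))), 0L)
  # output is a permutation of non-excluded nodes, non-increasing scores
  net <- randomTestGraph(50, 120, seed = 31)
  set.seed(32)
  sv2 <- grScores(net, buildSeed("KDP", sample(networkNodes(net), 5),
                                 character(), net))
  r2 <- rankProteins(sv2, exclude = networkNodes(net)[1:3])
  expect_setequal(r2$protein, networkNodes(net)[-(1:3)])
  expect_true(all(diff(r2$score) <= 0))
})

test_that("the diffusion configuration enforces operator non-negativity", {
  expect_error(diffusionConfig(alpha = 4, nIter = 3L), "<= 1")
  cfg <- diffusionConfig()
  expect_identical(cfg$alpha, 0.5)
  expect_identical(cfg$nIter, 3L)
})
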