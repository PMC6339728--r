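test_that("rocAuc handles separation, ties, and matches independent oracles", {
  expect_equal(auc(rocAuc(c(5, 4, 1, 2), c(1, 1, 0, 0))), 1)
  expect_equal(auc(rocAuc(rep(2, 10), rep(c(0, 1), 5))), 0.5)
  set.seed(51)
  for (i in 1:10) {
    sc <- round(rnorm(20), 1)  # rounding forces ties
    lab <- rbinom(20, 1, 0.4)
    if (sum(lab) == 0 || sum(lab) == 20) next
    expect_equal(auc(rocAuc(sc, lab)), bruteForceAuc(sc, lab),
                 tolerance = 1e-12)
    # cross-check against pROC, the field-standard implementation
    expect_equal(auc(rocAuc(sc, lab)),
                 as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
  expect_error(rocAuc(1:3, c(1, 1, 1)), "negative label")
})

test_that("the ROC curve integrates to the rank AUC and spans (0,0)-(1,1)", {
  set.seed(52)
  sc <- round(rnorm(50), 1)
  lab <- rbinom(50, 1, 0.5)
  rc <- rocAuc(sc, lab)
  expect_equal(rc@tpr[1], 0); expect_equal(rc@fpr[1], 0)
  expect_equal(rc@tpr[length(rc@tpr)], 1)
  expect_equal(rc@fpr[length(rc@fpr)], 1)
  trapezoid <- sum(diff(rc@fpr) * (utils::head(rc@tpr, -1) +
                                     utils::tail(rc@tpr, -1)) / 2)
  expect_equal(trapezoid, auc(rc), tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(53)
  sc <- rnorm(60); lab <- rbinom(60, 1, 0.3)
  expect_equal(auc(rocAuc(exp(sc), lab)), auc(rocAuc(sc, lab)))
  expect_equal(auc(rocAuc(rank(sc), lab)), auc(rocAuc(sc, lab)))
})

test_that("a perfectly informative topology gives pooled LOOCV AUC 1", {
  # KDPs form a clique; other nodes form a separate path, so every
  # held-out KDP outscores all possible negatives under LR
  kdps <- paste0("K", 1:5)
  clique <- t(combn(kdps, 2))
  others <- paste0("O", 1:40)
  path <- cbind(others[-40], others[-1])
  net <- edgelistToNetwork(rbind(clique, path))
  res <- loocv(net, kdps, seedKind = "KDP", method = "LR", nNeg = 20L,
               rngSeed = 5L)
  expect_equal(auc(res), 1)
  expect_identical(nrow(res@iterations), 5L * 21L)
  expect_true(all(res@perIterationAuc == 1))
})

test_that("LOOCV is bit-reproducible and seed-sensitive", {
  bench <- generateBenchmark(smallBenchConfig(rngSeed = 61))
  deps <- depProteins(callDEPs(bench$expression))
  run <- function(seed) loocv(bench$network, bench$diseaseProteins, deps,
                              seedKind = "eKDP", method = "GR",
                              nNeg = 50L, rngSeed = seed)
  a <- run(9L); b <- run(9L); c <- run(10L)
  expect_identical(a@iterations, b@iterations)
  expect_identical(auc(a), auc(b))
  expect_false(identical(a@iterations$protein, c@iterations$protein))
  # every iteration holds exactly one positive and nNeg negatives
  counts <- table(a@iterations$iteration, a@iterations$label)
  expect_true(all(counts[, "1"] == 1) && all(counts[, "0"] == 50))
})

test_that("the holdout rule is actually applied inside LOOCV", {
  # K1-D edge only: when K1 is held out, D must leave the eKDP seed,
  # leaving only K2; scores then come from K2 alone
  net <- edgelistToNetwork(rbind(c("K1", "D"), c("K1", "K2"),
                                 cbind(paste0("O", 1:30), "HUB")))
  res <- loocv(net, c("K1", "K2"), deps = "D", seedKind = "eKDP",
               method = "LR", nNeg = 10L, rngSeed = 3L)
  it1 <- res@iterations[res@iterations$heldOut == "K1", ]
  # K1 neighbors K2 (the only remaining seed): LR score 1
  expect_equal(it1$score[it1$protein == "K1"], 1)
})

test_that("top-k recovery counts KDPs with saturation and monotonicity", {
  ranking <- data.frame(rank = 1:10,
                        protein = c(paste0("K", 1:3), paste0("X", 1:7)),
                        score = 10:1)
  counts <- topkRecovery(ranking, paste0("K", 1:3), ks = c(1, 2, 5, 10))
  expect_identical(unname(counts), c(1L, 2L, 3L, 3L))
  expect_true(all(diff(counts) >= 0))
  expect_identical(unname(topkRecovery(ranking, "ABSENT", ks = 5)), 0L)
  expect_warning(topkRecovery(ranking, "K1", ks = 50), "exceed")
})

test_that("random rankings recover KDPs at the hypergeometric rate", {
  proteins <- sprintf("P%04d", 1:1000)
  kdps <- proteins[1:39]
  set.seed(71)
  counts <- replicate(200, {
    ranking <- data.frame(protein = sample(proteins))
    topkRecovery(ranking, kdps, ks = 100)
  })
  expected <- 100 * 39 / 1000  # 3.9
  se <- sd(counts) / sqrt(200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("KDP-DEP linkage behaves at the degenerate extremes", {
  net <- randomTestGraph(80, 300, seed = 81)
  nodes <- networkNodes(net)
  kdps <- nodes[1:8]
  none <- kdpDepLinkage(net, kdps, character(), nRandom = 20, rngSeed = 1)
  expect_equal(none$meanKdpLinks, 0)
  expect_equal(none$meanRandomLinks, 0)
  all <- kdpDepLinkage(net, kdps, nodes, nRandom = 20, rngSeed = 1)
  expect_equal(all$meanKdpLinks, mean(nodeDegrees(net)[kdps]))
  # reproducibility
  someDeps <- utils::tail(nodes, 20)
  a <- kdpDepLinkage(net, kdps, someDeps, nRandom = 30, rngSeed = 4)
  b <- kdpDepLinkage(net, kdps, someDeps, nRandom = 30, rngSeed = 4)
  expect_identical(a$controlMeans, b$controlMeans)
})
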