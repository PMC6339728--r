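# In-code fixtures shared across the suite. Everything is generated
# deterministically from explicit seeds; no binary data on disk.

# Erdos-Renyi-style random simple graph, built through the package's own
# constructor so dedup rules apply uniformly.
randomTestGraph <- function(nNodes, nEdges, seed, minDegreeOne = FALSE) {
  set.seed(seed)
  labels <- sprintf("N%03d", seq_len(nNodes))
  repeat {
    a <- sample(labels, nEdges, replace = TRUE)
    b <- sample(labels, nEdges, replace = TRUE)
    keep <- a != b
    if (!any(keep)) next
    net <- edgelistToNetwork(cbind(a[keep], b[keep]))
    if (!minDegreeOne || all(nodeDegrees(net) > 0)) return(net)
  }
}

# Dense, explicit matrix-power diffusion oracle in base R: builds A and
# D^-1 A as dense matrices and multiplies M out N times. Independent of
# the sparse iterative implementation under test.
denseGrOracle <- function(net, seedMembers, alpha = 0.5, nIter = 3L) {
  nodes <- networkNodes(net)
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  el <- networkEdges(net)
  for (i in seq_len(nrow(el))) {
    A[el[i, 1], el[i, 2]] <- 1
    A[el[i, 2], el[i, 1]] <- 1
  }
  d <- rowSums(A)
  W <- A / ifelse(d > 0, d, 1)
  W[d == 0, ] <- 0
  s <- alpha / nIter
  M <- (1 - s) * diag(length(nodes)) + s * W
  P <- diag(length(nodes))
  for (i in seq_len(nIter)) P <- P %*% M
  p0 <- as.numeric(nodes %in% seedMembers)
  stats::setNames(as.numeric(p0 %*% P), nodes)
}

# Pairwise brute-force AUC: P(pos > neg) + P(tie)/2 over all pairs.
bruteForceAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Small benchmark configuration used where the full default scale is not
# the point of the test.
smallBenchConfig <- function(rngSeed = 1L) {
  syntheticConfig(nNodes = 200L, attachEdges = 3L, moduleSize = 10L,
                  nTumor = 10L, nNormal = 10L, rngSeed = rngSeed)
}
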