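test_that("duplicate and self-linked interactions are removed, endpoints kept", {
  net <- edgelistToNetwork(rbind(c("A", "B"), c("B", "A"), c("C", "C"),
                                 c("A", "B")))
  expect_setequal(networkNodes(net), c("A", "B", "C"))
  expect_identical(numEdges(net), 1L)
  expect_identical(droppedRecords(net),
                   c(duplicate = 2L, self_loop = 1L))
  # C survives as an isolated node
  expect_identical(unname(nodeDegrees(net)["C"]), 0)
})

test_that("degrees and average degree follow the definitions", {
  net <- edgelistToNetwork(rbind(c("A", "B"), c("B", "C")))
  expect_equal(nodeDegrees(net)[c("A", "B", "C")],
               c(A = 1, B = 2, C = 1))
  expect_equal(averageDegree(net), 4 / 3)
})

test_that("construction agrees with a set-based dedup oracle on random records", {
  set.seed(42)
  labels <- sprintf("G%02d", 1:50)
  raw <- cbind(sample(labels, 500, replace = TRUE),
               sample(labels, 500, replace = TRUE))
  # independent oracle: canonicalize pairs as sorted strings, drop loops,
  # count unique
  keys <- apply(raw, 1, function(r) paste(sort(r), collapse = "|"))
  expectedEdges <- length(unique(keys[raw[, 1] != raw[, 2]]))
  expectedNodes <- length(unique(c(raw)))
  net <- edgelistToNetwork(raw)
  expect_identical(numEdges(net), as.integer(expectedEdges))
  expect_identical(numNodes(net), as.integer(expectedNodes))
})

test_that("edge lists round-trip through disk and are orientation/order invariant", {
  net <- randomTestGraph(30, 80, seed = 7)
  f <- withr::local_tempfile(fileext = ".tsv")
  writePPIEdgeList(net, f)
  back <- readPPIEdgeList(f, verbose = FALSE)
  expect_setequal(networkNodes(back), networkNodes(net))
  canon <- function(n) {
    el <- networkEdges(n)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(canon(back), canon(net))
  # shuffle rows and flip orientations: same network
  el <- networkEdges(net)
  set.seed(1)
  flip <- runif(nrow(el)) < 0.5
  el[flip, ] <- el[flip, 2:1]
  shuffled <- edgelistToNetwork(el[sample(nrow(el)), ])
  expect_identical(canon(shuffled), canon(net))
  expect_equal(sum(nodeDegrees(net)), 2 * numEdges(net))
})

test_that("header rows are auto-detected and can be forced", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2", "A\tB", "B\tC"), f)
  net <- readPPIEdgeList(f, verbose = FALSE)
  expect_setequal(networkNodes(net), c("A", "B", "C"))
  # identifiers that recur as endpoints are not mistaken for a header
  writeLines(c("A\tB", "B\tC"), f)
  expect_identical(numEdges(readPPIEdgeList(f, verbose = FALSE)), 2L)
  # explicit override drops the first row regardless
  expect_identical(numEdges(readPPIEdgeList(f, header = TRUE,
                                            verbose = FALSE)), 1L)
})

test_that("protein lists parse with normalization, dedup, and order", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("a; a; b", f)
  expect_identical(readProteinList(f, delimiter = ";"), c("A", "B"))
  writeLines(c(" kras ", "BRCA2", "kras"), f)
  expect_identical(readProteinList(f), c("KRAS", "BRCA2"))
  writeLines("; ;", f)
  expect_error(readProteinList(f, delimiter = ";"), "empty")
})

test_that("restriction to the network keeps exactly the covered members", {
  net <- edgelistToNetwork(rbind(c("A", "B"), c("B", "C")))
  expect_identical(
    suppressMessages(restrictToNetwork(c("A", "B", "X"), net)),
    c("A", "B"))
  expect_identical(
    suppressMessages(restrictToNetwork(c("C", "A"), net)), c("C", "A"))
  expect_warning(
    suppressMessages(restrictToNetwork("ZZZ", net)), "no list member")
})

test_that("a curated list intersects a network built to contain part of it", {
  # mirrors restricting a 44-member curated list to a network holding 39
  members <- sprintf("KDP%02d", 1:44)
  inNet <- members[1:39]
  set.seed(9)
  el <- cbind(inNet, sample(sprintf("X%02d", 1:30), 39, replace = TRUE))
  net <- edgelistToNetwork(el)
  expect_length(suppressMessages(restrictToNetwork(members, net)), 39L)
})

test_that("degenerate edge-list inputs error out", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("A\tA", f)
  expect_error(readPPIEdgeList(f, verbose = FALSE), "empty graph")
  expect_error(readPPIEdgeList(file.path(tempdir(), "nope.tsv")),
               "cannot read")
  expect_error(edgelistToNetwork(matrix("A", 1, 1)), "2 columns")
})
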