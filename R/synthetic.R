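#' Configuration of the synthetic benchmark generator
#'
#' The generator emulates the statistical structure the ranking method
#' assumes: a sparse scale-free interactome with average degree near 10,
#' a connected planted disease module standing in for the curated
#' known-disease-protein list, and tumor/normal expression in which
#' differential expression is enriched among the module's direct
#' neighbors (disease proteins touch far more DEPs than random
#' proteins). Defaults define the standard benchmark: 1000 proteins,
#' 5 attachments per node (average degree ~10), a 39-protein module,
#' 30 tumor and 30 normal samples, a 4-standard-deviation abundance
#' shift for truly differential proteins, neighbor DE probability 0.4
#' against a 0.02 background.
#'
#' @param nNodes network size.
#' @param attachEdges preferential-attachment edges per new node.
#' @param moduleSize planted disease-module size.
#' @param nTumor,nNormal sample sizes per group.
#' @param effectSize tumor-group mean abundance shift, in the units of
#'   `noiseSd`, applied to truly differential proteins.
#' @param neighborDepProb probability that a direct neighbor of the
#'   module is truly differentially expressed; must exceed
#'   `backgroundDepProb` (the enrichment the method exploits).
#' @param backgroundDepProb DE probability for all remaining proteins.
#' @param noiseSd abundance noise standard deviation.
#' @param missingRate uniform missing-at-random rate in the expression
#'   matrix (default 0).
#' @param dsShift,dsSd dependency-score mean and sd for module proteins
#'   in the target lineage (non-module and other-lineage scores draw
#'   from a standard normal).
#' @param rngSeed integer master seed.
#' @return a validated configuration list.
#' @export
syntheticConfig <- function(nNodes = 1000L, attachEdges = 5L,
                            moduleSize = 39L, nTumor = 30L, nNormal = 30L,
                            effectSize = 4, neighborDepProb = 0.4,
                            backgroundDepProb = 0.02, noiseSd = 1,
                            missingRate = 0, dsShift = -3, dsSd = 0.5,
                            rngSeed = 1L) {
  stopifnot(nNodes > attachEdges, attachEdges >= 1L,
            moduleSize >= 1L, moduleSize < nNodes,
            nTumor >= 2L, nNormal >= 2L, noiseSd > 0, dsSd > 0,
            neighborDepProb >= 0, neighborDepProb <= 1,
            backgroundDepProb >= 0, backgroundDepProb <= 1,
            missingRate >= 0, missingRate < 1)
  if (neighborDepProb <= backgroundDepProb)
    stop("neighborDepProb must exceed backgroundDepProb (the planted enrichment)")
  list(nNodes = as.integer(nNodes), attachEdges = as.integer(attachEdges),
       moduleSize = as.integer(moduleSize), nTumor = as.integer(nTumor),
       nNormal = as.integer(nNormal), effectSize = effectSize,
       neighborDepProb = neighborDepProb,
       backgroundDepProb = backgroundDepProb, noiseSd = noiseSd,
       missingRate = missingRate, dsShift = dsShift, dsSd = dsSd,
       rngSeed = as.integer(rngSeed))
}

.syntheticNodeNames <- function(n) {
  sprintf("P%0*d", max(4L, nchar(n)), seq_len(n))
}

#' Generate a synthetic scale-free interactome
#'
#' Undirected preferential-attachment (Barabasi-Albert) graph: PPI
#' degree distributions are heavy-tailed, and with `attachEdges = 5` the
#' average degree lands near the ~10 typical of high-quality
#' interactomes. The graph is connected by construction.
#'
#' @param cfg a [syntheticConfig()] list.
#' @param rngSeed seed override (defaults to `cfg$rngSeed`).
#' @return a [PPINetwork-class] with nodes named `P0001`, `P0002`, ...
#' @export
generateNetwork <- function(cfg = syntheticConfig(), rngSeed = cfg$rngSeed) {
  set.seed(rngSeed)
  g <- igraph::sample_pa(cfg$nNodes, m = cfg$attachEdges, directed = FALSE)
  igraph::V(g)$name <- .syntheticNodeNames(cfg$nNodes)
  methods::new("PPINetwork", graph = igraph::simplify(g),
               dropped = c(duplicate = 0L, self_loop = 0L))
}

#' Plant a connected disease module
#'
#' Grows a connected node set by seeded random breadth-first expansion:
#' starting from a random node, members are added one at a time by
#' uniform choice from the current frontier (non-member neighbors of the
#' member set). The induced subgraph is connected by construction,
#' mimicking the clustering of real disease proteins.
#'
#' @param net a [PPINetwork-class].
#' @param size module size.
#' @param rngSeed integer seed.
#' @return character vector of module member identifiers.
#' @export
plantDiseaseModule <- function(net, size, rngSeed = 1L) {
  stopifnot(methods::is(net, "PPINetwork"), size >= 1L)
  g <- net@graph
  comp <- igraph::components(g)
  if (max(comp$csize) < size)
    stop("module size exceeds the largest connected component")
  set.seed(rngSeed)
  eligible <- networkNodes(net)[comp$membership %in%
                                  which(comp$csize >= size)]
  start <- sample(eligible, 1L)
  members <- start
  frontier <- setdiff(names(igraph::neighbors(g, start)), members)
  while (length(members) < size) {
    nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    members <- c(members, nxt)
    frontier <- setdiff(union(frontier,
                              names(igraph::neighbors(g, nxt))), members)
  }
  members
}

#' Generate a tumor/normal expression matrix with planted enrichment
#'
#' Normal-group abundances are i.i.d. Gaussian(0, `noiseSd`); the tumor
#' group adds `effectSize` (a pure location shift, the minimal structure
#' Welch's test assumes) to the truly differential proteins. The true-DE
#' set is the whole module, each direct module neighbor independently
#' with probability `neighborDepProb`, and each remaining protein with
#' probability `backgroundDepProb` -- the neighbor enrichment that makes
#' disease proteins link to many DEPs. An optional uniform
#' missing-at-random mask is applied last.
#'
#' @param net a [PPINetwork-class].
#' @param module character vector of module members (see
#'   [plantDiseaseModule()]).
#' @param cfg a [syntheticConfig()] list.
#' @param rngSeed seed override.
#' @return list with `expression` (a `SummarizedExperiment`, see
#'   [makeExpressionDataset()]) and `trueDe` (character vector).
#' @export
generateExpression <- function(net, module, cfg = syntheticConfig(),
                               rngSeed = cfg$rngSeed) {
  stopifnot(methods::is(net, "PPINetwork"))
  nodes <- networkNodes(net)
  stopifnot(all(module %in% nodes))
  set.seed(rngSeed)
  nbrIdx <- unique(unlist(igraph::adjacent_vertices(net@graph, module)))
  nbr <- setdiff(nodes[nbrIdx], module)
  rest <- setdiff(nodes, c(module, nbr))
  trueDe <- c(module,
              nbr[stats::runif(length(nbr)) < cfg$neighborDepProb],
              rest[stats::runif(length(rest)) < cfg$backgroundDepProb])
  nS <- cfg$nTumor + cfg$nNormal
  X <- matrix(stats::rnorm(length(nodes) * nS, 0, cfg$noiseSd),
              nrow = length(nodes),
              dimnames = list(nodes,
                              c(sprintf("T%03d", seq_len(cfg$nTumor)),
                                sprintf("N%03d", seq_len(cfg$nNormal)))))
  X[trueDe, seq_len(cfg$nTumor)] <-
    X[trueDe, seq_len(cfg$nTumor)] + cfg$effectSize * cfg$noiseSd
  if (cfg$missingRate > 0)
    X[stats::runif(length(X)) < cfg$missingRate] <- NA_real_
  groups <- c(rep("tumor", cfg$nTumor), rep("normal", cfg$nNormal))
  list(expression = makeExpressionDataset(X, groups), trueDe = trueDe)
}

#' Generate a synthetic gene-dependency-score table
#'
#' Module proteins draw their target-lineage score from
#' Gaussian(`dsShift`, `dsSd`) (essential: well below the -2 cutoff),
#' all other scores -- non-module proteins and a second, independent
#' lineage -- from a standard normal.
#'
#' @inheritParams generateExpression
#' @param targetLineage lineage name for the shifted scores.
#' @param otherLineage name of the independent control lineage.
#' @return data.frame with columns `protein`, `lineage`, `ds`.
#' @export
generateDSTable <- function(net, module, cfg = syntheticConfig(),
                            targetLineage = "colon",
                            otherLineage = "lung",
                            rngSeed = cfg$rngSeed) {
  nodes <- networkNodes(net)
  set.seed(rngSeed)
  inMod <- nodes %in% module
  target <- ifelse(inMod,
                   stats::rnorm(length(nodes), cfg$dsShift, cfg$dsSd),
                   stats::rnorm(length(nodes), 0, 1))
  other <- stats::rnorm(length(nodes), 0, 1)
  data.frame(protein = rep(nodes, 2L),
             lineage = rep(c(targetLineage, otherLineage),
                           each = length(nodes)),
             ds = c(target, other), stringsAsFactors = FALSE)
}

#' Generate a complete synthetic benchmark dataset
#'
#' Chains the generators: network, planted module (the ground-truth
#' "KDPs"), expression matrix with enriched differential expression, and
#' dependency-score table. Sub-generators use offset seeds derived from
#' `cfg$rngSeed` so the whole dataset is bit-reproducible.
#'
#' @param cfg a [syntheticConfig()] list.
#' @return list with `network`, `diseaseProteins`, `trueDe`,
#'   `expression` (SummarizedExperiment), `dsTable`, and `config`.
#' @export
generateBenchmark <- function(cfg = syntheticConfig()) {
  net <- generateNetwork(cfg, rngSeed = cfg$rngSeed)
  module <- plantDiseaseModule(net, cfg$moduleSize,
                               rngSeed = cfg$rngSeed + 1L)
  expr <- generateExpression(net, module, cfg, rngSeed = cfg$rngSeed + 2L)
  ds <- generateDSTable(net, module, cfg, rngSeed = cfg$rngSeed + 3L)
  list(network = net, diseaseProteins = module, trueDe = expr$trueDe,
       expression = expr$expression, dsTable = ds, config = cfg)
}

#' Write a benchmark dataset as plain-text files
#'
#' Writes `network.tsv` (edge list), `expression.tsv`, `groups.tsv`,
#' `kdp.txt`, `ds.tsv` and `truth.json` (module members and true-DE set)
#' into a directory, the file dialects the readers in this package
#' expect.
#'
#' @param bench a [generateBenchmark()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBenchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePPIEdgeList(bench$network, file.path(dir, "network.tsv"))
  X <- SummarizedExperiment::assay(bench$expression, "abundance")
  utils::write.table(
    data.frame(protein = rownames(X), X, check.names = FALSE),
    file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  grp <- SummarizedExperiment::colData(bench$expression)
  utils::write.table(
    data.frame(sample = rownames(grp), group = as.character(grp$group)),
    file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeLines(bench$diseaseProteins, file.path(dir, "kdp.txt"))
  utils::write.table(bench$dsTable, file.path(dir, "ds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(diseaseProteins = bench$diseaseProteins, trueDe = bench$trueDe),
    file.path(dir, "truth.json"))
  invisible(dir)
}
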