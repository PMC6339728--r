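#' Build an initial protein set (seed) on the network
#'
#' The three seed kinds used for ranking:
#' \describe{
#'   \item{KDP}{the known disease proteins themselves;}
#'   \item{DEP}{the differentially expressed proteins;}
#'   \item{eKDP}{the KDPs expanded with every DEP that is a direct
#'     network neighbor of at least one KDP ("directly linked" means
#'     strictly distance 1 -- no multi-hop expansion).}
#' }
#' For eKDP seeds, each included DEP records which KDP neighbors justify
#' its membership (its provenance), which the leave-one-out holdout rule
#' needs. A protein that is both a KDP and a DEP is stored once, as a
#' KDP.
#'
#' @param kind `"KDP"`, `"DEP"` or `"eKDP"`.
#' @param kdps character vector of known disease proteins, already
#'   restricted to network nodes (see [restrictToNetwork()]).
#' @param deps character vector of DEP identifiers, already restricted to
#'   network nodes.
#' @param net a [PPINetwork-class].
#' @return a [SeedSet-class].
#' @examples
#' net <- edgelistToNetwork(rbind(c("K", "D"), c("D", "X")))
#' seedMembers(buildSeed("eKDP", "K", c("D", "X"), net))  # K and D only
#' @export
buildSeed <- function(kind = c("KDP", "DEP", "eKDP"), kdps, deps, net) {
  kind <- match.arg(kind)
  stopifnot(methods::is(net, "PPINetwork"))
  nodes <- networkNodes(net)
  kdps <- unique(normalizeProteinIds(kdps))
  deps <- unique(normalizeProteinIds(deps))
  if (!all(kdps %in% nodes) || !all(deps %in% nodes))
    stop("seed inputs must be restricted to network nodes first")
  members <- switch(kind, KDP = kdps, DEP = deps, eKDP = kdps)
  provenance <- list()
  if (kind == "eKDP") {
    candidates <- setdiff(deps, kdps)
    if (length(candidates) && length(kdps)) {
      nbrs <- igraph::adjacent_vertices(net@graph, candidates)
      provenance <- lapply(nbrs, function(v) intersect(names(v), kdps))
      names(provenance) <- candidates
      provenance <- provenance[vapply(provenance, length, 1L) > 0L]
    }
    members <- c(kdps, names(provenance))
  }
  if (length(members) == 0L)
    stop("resulting seed set is empty")
  methods::new("SeedSet", kind = kind, members = members,
               provenance = provenance)
}

#' Apply the leave-one-out seed-exclusion rule
#'
#' When a known disease protein (KDP) is held out for testing, it must
#' not inform the training seed: the held-out protein is removed and, for
#' an eKDP seed, so is every DEP member whose inclusion was justified
#' only by adjacency to the held-out KDP. A DEP that also neighbors a
#' retained KDP keeps its place, since that attribution is legitimate
#' training signal.
#'
#' @param seed a [SeedSet-class].
#' @param heldOut protein identifier being held out; if absent from the
#'   seed, the seed is returned unchanged.
#' @return a [SeedSet-class].
#' @export
holdoutSeed <- function(seed, heldOut) {
  stopifnot(methods::is(seed, "SeedSet"), length(heldOut) == 1L)
  heldOut <- normalizeProteinIds(heldOut)
  if (!heldOut %in% seed@members) return(seed)
  members <- setdiff(seed@members, heldOut)
  provenance <- seed@provenance
  if (seed@kind == "eKDP" && length(provenance)) {
    provenance[[heldOut]] <- NULL
    provenance <- lapply(provenance, setdiff, heldOut)
    orphaned <- names(provenance)[vapply(provenance, length, 1L) == 0L]
    provenance <- provenance[setdiff(names(provenance), orphaned)]
    members <- setdiff(members, orphaned)
  }
  methods::new("SeedSet", kind = seed@kind, members = members,
               provenance = provenance)
}

#' Serialize a seed set to newline-delimited text
#'
#' Writes a one-line `#` header recording the kind and the number of
#' provenance-attributed DEP members, followed by one member per line.
#'
#' @param seed a [SeedSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSeedSet <- function(seed, path) {
  stopifnot(methods::is(seed, "SeedSet"))
  header <- sprintf("# kind=%s members=%d provenance_deps=%d",
                    seed@kind, length(seed@members),
                    length(seed@provenance))
  writeLines(c(header, seed@members), path)
  invisible(path)
}
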