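#' @include AllClasses.R
NULL

#' Accessors for PPINetwork
#'
#' `networkNodes()` returns the protein identifiers; `networkEdges()` a
#' two-column character matrix of unordered edges; `nodeDegrees()` the
#' named degree vector; `numNodes()`/`numEdges()` the counts;
#' `averageDegree()` is 2·edges/nodes; `adjacencyMatrix()` the sparse
#' symmetric 0/1 adjacency; `droppedRecords()` the duplicate/self-loop
#' counts removed at construction.
#'
#' @param object a [PPINetwork-class].
#' @return see individual descriptions.
#' @name PPINetwork-accessors
#' @aliases networkNodes networkEdges nodeDegrees numNodes numEdges
#'   averageDegree adjacencyMatrix droppedRecords
#' @examples
#' net <- edgelistToNetwork(cbind(c("a", "b"), c("b", "c")))
#' networkNodes(net)
#' nodeDegrees(net)
NULL

#' @rdname PPINetwork-accessors
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname PPINetwork-accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname PPINetwork-accessors
#' @export
setGeneric("nodeDegrees", function(object) standardGeneric("nodeDegrees"))

#' @rdname PPINetwork-accessors
#' @export
setGeneric("numNodes", function(object) standardGeneric("numNodes"))

#' @rdname PPINetwork-accessors
#' @export
setGeneric("numEdges", function(object) standardGeneric("numEdges"))

#' @rdname PPINetwork-accessors
#' @export
setGeneric("averageDegree", function(object) standardGeneric("averageDegree"))

#' @rdname PPINetwork-accessors
#' @export
setGeneric("adjacencyMatrix", function(object) standardGeneric("adjacencyMatrix"))

#' @rdname PPINetwork-accessors
#' @export
setGeneric("droppedRecords", function(object) standardGeneric("droppedRecords"))

#' @rdname PPINetwork-accessors
setMethod("networkNodes", "PPINetwork", function(object)
  igraph::V(object@graph)$name)

#' @rdname PPINetwork-accessors
setMethod("networkEdges", "PPINetwork", function(object) {
  el <- igraph::as_edgelist(object@graph, names = TRUE)
  mode(el) <- "character"
  colnames(el) <- c("protein1", "protein2")
  el
})

#' @rdname PPINetwork-accessors
setMethod("nodeDegrees", "PPINetwork", function(object)
  igraph::degree(object@graph))

#' @rdname PPINetwork-accessors
setMethod("numNodes", "PPINetwork", function(object)
  as.integer(igraph::vcount(object@graph)))

#' @rdname PPINetwork-accessors
setMethod("numEdges", "PPINetwork", function(object)
  as.integer(igraph::ecount(object@graph)))

#' @rdname PPINetwork-accessors
setMethod("averageDegree", "PPINetwork", function(object)
  2 * numEdges(object) / numNodes(object))

#' @rdname PPINetwork-accessors
setMethod("adjacencyMatrix", "PPINetwork", function(object) {
  A <- igraph::as_adjacency_matrix(object@graph, sparse = TRUE)
  methods::as(A, "CsparseMatrix")
})

#' @rdname PPINetwork-accessors
setMethod("droppedRecords", "PPINetwork", function(object) object@dropped)

setMethod("show", "PPINetwork", function(object) {
  iso <- sum(nodeDegrees(object) == 0)
  cat(sprintf("PPINetwork: %d proteins, %d interactions (average degree %.2f)\n",
              numNodes(object), numEdges(object), averageDegree(object)))
  d <- droppedRecords(object)
  if (any(d > 0))
    cat(sprintf("  dropped at construction: %d duplicate, %d self-loop record(s)\n",
                d[["duplicate"]], d[["self_loop"]]))
  if (iso > 0)
    cat(sprintf("  note: %d isolated (degree-0) protein(s)\n", iso))
})

#' Accessors for SeedSet and ScoreVector
#'
#' `seedKind()` returns the seed kind (`"KDP"`, `"DEP"` or `"eKDP"`),
#' `seedMembers()` the member identifiers, and `seedProvenance()` the
#' DEP -> adjacent-KDP attribution map of an eKDP seed. `scores()`
#' returns the named score vector and `scoreMethod()` the scoring method
#' of a [ScoreVector-class].
#'
#' @param object a [SeedSet-class] or [ScoreVector-class].
#' @name seed-accessors
#' @aliases seedKind seedMembers seedProvenance scores scoreMethod
NULL

#' @rdname seed-accessors
#' @export
setGeneric("seedKind", function(object) standardGeneric("seedKind"))

#' @rdname seed-accessors
#' @export
setGeneric("seedMembers", function(object) standardGeneric("seedMembers"))

#' @rdname seed-accessors
#' @export
setGeneric("seedProvenance", function(object) standardGeneric("seedProvenance"))

#' @rdname seed-accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @rdname seed-accessors
#' @export
setGeneric("scoreMethod", function(object) standardGeneric("scoreMethod"))

#' @rdname seed-accessors
setMethod("seedKind", "SeedSet", function(object) object@kind)

#' @rdname seed-accessors
setMethod("seedMembers", "SeedSet", function(object) object@members)

#' @rdname seed-accessors
setMethod("seedProvenance", "SeedSet", function(object) object@provenance)

#' @rdname seed-accessors
setMethod("seedKind", "ScoreVector", function(object) object@seedKind)

#' @rdname seed-accessors
setMethod("scores", "ScoreVector", function(object) object@scores)

#' @rdname seed-accessors
setMethod("scoreMethod", "ScoreVector", function(object) object@method)

setMethod("show", "SeedSet", function(object) {
  cat(sprintf("SeedSet (%s): %d member(s)\n", object@kind,
              length(object@members)))
  if (object@kind == "eKDP")
    cat(sprintf("  %d DEP member(s) attributed to adjacent KDPs\n",
                length(object@provenance)))
})

setMethod("show", "ScoreVector", function(object) {
  cat(sprintf("ScoreVector: %s scores from a %s seed over %d proteins\n",
              object@method, object@seedKind, length(object@scores)))
  top <- utils::head(sort(object@scores, decreasing = TRUE), 3)
  cat("  top scores:", paste(sprintf("%s=%.4g", names(top), top),
                             collapse = ", "), "\n")
})

#' @rdname rocAuc
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))

#' @rdname rocAuc
setMethod("auc", "RocCurve", function(object) object@auc)

#' @rdname loocv
setMethod("auc", "LoocvResult", function(object) object@auc)

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d threshold(s), AUC = %.4f\n",
              length(object@thresholds), object@auc))
})

setMethod("show", "LoocvResult", function(object) {
  it <- object@iterations
  cat(sprintf("LoocvResult: %s method, %s seed\n", object@method,
              object@seedKind))
  cat(sprintf("  %d iteration(s), %d pooled scores, pooled AUC = %.4f\n",
              length(unique(it$iteration)), nrow(it), object@auc))
  if (length(object@skipped))
    cat(sprintf("  skipped (empty training seed): %s\n",
                paste(object@skipped, collapse = ", ")))
})
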