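#' @import methods
#' @importFrom igraph V E degree is_simple is_directed vcount ecount
NULL

#' PPINetwork: a simple undirected protein-protein interaction network
#'
#' Thin S4 wrapper around an undirected simple \pkg{igraph} graph whose
#' vertex names are case-normalized protein identifiers. Construction (see
#' [readPPIEdgeList()]) removes duplicate and self-linked interactions;
#' isolated (degree-0) nodes are retained but flagged by [show()].
#'
#' @slot graph an undirected simple `igraph` object with named vertices.
#' @slot dropped named integer vector with counts of `duplicate` and
#'   `self_loop` records removed during construction.
#'
#' @seealso [readPPIEdgeList()], [networkNodes()], [nodeDegrees()],
#'   [adjacencyMatrix()], [transitionOperator()]
#' @export
setClass("PPINetwork",
  representation(graph = "ANY", dropped = "integer"),
  prototype(dropped = c(duplicate = 0L, self_loop = 0L))
)

setValidity("PPINetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("slot 'graph' must be an igraph object")
  if (igraph::is_directed(g)) return("network must be undirected")
  if (!igraph::is_simple(g)) return("network must be simple (no loops or multi-edges)")
  nm <- igraph::V(g)$name
  if (is.null(nm) || anyNA(nm)) return("all vertices must be named")
  if (anyDuplicated(nm)) return("vertex names must be unique")
  TRUE
})

#' SeedSet: an initial protein set for network ranking
#'
#' The three seed kinds mirror the prioritization strategies: `"KDP"`
#' (known disease proteins), `"DEP"` (differentially expressed proteins),
#' and `"eKDP"` (KDPs expanded with their direct-neighbor DEPs). For
#' `"eKDP"` seeds, `provenance` records, for every DEP member, which KDP
#' neighbors justify its inclusion; the leave-one-out holdout rule
#' ([holdoutSeed()]) uses it to drop DEPs attributable only to the
#' held-out KDP.
#'
#' @slot kind one of `"KDP"`, `"DEP"`, `"eKDP"`.
#' @slot members character vector of protein identifiers (unique).
#' @slot provenance named list: DEP member -> character vector of adjacent
#'   KDP members (non-empty only for `kind = "eKDP"`).
#'
#' @seealso [buildSeed()], [holdoutSeed()]
#' @export
setClass("SeedSet",
  representation(kind = "character", members = "character",
                 provenance = "list"),
  prototype(kind = "KDP", members = character(), provenance = list())
)

setValidity("SeedSet", function(object) {
  if (length(object@kind) != 1L || !object@kind %in% c("KDP", "DEP", "eKDP"))
    return("kind must be one of 'KDP', 'DEP', 'eKDP'")
  if (anyDuplicated(object@members))
    return("seed members must be unique")
  if (length(object@provenance)) {
    if (object@kind != "eKDP")
      return("provenance is only meaningful for eKDP seeds")
    if (is.null(names(object@provenance)) ||
        !all(names(object@provenance) %in% object@members))
      return("provenance names must be seed members")
    if (any(!vapply(object@provenance, length, 1L)))
      return("provenance entries must be non-empty")
  }
  TRUE
})

#' ScoreVector: per-protein ranking scores
#'
#' Holds one score per network node, together with the scoring method
#' (`"LR"` local neighbor counting or `"GR"` heat-kernel diffusion) and
#' the seed kind that produced it.
#'
#' @slot scores named numeric vector, one entry per network node.
#' @slot method `"LR"` or `"GR"`.
#' @slot seedKind seed kind the scores were computed from.
#'
#' @seealso [grScores()], [lrScores()], [rankProteins()]
#' @export
setClass("ScoreVector",
  representation(scores = "numeric", method = "character",
                 seedKind = "character")
)

setValidity("ScoreVector", function(object) {
  if (is.null(names(object@scores)) || anyDuplicated(names(object@scores)))
    return("scores must be uniquely named by protein")
  if (!object@method %in% c("LR", "GR"))
    return("method must be 'LR' or 'GR'")
  if (any(object@scores < 0)) return("scores must be non-negative")
  TRUE
})

#' RocCurve: receiver-operating characteristic of a score/label set
#'
#' @slot thresholds score thresholds of the sweep (decreasing).
#' @slot tpr,fpr true/false positive rates at each threshold, including
#'   the (0,0) and (1,1) endpoints.
#' @slot auc area under the curve, computed by the tie-corrected rank
#'   (Mann-Whitney) statistic: P(score_pos > score_neg) + P(tie)/2.
#'
#' @seealso [rocAuc()]
#' @export
setClass("RocCurve",
  representation(thresholds = "numeric", tpr = "numeric", fpr = "numeric",
                 auc = "numeric")
)

setValidity("RocCurve", function(object) {
  if (length(object@tpr) != length(object@fpr))
    return("tpr and fpr must have equal length")
  if (is.unsorted(object@tpr) || is.unsorted(object@fpr))
    return("tpr and fpr must be non-decreasing along the curve")
  if (object@auc < 0 || object@auc > 1) return("auc must be in [0, 1]")
  TRUE
})

#' LoocvResult: pooled leave-one-out cross-validation outcome
#'
#' Each iteration holds out one known disease protein (KDP), rebuilds the
#' training seed from the rest, scores the network, and records the score
#' of the held-out positive against `nNeg` randomly sampled non-KDP
#' negatives. Scores are pooled over iterations into a single ROC.
#'
#' @slot iterations data.frame with one row per scored test protein:
#'   `iteration`, `heldOut`, `protein`, `score`, `label` (1 = held-out
#'   KDP, 0 = sampled negative).
#' @slot auc pooled AUC.
#' @slot perIterationAuc numeric vector of per-iteration AUCs (secondary
#'   summary; the pooled AUC is the headline metric).
#' @slot method,seedKind scoring method and seed kind evaluated.
#' @slot rngSeed integer seed that makes the negative sampling
#'   reproducible.
#' @slot skipped character vector of KDPs whose iteration was skipped
#'   (empty training seed).
#'
#' @seealso [loocv()], [rocAuc()]
#' @export
setClass("LoocvResult",
  representation(iterations = "data.frame", auc = "numeric",
                 perIterationAuc = "numeric", method = "character",
                 seedKind = "character", rngSeed = "integer",
                 skipped = "character")
)

setValidity("LoocvResult", function(object) {
  need <- c("iteration", "heldOut", "protein", "score", "label")
  if (!all(need %in% names(object@iterations)))
    return(paste("iterations must have columns:", paste(need, collapse = ", ")))
  if (!all(object@iterations$label %in% c(0, 1)))
    return("labels must be 0/1")
  TRUE
})
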