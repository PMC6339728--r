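#' Diffusion configuration for Global Ranking
#'
#' The discrete heat-kernel diffusion has two hyperparameters: the
#' diffusion rate `alpha` and the iteration count `nIter` (the number of
#' discrete steps approximating exp(-alpha L)). The defaults
#' `alpha = 0.5`, `nIter = 3` are the settings the method was developed
#' with. The constraint `alpha / nIter <= 1` keeps the one-step operator
#' `(1 - alpha/nIter) I + (alpha/nIter) W` non-negative, so scores can
#' never go negative.
#'
#' @param alpha diffusion rate, > 0.
#' @param nIter number of discrete diffusion steps, positive integer.
#' @return a validated list with elements `alpha` and `nIter`.
#' @export
diffusionConfig <- function(alpha = 0.5, nIter = 3L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            length(nIter) == 1L, nIter == as.integer(nIter), nIter >= 1L)
  if (alpha / nIter > 1)
    stop("alpha/nIter must be <= 1 to keep the propagation operator non-negative")
  list(alpha = alpha, nIter = as.integer(nIter))
}

#' Random-walk transition operator W = D^-1 A
#'
#' Row-normalized adjacency: the row of a degree-d node assigns
#' probability 1/d to each neighbor. Degree-0 nodes get an all-zero row
#' (their seed mass decays instead of propagating), which is the
#' degenerate-degree convention used throughout the diffusion.
#'
#' @param net a [PPINetwork-class].
#' @return sparse `dgCMatrix` with rows and columns named by protein.
#' @export
transitionOperator <- function(net) {
  stopifnot(methods::is(net, "PPINetwork"))
  A <- adjacencyMatrix(net)
  d <- nodeDegrees(net)[rownames(A)]
  inv <- ifelse(d > 0, 1 / d, 0)
  W <- methods::as(Matrix::Diagonal(x = inv) %*% A, "CsparseMatrix")
  dimnames(W) <- dimnames(A)
  W
}

# One heat-kernel diffusion: p0 (row vector) times M^N with
# M = (1 - alpha/N) I + (alpha/N) W, as N successive vector-operator
# products. Equivalent to p0 (I - (alpha/N) L)^N with L = I - W.
.grDiffuse <- function(W, p0, alpha, nIter) {
  step <- alpha / nIter
  p <- p0
  for (i in seq_len(nIter)) {
    p <- (1 - step) * p + step * as.numeric(p %*% W)
  }
  p
}

#' Global Ranking: heat-kernel diffusion scores
#'
#' Diffuses a binary seed indicator over the network with the discrete
#' heat-kernel operator built from the random-walk Laplacian L = I - W,
#' W = D^-1 A. The initial vector p0 has 1 on seed members and 0
#' elsewhere (it is deliberately not normalized; ranking is
#' scale-invariant). The score vector is
#' p0 ((1 - alpha/N) I + (alpha/N) W)^N, computed as N successive
#' vector-operator products so the dense matrix power is never formed.
#'
#' On graphs with no isolated node the operator is row-stochastic, so
#' total score mass equals the seed size exactly.
#'
#' @param net a [PPINetwork-class].
#' @param seed a [SeedSet-class] with members in the network (an empty
#'   seed yields all-zero scores with a warning, so leave-one-out loops
#'   stay robust).
#' @param cfg a [diffusionConfig()] list.
#' @param W optional precomputed [transitionOperator()] for `net`,
#'   to amortize construction across many calls.
#' @return a [ScoreVector-class] with `method = "GR"`.
#' @examples
#' net <- edgelistToNetwork(rbind(c("A", "B")))
#' seed <- buildSeed("KDP", "A", character(), net)
#' scores(grScores(net, seed))  # (35/54, 19/54) at the defaults
#' @export
grScores <- function(net, seed, cfg = diffusionConfig(), W = NULL) {
  stopifnot(methods::is(net, "PPINetwork"), methods::is(seed, "SeedSet"))
  if (is.null(W)) W <- transitionOperator(net)
  nodes <- rownames(W)
  if (!all(seed@members %in% nodes))
    stop("seed members must all be network nodes")
  p0 <- stats::setNames(as.numeric(nodes %in% seed@members), nodes)
  if (length(seed@members) == 0L) {
    warning("empty seed set: all GR scores are zero")
    p <- p0
  } else {
    p <- .grDiffuse(W, p0, cfg$alpha, cfg$nIter)
  }
  methods::new("ScoreVector", scores = stats::setNames(p, nodes),
               method = "GR", seedKind = seed@kind)
}

#' Local Ranking: direct-neighbor seed counts
#'
#' Guilt-by-association scoring: each protein's score is the number of
#' seed members among its direct neighbors. Seed members are scored like
#' any other node (a seed protein gets no credit for itself, only for
#' seed neighbors).
#'
#' @inheritParams grScores
#' @param A optional precomputed [adjacencyMatrix()] for `net`.
#' @return a [ScoreVector-class] with `method = "LR"` and integer-valued
#'   scores.
#' @export
lrScores <- function(net, seed, A = NULL) {
  stopifnot(methods::is(net, "PPINetwork"), methods::is(seed, "SeedSet"))
  if (is.null(A)) A <- adjacencyMatrix(net)
  nodes <- rownames(A)
  if (!all(seed@members %in% nodes))
    stop("seed members must all be network nodes")
  ind <- as.numeric(nodes %in% seed@members)
  counts <- as.numeric(A %*% ind)
  methods::new("ScoreVector", scores = stats::setNames(counts, nodes),
               method = "LR", seedKind = seed@kind)
}

#' Rank proteins by score
#'
#' Orders proteins by decreasing score; ties break lexicographically by
#' identifier (C locale) so rankings are fully deterministic. Ranks are
#' 1-based and consecutive in the tie-broken order.
#'
#' @param sv a [ScoreVector-class].
#' @param exclude identifiers to omit from the ranked list (e.g. the
#'   seed members, when only novel candidates are wanted).
#' @param seed optional [SeedSet-class] used to populate the `inSeed`
#'   column (defaults to all `FALSE` when absent).
#' @return data.frame with columns `rank`, `protein`, `score`, `inSeed`.
#' @export
rankProteins <- function(sv, exclude = character(), seed = NULL) {
  stopifnot(methods::is(sv, "ScoreVector"))
  s <- scores(sv)
  exclude <- normalizeProteinIds(exclude)
  s <- s[!names(s) %in% exclude]
  ord <- order(-s, names(s), method = "radix")
  s <- s[ord]
  inSeed <- if (is.null(seed)) rep(FALSE, length(s)) else
    names(s) %in% seedMembers(seed)
  data.frame(rank = seq_along(s), protein = names(s), score = unname(s),
             inSeed = inSeed, stringsAsFactors = FALSE, row.names = NULL)
}
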