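#' ROC curve and AUC from pooled scores and labels
#'
#' The AUC is computed by the tie-corrected rank (Mann-Whitney)
#' formulation, AUC = P(score_pos > score_neg) + P(tie)/2, and the curve
#' points come from a threshold sweep over the distinct scores. The
#' trapezoidal integral of the curve equals the rank statistic (a
#' property the test suite asserts to 1e-12).
#'
#' @param scoreValues numeric vector of predictor scores.
#' @param labels 0/1 (or logical) vector, 1 = positive; at least one of
#'   each class is required.
#' @return a [RocCurve-class].
#' @examples
#' auc(rocAuc(c(3, 2, 1), c(1, 0, 0)))  # 1: perfect separation
#' @export
rocAuc <- function(scoreValues, labels) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  stopifnot(length(scoreValues) == length(labels), !anyNA(scoreValues),
            !anyNA(labels))
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both a positive and a negative label are required")
  r <- rank(scoreValues)  # midranks handle ties
  aucValue <- (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  ord <- order(scoreValues, decreasing = TRUE)
  s <- scoreValues[ord]; l <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tie block
  tpr <- c(0, cumsum(l)[last] / nPos)
  fpr <- c(0, cumsum(1 - l)[last] / nNeg)
  methods::new("RocCurve", thresholds = s[last], tpr = tpr, fpr = fpr,
               auc = aucValue)
}

#' Leave-one-out cross-validation of a ranking strategy
#'
#' Each known disease protein (KDP) is held out in turn. The training
#' seed is rebuilt from the remaining KDPs via the holdout rule (for
#' eKDP seeds, DEPs attributable only to the held-out KDP are also
#' dropped; see [holdoutSeed()]), the whole network is scored, and the
#' held-out KDP competes against `nNeg` negatives sampled uniformly
#' without replacement from the non-KDP network nodes. Scores from all
#' iterations are pooled into one ROC; per-iteration AUCs are kept as a
#' secondary summary.
#'
#' Negative sampling in iteration i uses RNG seed `rngSeed + i`, so runs
#' are bit-reproducible and iterations are independently seeded.
#'
#' @param net a [PPINetwork-class].
#' @param kdps KDP identifiers, already restricted to the network.
#' @param deps DEP identifiers restricted to the network (needed for
#'   `"DEP"`/`"eKDP"` seeds; may be empty for `"KDP"`).
#' @param seedKind `"KDP"`, `"DEP"` or `"eKDP"`.
#' @param method `"GR"` (heat-kernel diffusion) or `"LR"` (neighbor
#'   counting).
#' @param cfg [diffusionConfig()] for the GR method.
#' @param nNeg negatives per iteration (default 99, the 1-vs-99 design).
#' @param rngSeed integer seed.
#' @return a [LoocvResult-class].
#' @export
loocv <- function(net, kdps, deps = character(),
                  seedKind = c("KDP", "DEP", "eKDP"),
                  method = c("GR", "LR"), cfg = diffusionConfig(),
                  nNeg = 99L, rngSeed = 1L) {
  seedKind <- match.arg(seedKind)
  method <- match.arg(method)
  stopifnot(methods::is(net, "PPINetwork"))
  nodes <- networkNodes(net)
  kdps <- unique(normalizeProteinIds(kdps))
  deps <- unique(normalizeProteinIds(deps))
  if (!all(kdps %in% nodes)) stop("kdps must be restricted to the network")
  candidates <- setdiff(nodes, kdps)
  if (length(candidates) < nNeg)
    stop("not enough non-KDP nodes to sample ", nNeg, " negatives")
  fullSeed <- buildSeed(seedKind, kdps, deps, net)
  W <- if (method == "GR") transitionOperator(net) else NULL
  A <- if (method == "LR") adjacencyMatrix(net) else NULL
  rows <- vector("list", length(kdps))
  perIter <- rep(NA_real_, length(kdps))
  skipped <- character()
  for (i in seq_along(kdps)) {
    k <- kdps[i]
    trainSeed <- holdoutSeed(fullSeed, k)
    if (length(seedMembers(trainSeed)) == 0L) {
      skipped <- c(skipped, k)
      next
    }
    set.seed(rngSeed + i)
    negs <- sample(candidates, nNeg)
    sv <- if (method == "GR") grScores(net, trainSeed, cfg, W = W)
          else lrScores(net, trainSeed, A = A)
    test <- c(k, negs)
    sc <- scores(sv)[test]
    lab <- c(1L, rep(0L, nNeg))
    perIter[i] <- auc(rocAuc(sc, lab))
    rows[[i]] <- data.frame(iteration = i, heldOut = k, protein = test,
                            score = unname(sc), label = lab,
                            stringsAsFactors = FALSE)
  }
  if (length(skipped))
    message(length(skipped), " iteration(s) skipped (empty training seed)")
  pooled <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(pooled)) stop("no LOOCV iteration could be evaluated")
  methods::new("LoocvResult", iterations = pooled,
               auc = auc(rocAuc(pooled$score, pooled$label)),
               perIterationAuc = perIter[!is.na(perIter)],
               method = method, seedKind = seedKind,
               rngSeed = as.integer(rngSeed), skipped = skipped)
}

#' Count known disease proteins recovered in the top k of a ranking
#'
#' @param ranking data.frame from [rankProteins()] (ordered by rank).
#' @param kdps character vector of KDP identifiers.
#' @param ks cutoffs to evaluate (default 10, 20, 50, 100, 200).
#' @return named integer vector, one count per cutoff; counts are
#'   non-decreasing in k. Cutoffs beyond the list length count over the
#'   available entries, with a warning.
#' @export
topkRecovery <- function(ranking, kdps, ks = c(10L, 20L, 50L, 100L, 200L)) {
  stopifnot(is.data.frame(ranking), "protein" %in% names(ranking))
  kdps <- normalizeProteinIds(kdps)
  if (any(ks > nrow(ranking)))
    warning("cutoff(s) exceed ranking length; counting over available entries")
  hits <- cumsum(ranking$protein %in% kdps)
  counts <- vapply(ks, function(k) {
    k <- min(k, nrow(ranking))
    if (k == 0L) 0L else hits[k]
  }, integer(1))
  stats::setNames(counts, paste0("top", ks))
}

#' Mean DEP linkage of disease proteins versus random controls
#'
#' Measures how many differentially expressed proteins (DEPs) a disease
#' protein touches on average: the mean over KDPs of the number of DEP
#' direct neighbors, compared against the same statistic on equally
#' sized sets of non-KDP proteins sampled uniformly at random. The
#' empirical permutation p-value is the fraction of control sets whose
#' mean reaches the KDP mean (with the +1 correction).
#'
#' @param net a [PPINetwork-class].
#' @param kdps KDP identifiers (network-restricted).
#' @param deps DEP identifiers (network-restricted).
#' @param nRandom number of random control sets (default 100).
#' @param rngSeed integer seed.
#' @return list with `meanKdpLinks`, `meanRandomLinks` (mean of control
#'   means), `controlMeans`, and `p`.
#' @export
kdpDepLinkage <- function(net, kdps, deps, nRandom = 100L, rngSeed = 1L) {
  stopifnot(methods::is(net, "PPINetwork"))
  nodes <- networkNodes(net)
  kdps <- unique(normalizeProteinIds(kdps))
  deps <- unique(normalizeProteinIds(deps))
  stopifnot(all(kdps %in% nodes), all(deps %in% nodes))
  pool <- setdiff(nodes, kdps)
  if (length(pool) < length(kdps))
    stop("not enough non-KDP nodes for control sampling")
  A <- adjacencyMatrix(net)
  depLinks <- as.numeric(A %*% as.numeric(nodes %in% deps))
  names(depLinks) <- nodes
  meanKdp <- if (length(kdps)) mean(depLinks[kdps]) else 0
  controls <- vapply(seq_len(nRandom), function(r) {
    set.seed(rngSeed + r)
    mean(depLinks[sample(pool, length(kdps))])
  }, numeric(1))
  list(meanKdpLinks = meanKdp,
       meanRandomLinks = mean(controls),
       controlMeans = controls,
       p = (1 + sum(controls >= meanKdp)) / (nRandom + 1))
}
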