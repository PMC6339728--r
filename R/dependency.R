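#' Read a gene-dependency-score table
#'
#' Tab-delimited with columns protein, lineage, DS (differential
#' dependency score from genome-scale loss-of-function screens; more
#' negative = more essential for that lineage's tumor lines). A header
#' row is accepted.
#'
#' @param path path to the table.
#' @return data.frame with columns `protein`, `lineage`, `ds`.
#' @export
readDependencyTable <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = c("character", "character",
                                          "character"),
                           quote = "", comment.char = "")
  names(tab) <- c("protein", "lineage", "ds")
  if (is.na(suppressWarnings(as.numeric(tab$ds[1L]))))
    tab <- tab[-1L, , drop = FALSE]
  data.frame(protein = normalizeProteinIds(tab$protein),
             lineage = tolower(trimws(tab$lineage)),
             ds = as.numeric(tab$ds), stringsAsFactors = FALSE)
}

#' Classify proteins by tumor-survival essentiality
#'
#' A protein is called `target-lineage-essential` when its dependency
#' score in the target lineage falls below the threshold (default -2,
#' the conventional cutoff for "needed for tumor-line survival");
#' failing that, `other-cancer-essential` when some other lineage's
#' score does; otherwise `none`. Proteins without any record are
#' `unknown`. When a lineage has multiple records for one protein (e.g.
#' several cell lines), the minimum (most essential) score represents
#' the lineage.
#'
#' @param records data.frame with columns `protein`, `lineage`, `ds`
#'   (see [readDependencyTable()]).
#' @param targetLineage lineage of interest, e.g. `"colon"`.
#' @param threshold essentiality cutoff on DS (default -2).
#' @param proteins optional identifiers to classify; defaults to the
#'   proteins present in `records`. Identifiers absent from `records`
#'   come back as `unknown`.
#' @param aggregate how to collapse multiple records per
#'   (protein, lineage): `"min"` (default) or `"mean"`.
#' @return data.frame with columns `protein`, `category`.
#' @export
classifyEssentiality <- function(records, targetLineage, threshold = -2,
                                 proteins = NULL,
                                 aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.finite(threshold))
  targetLineage <- tolower(trimws(targetLineage))
  records$protein <- normalizeProteinIds(records$protein)
  records$lineage <- tolower(trimws(records$lineage))
  agg <- stats::aggregate(ds ~ protein + lineage, data = records,
                          FUN = if (aggregate == "min") min else mean)
  if (is.null(proteins)) proteins <- unique(records$protein)
  proteins <- normalizeProteinIds(proteins)
  category <- vapply(proteins, function(p) {
    rec <- agg[agg$protein == p, , drop = FALSE]
    if (nrow(rec) == 0L) return("unknown")
    target <- rec$ds[rec$lineage == targetLineage]
    if (length(target) && any(target < threshold))
      return("target-lineage-essential")
    other <- rec$ds[rec$lineage != targetLineage]
    if (length(other) && any(other < threshold))
      return("other-cancer-essential")
    "none"
  }, character(1))
  data.frame(protein = proteins, category = unname(category),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson chi-square test of essentiality enrichment
#'
#' Compares the essential fraction between two protein groups (e.g. top
#' ranked candidates versus randomly selected candidates) on the 2x2
#' table `[[essentialA, totalA - essentialA], [essentialB, totalB -
#' essentialB]]`, without continuity correction, with the p-value from
#' the chi-square distribution on 1 degree of freedom.
#'
#' @param essentialA,totalA essential count and group size of group A.
#' @param essentialB,totalB essential count and group size of group B.
#' @return list with `chi2` and `p` (both `NA` with a warning when a
#'   marginal of the table is zero, where the statistic is undefined).
#' @examples
#' essentialityChisq(15, 20, 8, 20)  # chi2 = 5.013, p = 0.025
#' @export
essentialityChisq <- function(essentialA, totalA, essentialB, totalB) {
  stopifnot(totalA > 0, totalB > 0, essentialA <= totalA,
            essentialB <= totalB, essentialA >= 0, essentialB >= 0)
  tab <- matrix(c(essentialA, totalA - essentialA,
                  essentialB, totalB - essentialB),
                nrow = 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("chi-square statistic undefined: zero marginal in the table")
    return(list(chi2 = NA_real_, p = NA_real_))
  }
  # the large-sample approximation warning is irrelevant here: the
  # Pearson statistic itself is what this comparison reports
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Random candidate samples for the essentiality control
#'
#' Draws `replicates` uniform samples of `n` proteins without
#' replacement from the candidate list (the control arm of the
#' essentiality comparison). Replicate r uses RNG seed `rngSeed + r`, so
#' results are reproducible.
#'
#' @param candidates character vector of candidate identifiers.
#' @param n sample size per replicate (default 20).
#' @param replicates number of samples (default 10).
#' @param rngSeed integer seed.
#' @return list of character vectors, one per replicate.
#' @export
randomCandidateSample <- function(candidates, n = 20L, replicates = 10L,
                                  rngSeed = 1L) {
  candidates <- unique(normalizeProteinIds(candidates))
  if (n > length(candidates))
    stop("sample size exceeds the number of candidates")
  lapply(seq_len(replicates), function(r) {
    set.seed(rngSeed + r)
    sample(candidates, n)
  })
}

#' Mean essential fraction of random candidate samples
#'
#' Convenience summary for the control arm: classifies each sampled
#' protein and averages the essential fraction (target-lineage or
#' other-cancer essential) across replicates.
#'
#' @param samples list of samples from [randomCandidateSample()].
#' @param records dependency records (see [classifyEssentiality()]).
#' @inheritParams classifyEssentiality
#' @return list with `fractionPerReplicate` and `meanFraction`.
#' @export
essentialFraction <- function(samples, records, targetLineage,
                              threshold = -2) {
  fr <- vapply(samples, function(s) {
    cls <- classifyEssentiality(records, targetLineage, threshold,
                                proteins = s)
    mean(cls$category %in% c("target-lineage-essential",
                             "other-cancer-essential"))
  }, numeric(1))
  list(fractionPerReplicate = fr, meanFraction = mean(fr))
}
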