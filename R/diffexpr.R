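#' Assemble a protein expression dataset
#'
#' Wraps a proteins x samples abundance matrix and its tumor/normal
#' sample labels into a [SummarizedExperiment::SummarizedExperiment]
#' with assay `"abundance"` and a `group` column in `colData`. Abundances
#' are assumed pre-normalized; missing entries (`NA`) are permitted.
#'
#' @param values numeric matrix, proteins in rows (rownames = protein
#'   identifiers, normalized on construction), samples in columns.
#' @param groups character/factor of group labels, one per sample, either
#'   named by sample or in column order.
#' @param tumorLabel,normalLabel the two expected group names.
#' @return a `SummarizedExperiment`.
#' @export
makeExpressionDataset <- function(values, groups, tumorLabel = "tumor",
                                  normalLabel = "normal") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have protein rownames")
  rownames(values) <- normalizeProteinIds(rownames(values))
  if (anyDuplicated(rownames(values))) stop("duplicate protein identifiers")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  if (!is.null(names(groups))) {
    miss <- setdiff(colnames(values), names(groups))
    if (length(miss))
      stop("samples without a group label: ", paste(miss, collapse = ", "))
    groups <- groups[colnames(values)]
  } else if (length(groups) != ncol(values)) {
    stop("one group label per sample is required")
  }
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), c(tumorLabel, normalLabel))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (!all(c(tumorLabel, normalLabel) %in% groups))
    stop("both groups must be non-empty")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values),
    colData = S4Vectors::DataFrame(
      group = factor(groups, levels = c(tumorLabel, normalLabel)),
      row.names = colnames(values)))
}

#' Read an expression matrix and sample-group labels from disk
#'
#' The expression file is tab-delimited with the protein identifier in
#' the first column and a header row of sample identifiers; the group
#' file is two-column tab-delimited (sample, group).
#'
#' @param exprPath path to the expression matrix.
#' @param groupPath path to the sample-group table.
#' @inheritParams makeExpressionDataset
#' @return a `SummarizedExperiment` (see [makeExpressionDataset()]).
#' @export
readExpressionMatrix <- function(exprPath, groupPath, tumorLabel = "tumor",
                                 normalLabel = "normal") {
  expr <- utils::read.table(exprPath, header = TRUE, sep = "\t",
                            row.names = 1L, check.names = FALSE,
                            quote = "", comment.char = "")
  grp <- utils::read.table(groupPath, header = FALSE, sep = "\t",
                           col.names = c("sample", "group"),
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (grp$sample[1L] == "sample") grp <- grp[-1L, , drop = FALSE]
  groups <- stats::setNames(grp$group, grp$sample)
  makeExpressionDataset(as.matrix(expr), groups, tumorLabel, normalLabel)
}

#' Welch's two-sample t-test
#'
#' The unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. Missing values are dropped per
#' vector.
#'
#' @param x,y numeric vectors (tumor and normal abundances).
#' @return named numeric: `t`, `df`, `p`.
#' @examples
#' welchT(c(10, 11, 12, 13), c(1, 2, 3))
#' @export
welchT <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("welchT requires at least 2 non-missing values per group")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0)
    stop("welchT is undefined when both groups have zero variance")
  se2x <- vx / length(x); se2y <- vy / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df <- (se2x + se2y)^2 /
    (se2x^2 / (length(x) - 1L) + se2y^2 / (length(y) - 1L))
  c(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

# Vectorized Welch over matrix rows with per-row complete cases.
.welchRows <- function(X, Y) {
  nx <- rowSums(!is.na(X)); ny <- rowSums(!is.na(Y))
  mx <- rowMeans(X, na.rm = TRUE); my <- rowMeans(Y, na.rm = TRUE)
  # sample variance via centered sums of squares (stable at these scales)
  vx <- rowSums((X - mx)^2, na.rm = TRUE) / pmax(nx - 1, 1)
  vy <- rowSums((Y - my)^2, na.rm = TRUE) / pmax(ny - 1, 1)
  reason <- rep(NA_character_, nrow(X))
  reason[nx < 2 | ny < 2] <- "too_few_observations"
  reason[is.na(reason) & vx == 0 & vy == 0] <- "zero_variance"
  ok <- is.na(reason)
  se2x <- vx / nx; se2y <- vy / ny
  tstat <- df <- p <- rep(NA_real_, nrow(X))
  tstat[ok] <- (mx[ok] - my[ok]) / sqrt(se2x[ok] + se2y[ok])
  df[ok] <- (se2x[ok] + se2y[ok])^2 /
    (se2x[ok]^2 / (nx[ok] - 1) + se2y[ok]^2 / (ny[ok] - 1))
  p[ok] <- 2 * stats::pt(-abs(tstat[ok]), df[ok])
  data.frame(t = tstat, df = df, pRaw = p, nTumor = nx, nNormal = ny,
             reason = reason, stringsAsFactors = FALSE)
}

#' Call differentially expressed proteins (DEPs)
#'
#' Tests every protein for a tumor-vs-normal abundance difference with
#' Welch's t-test and applies a Bonferroni correction over the proteins
#' actually tested; a protein is a DEP when its adjusted p-value falls
#' below `alpha`. Proteins with fewer than 2 non-missing values in either
#' group, or zero variance in both groups, are reported as untestable
#' (`reason` column) and excluded from the correction denominator.
#'
#' @param se a `SummarizedExperiment` from [makeExpressionDataset()].
#' @param alpha significance level on the Bonferroni-adjusted p-value
#'   (default 0.05).
#' @param tumorLabel,normalLabel group names in `colData(se)$group`.
#' @return data.frame with one row per protein: `protein`, `t`, `df`,
#'   `pRaw`, `pAdjusted`, `isDEP`, `nTumor`, `nNormal`, `reason` (NA for
#'   testable proteins). The number of tests `m` is attached as
#'   `attr(, "m")`.
#' @seealso [depProteins()] to extract the DEP identifiers.
#' @export
callDEPs <- function(se, alpha = 0.05, tumorLabel = "tumor",
                     normalLabel = "normal") {
  stopifnot(alpha >= 0, alpha < 1)
  grp <- as.character(SummarizedExperiment::colData(se)$group)
  X <- SummarizedExperiment::assay(se, "abundance")
  tum <- X[, grp == tumorLabel, drop = FALSE]
  nor <- X[, grp == normalLabel, drop = FALSE]
  if (ncol(tum) == 0L || ncol(nor) == 0L)
    stop("both sample groups must be non-empty")
  res <- .welchRows(tum, nor)
  res <- cbind(protein = rownames(X), res, stringsAsFactors = FALSE)
  m <- sum(is.na(res$reason))
  if (m == 0L) stop("no testable proteins")
  res$pAdjusted <- pmin(1, res$pRaw * m)
  res$isDEP <- res$pAdjusted < alpha
  rownames(res) <- NULL
  res <- res[, c("protein", "t", "df", "pRaw", "pAdjusted", "isDEP",
                 "nTumor", "nNormal", "reason")]
  attr(res, "m") <- m
  res
}

#' Extract DEP identifiers from a [callDEPs()] result
#'
#' @param results data.frame returned by [callDEPs()].
#' @return character vector of DEP identifiers.
#' @export
depProteins <- function(results) {
  results$protein[which(results$isDEP)]
}

#' Write a differential-expression results table
#'
#' @param results data.frame from [callDEPs()].
#' @param path output file path (tab-delimited).
#' @return `path`, invisibly.
#' @export
writeDEPTable <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
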