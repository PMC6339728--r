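#' Normalize protein identifiers
#'
#' Gene symbols are case-insensitive in practice (published lists mix
#' "kras" with "KRAS"), so every identifier entering the package is
#' uppercased and stripped of surrounding whitespace before comparison.
#'
#' @param x character vector of raw identifiers.
#' @return normalized character vector.
#' @export
normalizeProteinIds <- function(x) toupper(trimws(as.character(x)))

#' Build a PPINetwork from a raw edge list
#'
#' Applies the network-construction rules: identifiers are normalized,
#' self-linked interactions are dropped, and duplicate records (in either
#' orientation) collapse to a single undirected edge. Endpoints of
#' dropped self-loop records are retained as isolated nodes.
#'
#' @param edges two-column character matrix or data.frame of interaction
#'   records.
#' @param verbose log a construction summary via [message()].
#' @return a [PPINetwork-class].
#' @examples
#' net <- edgelistToNetwork(rbind(c("A", "B"), c("B", "A"), c("C", "C")))
#' numEdges(net)  # 1
#' @export
edgelistToNetwork <- function(edges, verbose = FALSE) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("edge list must have at least 2 columns")
  a <- normalizeProteinIds(edges[, 1L])
  b <- normalizeProteinIds(edges[, 2L])
  keep <- !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b)
  a <- a[keep]; b <- b[keep]
  nodes <- unique(c(a, b))
  self <- a == b
  nSelf <- sum(self)
  # canonical unordered orientation, then drop repeats
  lo <- pmin(a[!self], b[!self])
  hi <- pmax(a[!self], b[!self])
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  nDup <- sum(dup)
  lo <- lo[!dup]; hi <- hi[!dup]
  if (length(lo) == 0L)
    stop("empty graph: no edges remain after removing duplicates and self-loops")
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes))
  net <- methods::new("PPINetwork", graph = g,
                      dropped = c(duplicate = nDup, self_loop = nSelf))
  if (verbose)
    message(sprintf(
      "network: %d nodes, %d edges, average degree %.2f (%d duplicate, %d self-loop record(s) dropped)",
      numNodes(net), numEdges(net), averageDegree(net), nDup, nSelf))
  net
}

#' Read a PPI network from a tab- or whitespace-delimited edge list
#'
#' Reads a two-column (HINT-style) interaction export, removes duplicate
#' and self-linked interactions, and returns a simple undirected
#' [PPINetwork-class]. Extra columns are ignored.
#'
#' A header row is auto-detected by default: if neither cell of the first
#' row reappears as an endpoint anywhere else in the file, the row is
#' treated as a header. Set `header` to `TRUE`/`FALSE` to override.
#'
#' @param path path to the edge-list file.
#' @param columns integer pair selecting the two identifier columns
#'   (default first and second).
#' @param header `NA` (auto-detect, default), `TRUE` or `FALSE`.
#' @param verbose log a construction summary.
#' @return a [PPINetwork-class].
#' @export
readPPIEdgeList <- function(path, columns = c(1L, 2L), header = NA,
                            verbose = TRUE) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  raw <- utils::read.table(path, header = FALSE, sep = "",
                           colClasses = "character", comment.char = "",
                           quote = "", stringsAsFactors = FALSE)
  if (ncol(raw) < max(columns))
    stop("edge list has fewer columns than requested")
  m <- as.matrix(raw[, columns, drop = FALSE])
  if (isTRUE(header)) {
    m <- m[-1L, , drop = FALSE]
  } else if (is.na(header) && nrow(m) > 1L) {
    first <- normalizeProteinIds(m[1L, ])
    rest <- normalizeProteinIds(m[-1L, ])
    if (!any(first %in% rest)) m <- m[-1L, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("empty edge list: ", path)
  edgelistToNetwork(m, verbose = verbose)
}

#' Write a PPINetwork as a two-column tab-delimited edge list
#'
#' @param net a [PPINetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePPIEdgeList <- function(net, path) {
  stopifnot(methods::is(net, "PPINetwork"))
  utils::write.table(networkEdges(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a protein list
#'
#' Parses a plain-text protein list -- newline-delimited by default, or
#' any single-string delimiter such as the semicolons used by published
#' known-disease-protein tables. Identifiers are normalized and
#' deduplicated, preserving first-appearance order.
#'
#' @param path path to the list file.
#' @param delimiter entry separator; `"\n"` (default) or e.g. `";"`.
#' @return character vector of unique, normalized identifiers.
#' @export
readProteinList <- function(path, delimiter = "\n") {
  if (!file.exists(path)) stop("cannot read protein list: ", path)
  txt <- readLines(path, warn = FALSE)
  if (!identical(delimiter, "\n"))
    txt <- unlist(strsplit(txt, delimiter, fixed = TRUE))
  ids <- normalizeProteinIds(txt)
  ids <- unique(ids[nzchar(ids) & !is.na(ids)])
  if (length(ids) == 0L) stop("protein list is empty after parsing: ", path)
  ids
}

#' Packaged known-disease-protein lists
#'
#' Returns the packaged transcription of the curated known disease
#' proteins (KDPs) that are present in the interaction network: 39
#' colorectal-cancer proteins or 28 breast-cancer proteins. The lists are
#' transcribed verbatim from their published form (including ambiguous
#' symbols such as "cds1") and normalized on load.
#'
#' @param disease `"crc"` (colorectal) or `"bc"` (breast).
#' @return character vector of protein identifiers.
#' @examples
#' length(knownDiseaseProteins("crc"))  # 39
#' @export
knownDiseaseProteins <- function(disease = c("crc", "bc")) {
  disease <- match.arg(disease)
  f <- system.file("extdata",
                   paste0(disease, "_known_proteins.txt"),
                   package = "ppiRank", mustWork = TRUE)
  readProteinList(f, delimiter = ";")
}

#' Restrict a protein list to network nodes
#'
#' Keeps only the list members that exist as nodes of the network (the
#' usual first step after loading a curated disease list: only proteins
#' covered by the interactome can be ranked).
#'
#' @param proteins character vector of identifiers (normalized or not).
#' @param net a [PPINetwork-class].
#' @param verbose log retained/dropped counts.
#' @return character vector of retained members, original order.
#' @export
restrictToNetwork <- function(proteins, net, verbose = TRUE) {
  stopifnot(methods::is(net, "PPINetwork"))
  ids <- unique(normalizeProteinIds(proteins))
  keep <- ids[ids %in% networkNodes(net)]
  if (verbose)
    message(sprintf("restricted protein list: %d of %d member(s) found in the network",
                    length(keep), length(ids)))
  if (length(keep) == 0L)
    warning("no list member is present in the network")
  keep
}
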