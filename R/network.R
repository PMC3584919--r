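#' Build the weighted network of reciprocal matches
#'
#' Runs the template/match/filter/reciprocity machinery over *all*
#' unordered pairs of the given chains -- the query-query,
#' query-target and target-target parts of the network -- and keeps
#' one undirected edge per reciprocal pair, carrying the
#' minimum-RMSD significant match's (rmsd, ETScore). Edge weights are
#' then derived via [networkFromEdges()].
#'
#' @inheritParams runMode
#' @param annotations known labels attached to the nodes (pass a
#'   table without the query entries to treat them as unknown).
#' @param weightTransform mapping from the standardized edge score
#'   `s` to a non-negative weight: `"exp"` (default, `exp(-s)`),
#'   `"relu"` (`max(0, -s)`) or `"unit"` (all 1).
#' @return a [MatchNetwork-class].
#' @export
buildNetwork <- function(dataset, queries = chainIds(dataset),
                         targets = chainIds(dataset),
                         mode = c("6R", "5R", "M6R", "M5R"), model,
                         annotations = dataset@annotations, tol = 2.5,
                         maxRmsd = 2, cap = 1e5, useMsa = FALSE,
                         weightTransform = "exp", ...) {
  mode <- match.arg(mode)
  nodes <- union(queries, targets)
  tmpl <- templateSet(dataset, nodes, mode, useMsa = useMsa, ...)
  sig <- list()
  for (a in nodes) for (b in nodes) {
    if (a >= b) next
    sig <- c(sig,
             significantMatchesFor(dataset, tmpl[[a]], a, b, model,
                                   tol, maxRmsd, cap),
             significantMatchesFor(dataset, tmpl[[b]], b, a, model,
                                   tol, maxRmsd, cap))
  }
  rec <- reciprocalMatches(sig)
  edges <- rec[, c("a", "b", "rmsd", "etScore")]
  networkFromEdges(nodes, edges, annotations,
                   weightTransform = weightTransform)
}

#' Assemble a match network from an edge table
#'
#' Standardizes every edge's (rmsd, ETScore) against the network-wide
#' means and population standard deviations,
#' `s = 1/2[(rmsd - mu_r)/sd_r + (ET - mu_ET)/sd_ET]`, and maps `s`
#' to a non-negative weight. The default transform `exp(-s)` is
#' monotone decreasing in `s`, so better-than-average matches (low
#' rmsd, low ETScore) get weight above 1.
#'
#' @param nodes character node ids (superset of the edge endpoints).
#' @param edges data.frame with columns `a`, `b`, `rmsd`, `etScore`;
#'   self-edges are rejected.
#' @param annotations an [AnnotationTable-class] of known labels
#'   (nodes absent from it are unknown).
#' @param weightTransform `"exp"`, `"relu"` or `"unit"` (see
#'   [buildNetwork()]).
#' @return a [MatchNetwork-class].
#' @export
networkFromEdges <- function(nodes, edges,
                             annotations = annotationTable(),
                             weightTransform = c("exp", "relu", "unit")) {
  weightTransform <- match.arg(weightTransform)
  nodes <- as.character(nodes)
  n <- length(nodes)
  labels <- lapply(nodes, function(id) ecOf(fullEcOnly(annotations), id))
  names(labels) <- nodes
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0L) {
    edges$a <- as.character(edges$a)
    edges$b <- as.character(edges$b)
    if (any(edges$a == edges$b)) stop("self-edges are not allowed")
    if (!all(c(edges$a, edges$b) %in% nodes))
      stop("edge endpoint not among the nodes")
    popSd <- function(x) sqrt(mean((x - mean(x))^2))
    mur <- mean(edges$rmsd); sdr <- popSd(edges$rmsd)
    mue <- mean(edges$etScore); sde <- popSd(edges$etScore)
    if (weightTransform != "unit" && (sdr == 0 || sde == 0))
      stop("zero variance in rmsd or ETScore across network matches; ",
           "use weightTransform = \"unit\" for fixed unit weights")
    if (weightTransform == "unit") {
      edges$s <- 0
      edges$w <- 1
    } else {
      edges$s <- 0.5 * ((edges$rmsd - mur) / sdr +
                          (edges$etScore - mue) / sde)
      edges$w <- switch(weightTransform,
                        exp = exp(-edges$s),
                        relu = pmax(0, -edges$s))
    }
    for (i in seq_len(nrow(edges))) {
      W[edges$a[i], edges$b[i]] <- edges$w[i]
      W[edges$b[i], edges$a[i]] <- edges$w[i]
    }
    stats <- c(muRmsd = mur, sdRmsd = sdr, muEt = mue, sdEt = sde)
  } else {
    edges <- data.frame(a = character(0), b = character(0),
                        rmsd = numeric(0), etScore = numeric(0),
                        s = numeric(0), w = numeric(0))
    stats <- c(muRmsd = NA_real_, sdRmsd = NA_real_,
               muEt = NA_real_, sdEt = NA_real_)
  }
  new("MatchNetwork", nodes = nodes, labels = labels, W = W,
      edges = as.data.frame(edges), stats = stats)
}

#' Write / read a network edge list
#'
#' Tab-separated columns `a b rmsd etScore s w`; the reader rebuilds
#' the network (recomputing `s` and `w` from the stored rmsd/ETScore)
#' given the node set and annotations.
#'
#' @param network a [MatchNetwork-class].
#' @param path file path.
#' @inheritParams networkFromEdges
#' @return the writer returns `path` invisibly; the reader a
#'   [MatchNetwork-class].
#' @export
writeEdgeList <- function(network, path) {
  utils::write.table(network@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path, nodes, annotations = annotationTable(),
                         weightTransform = "exp") {
  edges <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  networkFromEdges(nodes, edges[, c("a", "b", "rmsd", "etScore")],
                   annotations, weightTransform = weightTransform)
}
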