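#' Spatial clusters of evolutionarily important residues
#'
#' At rank coverage `coverage`, the important residues are those whose
#' percentile rank is at most `coverage` (the top fraction by rank).
#' Clusters are the single-linkage components of the important
#' residues under C-alpha distance <= `linkCutoff`: growing the
#' coverage can only grow cluster membership. Clusters are returned
#' most-important first (ascending best surface rank).
#'
#' @param chain a [ProteinChain-class].
#' @param ranks an [ETRanking-class] for the chain.
#' @param surface a [SurfaceAnnotation-class] for the chain.
#' @param coverage rank coverage in (0, 1].
#' @param linkCutoff single-linkage C-alpha distance cutoff in A
#'   (default 8).
#' @return list of [ResidueCluster-class] (possibly empty).
#' @seealso [selectPrimaryCluster()], [selectAdditionalClusters()]
#' @export
identifyClusters <- function(chain, ranks, surface, coverage,
                             linkCutoff = 8) {
  stopifnot(coverage > 0, coverage <= 1, linkCutoff > 0)
  imp <- ranks@resno[ranks@percentile <= coverage]
  imp <- imp[imp %in% chain@resno]
  if (length(imp) == 0L) return(list())
  idx <- match(imp, chain@resno)
  xyz <- chain@coords[idx, , drop = FALSE]
  if (length(imp) == 1L) {
    comp <- 1L
  } else {
    hc <- stats::hclust(stats::dist(xyz), method = "single")
    comp <- stats::cutree(hc, h = linkCutoff)
  }
  clusters <- lapply(split(seq_along(imp), comp), function(i) {
    members <- sort(imp[i])
    surf <- members[which(isSurface(surface, members))]
    best <- if (length(surf)) min(rankOf(ranks, surf)) else Inf
    new("ResidueCluster", members = members, surfaceMembers = surf,
        formationThreshold = coverage, bestRank = best,
        cm = unname(colMeans(chain@coords[match(members, chain@resno), ,
                                          drop = FALSE])))
  })
  ord <- order(vapply(clusters, function(cl) cl@bestRank, numeric(1)),
               vapply(clusters, function(cl) min(cl@members), numeric(1)))
  unname(clusters[ord])
}

#' Select the primary functional-site cluster
#'
#' Sweeps the rank coverage upward in steps of `step` until some
#' cluster holds at least `minSurface` important surface residues, and
#' returns that cluster at the smallest qualifying coverage
#' (simultaneous qualifiers are broken by best surface rank). Returns
#' `NULL` when no cluster ever qualifies -- the chain then yields no
#' template and no prediction.
#'
#' @inheritParams identifyClusters
#' @param minSurface required number of important surface residues
#'   (default 11).
#' @param step coverage sweep step (default 0.01).
#' @return a [ResidueCluster-class] with `formationThreshold` set, or
#'   `NULL`.
#' @export
selectPrimaryCluster <- function(chain, ranks, surface, linkCutoff = 8,
                                 minSurface = 11, step = 0.01) {
  for (cov in seq(step, 1, by = step)) {
    cls <- identifyClusters(chain, ranks, surface, cov, linkCutoff)
    qual <- Filter(function(cl) length(cl@surfaceMembers) >= minSurface, cls)
    if (length(qual)) return(qual[[1L]])  # already sorted by bestRank
  }
  NULL
}

#' Select additional clusters for multiple-template mode
#'
#' After the primary cluster is fixed, other clusters can contribute
#' templates when they (a) do not coincide with the primary site --
#' clusters identical to, contained in, or containing the primary are
#' excluded; (b) contain at least one surface residue ranked better
#' (smaller) than the `comparator` (best / median / worst) surface
#' rank of the primary; and (c) hold at least `minSurface` surface
#' residues so a template can be picked from them. The coverage is
#' swept upward as for the primary and the qualifying clusters at the
#' first coverage where any appears are returned; the sweep stops at
#' `maxCoverage` so that "additional" sites are drawn from genuinely
#' important residues.
#'
#' @inheritParams identifyClusters
#' @param primary the primary [ResidueCluster-class].
#' @param minSurface surface residues required to support a template
#'   (default 5, i.e. the smaller template size).
#' @param comparator reference surface rank of the primary to beat:
#'   `"median"` (default), `"best"` or `"worst"`.
#' @param maxCoverage sweep bound (default 0.5).
#' @param step coverage sweep step (default 0.01).
#' @return list of [ResidueCluster-class] (possibly empty).
#' @export
selectAdditionalClusters <- function(chain, ranks, surface, primary,
                                     linkCutoff = 8, minSurface = 5,
                                     comparator = c("median", "best",
                                                    "worst"),
                                     maxCoverage = 0.5, step = 0.01) {
  comparator <- match.arg(comparator)
  stopifnot(is(primary, "ResidueCluster"))
  psurf <- rankOf(ranks, primary@surfaceMembers)
  refRank <- switch(comparator,
                    best = min(psurf),
                    median = stats::median(psurf),
                    worst = max(psurf))
  for (cov in seq(step, maxCoverage, by = step)) {
    cls <- identifyClusters(chain, ranks, surface, cov, linkCutoff)
    qual <- Filter(function(cl) {
      if (identical(cl@members, primary@members)) return(FALSE)
      if (all(cl@members %in% primary@members)) return(FALSE)
      if (all(primary@members %in% cl@members)) return(FALSE)
      if (length(cl@surfaceMembers) < minSurface) return(FALSE)
      any(rankOf(ranks, cl@surfaceMembers) < refRank)
    }, cls)
    if (length(qual)) return(unname(qual))
  }
  list()
}
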