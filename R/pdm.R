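#' Paired-distance matching of a template into a target chain
#'
#' Depth-first enumeration of residue assignments. A target residue is
#' a candidate for template position k when (a) its type is among the
#' position's allowed types, (b) it is not already used in the partial
#' assignment (one target residue fills at most one position), and
#' (c) for every previously placed position j, the target-target
#' C-alpha distance agrees with the template's position k-j distance
#' within `tol`. All complete assignments are returned, residue
#' correspondence in template order. If the number of explored search
#' nodes exceeds `cap`, enumeration stops and the result carries
#' `attr(, "partial") = TRUE`.
#'
#' RMSD, rank differences and ETScore are left unset; see
#' [scoreMatches()].
#'
#' @param template a [Template-class].
#' @param target a [ProteinChain-class].
#' @param tol paired-distance tolerance in A (default 2.5).
#' @param cap search-node budget (default 1e5).
#' @return list of [TemplateMatch-class]; attribute `partial` flags a
#'   truncated enumeration.
#' @seealso [scoreMatches()], [superposeRmsd()]
#' @export
pdmSearch <- function(template, target, tol = 2.5, cap = 1e5) {
  k <- length(template@positions)
  if (k == 0L) stop("empty template")
  stopifnot(tol > 0)
  if (length(target@resno) < k) {
    out <- list(); attr(out, "partial") <- FALSE; return(out)
  }
  tmplD <- as.matrix(stats::dist(template@coords))
  targD <- as.matrix(stats::dist(target@coords))
  cand <- lapply(template@allowedTypes, function(types)
    which(target@aa %in% types))
  results <- list()
  nodes <- 0L
  partial <- FALSE
  assign <- integer(k)
  recurse <- function(depth) {
    if (partial) return()
    for (i in cand[[depth]]) {
      if (partial) return()
      nodes <<- nodes + 1L
      if (nodes > cap) { partial <<- TRUE; return() }
      if (i %in% assign[seq_len(depth - 1L)]) next
      ok <- TRUE
      for (j in seq_len(depth - 1L)) {
        if (abs(targD[i, assign[j]] - tmplD[depth, j]) > tol) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign[depth] <<- i
      if (depth == k) {
        results[[length(results) + 1L]] <<- assign
      } else {
        recurse(depth + 1L)
      }
    }
  }
  recurse(1L)
  matches <- lapply(results, function(idx)
    new("TemplateMatch",
        queryChain = template@sourceChain, targetChain = target@id,
        templatePositions = template@positions,
        matchedPositions = target@resno[idx],
        direction = paste0(template@sourceChain, "->", target@id)))
  attr(matches, "partial") <- partial
  matches
}

#' Score matches: superposition RMSD, rank differences, ETScore
#'
#' Fills each match's `rmsd` (least-squares superposition of the
#' template coordinates onto the matched target C-alphas),
#' `rankDiffs` (per-position absolute percentile-rank difference
#' between query template residue and matched target residue) and
#' `etScore` (their sum).
#'
#' @param matches list of [TemplateMatch-class] from [pdmSearch()].
#' @param template the searched [Template-class].
#' @param target the target [ProteinChain-class].
#' @param queryRanks,targetRanks [ETRanking-class] objects for query
#'   and target chains.
#' @return the scored match list (attributes preserved).
#' @export
scoreMatches <- function(matches, template, target, queryRanks,
                         targetRanks) {
  qp <- percentileOf(queryRanks, template@positions)
  out <- lapply(matches, function(m) {
    idx <- match(m@matchedPositions, target@resno)
    tp <- percentileOf(targetRanks, m@matchedPositions)
    if (anyNA(qp) || anyNA(tp))
      stop("missing percentile rank for a matched residue")
    m@rmsd <- superposeRmsd(template@coords,
                            target@coords[idx, , drop = FALSE])
    m@rankDiffs <- abs(qp - tp)
    m@etScore <- sum(m@rankDiffs)
    m
  })
  attributes(out) <- attributes(matches)
  out
}

#' Keep the best (lowest-RMSD) match per template/target pair
#'
#' Downstream voting and network construction use one match per
#' (template, target) pair; this selects the minimum-RMSD assignment
#' from a scored match list.
#'
#' @param matches scored list of [TemplateMatch-class] for one
#'   template/target pair.
#' @return a list of length 0 or 1.
#' @export
bestMatch <- function(matches) {
  if (length(matches) == 0L) return(list())
  rmsds <- vapply(matches, function(m) m@rmsd, numeric(1))
  if (anyNA(rmsds)) stop("matches must be scored before selection")
  matches[which.min(rmsds)]
}
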