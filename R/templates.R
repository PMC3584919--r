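#' Pick a 5- or 6-residue template from a cluster
#'
#' Greedy, deterministic picker. The first residue is, among the
#' cluster members of best (smallest) rank, the one closest to the
#' cluster centre of mass. Each further residue is chosen by first
#' restricting to the best remaining rank (exact-equality rank bands),
#' then taking the member closest to the midpoint between the centre
#' of mass of the residues already selected and the cluster centre of
#' mass. All ties break on the smallest residue number. Because the
#' rule does not look ahead, the 5-residue template of a cluster is
#' the ordered prefix of its 6-residue template.
#'
#' @param cluster a [ResidueCluster-class] with at least `size`
#'   members.
#' @param chain the source [ProteinChain-class].
#' @param ranks the chain's [ETRanking-class].
#' @param size 5 or 6.
#' @param modeTag tag to record on the template (default matches
#'   `size`).
#' @return a [Template-class]; `allowedTypes` holds the native types
#'   until [templateTypeVariants()] widens them.
#' @export
pickTemplate <- function(cluster, chain, ranks, size,
                         modeTag = if (size == 6L) "6R" else "5R") {
  size <- as.integer(size)
  stopifnot(size %in% c(5L, 6L))
  if (length(cluster@members) < size)
    stop("cluster has ", length(cluster@members),
         " members; cannot pick a ", size, "-residue template")
  members <- cluster@members
  xyz <- chain@coords[match(members, chain@resno), , drop = FALSE]
  rk <- rankOf(ranks, members)
  picked <- integer(0)
  for (k in seq_len(size)) {
    left <- setdiff(seq_along(members), picked)
    band <- left[rk[left] == min(rk[left])]
    ref <- if (k == 1L) cluster@cm
           else (colMeans(xyz[picked, , drop = FALSE]) + cluster@cm) / 2
    d <- sqrt(colSums((t(xyz[band, , drop = FALSE]) - ref)^2))
    best <- band[order(d, members[band])][1L]
    picked <- c(picked, best)
  }
  pos <- members[picked]
  aa <- chain@aa[match(pos, chain@resno)]
  new("Template", sourceChain = chain@id, modeTag = modeTag,
      positions = pos, coords = xyz[picked, , drop = FALSE],
      nativeTypes = aa, allowedTypes = as.list(aa))
}

#' Widen template residue types from a multiple sequence alignment
#'
#' A residue type is allowed at a template position when some
#' alignment row, non-gapped across *all* template columns, shows that
#' type there at least twice (counting identical full patterns across
#' the template columns). The native structural type is always
#' allowed. The alignment's first sequence must be the (ungapped or
#' gapped) source chain: its k-th non-gap column corresponds to the
#' chain's k-th residue.
#'
#' @param template a [Template-class].
#' @param msa an aligned `AAStringSet` (equal widths), first row the
#'   source chain.
#' @param chain the source [ProteinChain-class] (maps residue numbers
#'   to sequence positions).
#' @param minCount occurrences required for a variant pattern
#'   (default 2).
#' @return the template with `allowedTypes` filled.
#' @export
templateTypeVariants <- function(template, msa, chain, minCount = 2L) {
  m <- as.matrix(msa)
  if (length(unique(nchar(as.character(msa)))) != 1L)
    stop("msa rows must be aligned to equal width")
  refCols <- which(m[1L, ] != "-")
  seqIdx <- match(template@positions, chain@resno)
  if (anyNA(seqIdx) || any(seqIdx > length(refCols)))
    stop("template position not mappable to an alignment column")
  cols <- refCols[seqIdx]
  sub <- m[, cols, drop = FALSE]
  ok <- rowSums(sub == "-") == 0L  # non-gapped across all template columns
  allowed <- as.list(template@nativeTypes)
  if (any(ok)) {
    patterns <- apply(sub[ok, , drop = FALSE], 1L, paste, collapse = "")
    counts <- table(patterns)
    seen <- names(counts)[counts >= minCount]
    for (p in seen) {
      chars <- strsplit(p, "")[[1L]]
      for (k in seq_along(chars))
        allowed[[k]] <- union(allowed[[k]], chars[k])
    }
  }
  template@allowedTypes <- allowed
  validObject(template)
  template
}

#' Generate the template set of a chain for one selection mode
#'
#' Single-template modes (`6R`, `5R`) return one template picked from
#' the primary cluster (the first cluster of at least 11 important
#' surface residues). Multiple-template modes (`M6R`, `M5R`)
#' additionally return one template per qualifying additional cluster
#' (see [selectAdditionalClusters()]); when no additional cluster
#' exists, the multiple mode degenerates to the single one. Chains
#' with no qualifying primary cluster yield an empty list (no
#' prediction).
#'
#' @inheritParams identifyClusters
#' @param mode `"6R"`, `"5R"`, `"M6R"` or `"M5R"`.
#' @param msa optional aligned `AAStringSet` for
#'   [templateTypeVariants()].
#' @param minSurfacePrimary cluster size rule for the primary
#'   (default 11).
#' @param comparator,maxCoverage,step passed to the cluster selectors.
#' @return list of [Template-class] (possibly empty).
#' @export
makeTemplates <- function(chain, ranks, surface,
                          mode = c("6R", "5R", "M6R", "M5R"),
                          msa = NULL, linkCutoff = 8,
                          minSurfacePrimary = 11,
                          comparator = "median", maxCoverage = 0.5,
                          step = 0.01) {
  mode <- match.arg(mode)
  size <- if (mode %in% c("6R", "M6R")) 6L else 5L
  primary <- selectPrimaryCluster(chain, ranks, surface,
                                  linkCutoff = linkCutoff,
                                  minSurface = minSurfacePrimary,
                                  step = step)
  if (is.null(primary)) return(list())
  templates <- list(pickTemplate(primary, chain, ranks, size,
                                 modeTag = mode))
  if (mode %in% c("M6R", "M5R")) {
    extra <- selectAdditionalClusters(chain, ranks, surface, primary,
                                      linkCutoff = linkCutoff,
                                      minSurface = size,
                                      comparator = comparator,
                                      maxCoverage = maxCoverage,
                                      step = step)
    for (cl in extra) {
      if (length(cl@members) < size) {
        message("additional cluster of ", length(cl@members),
                " members in ", chain@id, " too small for a ", size,
                "-residue template; skipped")
        next
      }
      templates <- c(templates, list(
        pickTemplate(cl, chain, ranks, size, modeTag = mode)))
    }
  }
  if (!is.null(msa))
    templates <- lapply(templates, templateTypeVariants, msa = msa,
                        chain = chain)
  templates
}
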