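#' Accessors for the core classes
#'
#' Small read-only accessors: `chainId()` and `chainIds()` return
#' identifiers; `residueNumbers()`, `residueTypes()` and `caCoords()`
#' expose a chain's residues; `rankOf()` / `percentileOf()` look up
#' evolutionary ranks by residue number; `isSurface()` applies the
#' strict 2 A^2 accessibility convention; `ecOf()` returns the EC set
#' of a chain (empty when unannotated).
#'
#' @param x object to access.
#' @param resno integer residue numbers to look up; all residues when
#'   missing.
#' @param id chain identifier.
#' @return vectors of the corresponding slot values; lookups return
#'   values aligned with `resno` (`NA` where absent).
#' @name accessors
NULL

#' @rdname accessors
setMethod("chainId", "ProteinChain", function(x) x@id)
#' @rdname accessors
setMethod("chainId", "ETRanking", function(x) x@chainId)
#' @rdname accessors
setMethod("chainId", "SurfaceAnnotation", function(x) x@chainId)

#' @rdname accessors
setMethod("residueNumbers", "ProteinChain", function(x) x@resno)
#' @rdname accessors
setMethod("residueNumbers", "ETRanking", function(x) x@resno)
#' @rdname accessors
setMethod("residueTypes", "ProteinChain", function(x) x@aa)
#' @rdname accessors
setMethod("caCoords", "ProteinChain", function(x) x@coords)
#' @rdname accessors
setMethod("caCoords", "Template", function(x) x@coords)

#' @rdname accessors
setMethod("rankOf", "ETRanking", function(x, resno) {
  if (missing(resno)) return(stats::setNames(x@rank, x@resno))
  x@rank[match(resno, x@resno)]
})

#' @rdname accessors
setMethod("percentileOf", "ETRanking", function(x, resno) {
  if (missing(resno)) return(stats::setNames(x@percentile, x@resno))
  x@percentile[match(resno, x@resno)]
})

SURFACE_AREA_CUTOFF <- 2  # A^2, strict '>' per the DSSP convention

#' @rdname accessors
setMethod("isSurface", "SurfaceAnnotation", function(x, resno) {
  if (missing(resno)) resno <- x@resno
  x@area[match(resno, x@resno)] > SURFACE_AREA_CUTOFF
})

#' @rdname accessors
setMethod("ecOf", "AnnotationTable", function(x, id) {
  if (missing(id)) return(x@labels)
  if (is.null(x@labels[[id]])) character(0) else x@labels[[id]]
})

#' @rdname accessors
setMethod("chainIds", "AnnotationTable", function(x) names(x@labels))
#' @rdname accessors
setMethod("chainIds", "EtaDataset", function(x) names(x@chains))

setMethod("show", "ProteinChain", function(object) {
  cat("ProteinChain", object@id, "with", length(object@resno),
      "C-alpha residues")
  if (!is.na(object@fullLength))
    cat(" (full length ", object@fullLength, ")", sep = "")
  cat("\n")
})

setMethod("show", "ETRanking", function(object) {
  cat("ETRanking for", object@chainId, "over", length(object@resno),
      "residues; rank range",
      paste(signif(range(object@rank), 4), collapse = " - "), "\n")
})

setMethod("show", "Template", function(object) {
  cat(sprintf("Template [%s] from %s: positions %s (%s)\n",
              object@modeTag, object@sourceChain,
              paste(object@positions, collapse = ","),
              paste(object@nativeTypes, collapse = "")))
})

setMethod("show", "TemplateMatch", function(object) {
  cat(sprintf("TemplateMatch %s: %s -> %s, rmsd %s, ETScore %s%s\n",
              object@direction,
              paste(object@templatePositions, collapse = ","),
              paste(object@matchedPositions, collapse = ","),
              format(object@rmsd, digits = 3),
              format(object@etScore, digits = 3),
              if (isTRUE(object@significant)) " [significant]" else ""))
})

setMethod("show", "MatchNetwork", function(object) {
  cat("MatchNetwork with", length(object@nodes), "nodes and",
      nrow(object@edges), "reciprocal-match edges\n")
})

setMethod("show", "DiffusionResult", function(object) {
  cat("DiffusionResult over", length(object@nodes), "nodes,",
      length(object@functions), "functions,",
      sum(object@unknown), "unknown nodes (alpha =", object@alpha, ")\n")
})

setMethod("show", "EtaDataset", function(object) {
  cat("EtaDataset with", length(object@chains), "chains;",
      sum(lengths(object@annotations@labels) > 0), "annotated\n")
})

setMethod("show", "MatchClassifier", function(object) {
  cat("MatchClassifier (", object@kind, "): ", object@provenance, "\n",
      sep = "")
})
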