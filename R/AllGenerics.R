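#' @rdname accessors
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))

#' @rdname accessors
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))

#' @rdname accessors
#' @export
setGeneric("residueTypes", function(x) standardGeneric("residueTypes"))

#' @rdname accessors
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))

#' @rdname accessors
#' @export
setGeneric("percentileOf", function(x, resno) standardGeneric("percentileOf"))

#' @rdname accessors
#' @export
setGeneric("rankOf", function(x, resno) standardGeneric("rankOf"))

#' @rdname accessors
#' @export
setGeneric("isSurface", function(x, resno) standardGeneric("isSurface"))

#' @rdname accessors
#' @export
setGeneric("ecOf", function(x, id) standardGeneric("ecOf"))

#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' Classify match feature vectors
#'
#' Applies a trained [MatchClassifier-class] to a matrix of match
#' features (columns `rmsd, r1..r6`), returning one logical
#' significance flag per row. Deterministic for a fixed model.
#'
#' @param model a [MatchClassifier-class].
#' @param features numeric matrix (or single vector) of 7 columns.
#' @return logical vector of significance calls.
#' @seealso [trainMatchSvm()], [thresholdClassifier()]
#' @export
setGeneric("classifyMatches",
  function(model, features) standardGeneric("classifyMatches"))
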