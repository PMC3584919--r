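#' @import methods
NULL

AA_ALPHABET1 <- c("A","R","N","D","C","Q","E","G","H","I",
                  "L","K","M","F","P","S","T","W","Y","V")

#' Protein chain with C-alpha coordinates
#'
#' One polypeptide chain reduced to its C-alpha trace: author residue
#' numbers, one-letter residue types and 3D coordinates in Angstrom.
#' Residues are identified throughout the package by their author
#' `resno` (PDB numbering), never by 0- or 1-based index.
#'
#' @slot id chain identifier, conventionally PDB code plus chain letter
#'   (e.g. `"3f0nA"`).
#' @slot resno integer vector of author residue numbers, strictly
#'   increasing.
#' @slot aa character vector of one-letter residue types (20-letter
#'   alphabet or `"X"`).
#' @slot coords numeric matrix, one row per residue, columns x/y/z (A).
#' @slot fullLength length of the full (possibly unresolved) sequence;
#'   `NA` when unknown. Used by [truncationRatio()].
#'
#' @seealso [readPdbChain()], [writePdbChain()], [truncationRatio()]
#' @exportClass ProteinChain
setClass("ProteinChain",
  representation(id = "character", resno = "integer", aa = "character",
                 coords = "matrix", fullLength = "integer"),
  prototype(fullLength = NA_integer_))

setValidity("ProteinChain", function(object) {
  n <- length(object@resno)
  if (length(object@id) != 1L || !nzchar(object@id))
    return("'id' must be a single non-empty string")
  if (length(object@aa) != n || nrow(object@coords) != n)
    return("resno, aa and coords must describe the same residues")
  if (n > 0L && any(diff(object@resno) <= 0L))
    return("residue numbers must be strictly increasing")
  if (n > 0L && !all(is.finite(object@coords)))
    return("all coordinates must be finite")
  if (!all(object@aa %in% c(AA_ALPHABET1, "X")))
    return("residue types must be one-letter amino-acid codes or 'X'")
  if (ncol(object@coords) != 3L)
    return("coords must have three columns")
  if (!is.na(object@fullLength) && object@fullLength < n)
    return("fullLength cannot be smaller than the number of residues")
  TRUE
})

#' Per-residue evolutionary-importance ranking
#'
#' Real-valued evolutionary ranks (lower = more important) for the
#' residues of one chain, plus the derived percentile rank: the
#' fraction of residues ranked at least as important,
#' `percentile(i) = #\{j : rank(j) <= rank(i)\} / N`. Ties share the
#' maximal coverage value, so percentiles lie in (0, 1].
#'
#' @slot chainId chain the ranking belongs to.
#' @slot resno integer residue numbers (subset of the chain's).
#' @slot rank numeric ranks, all >= 1.
#' @slot percentile numeric percentile ranks in (0, 1].
#'
#' @seealso [newETRanking()], [readEtRanks()]
#' @exportClass ETRanking
setClass("ETRanking",
  representation(chainId = "character", resno = "integer",
                 rank = "numeric", percentile = "numeric"))

setValidity("ETRanking", function(object) {
  n <- length(object@resno)
  if (length(object@rank) != n || length(object@percentile) != n)
    return("resno, rank and percentile must have equal length")
  if (anyDuplicated(object@resno))
    return("duplicate residue numbers in ranking")
  if (n > 0L && any(object@rank < 1))
    return("ranks must be >= 1")
  if (n > 0L && (any(object@percentile <= 0) || any(object@percentile > 1)))
    return("percentiles must lie in (0, 1]")
  TRUE
})

#' Solvent-accessibility annotation
#'
#' Accessible surface area per residue (A^2). A residue counts as a
#' surface residue when its area exceeds 2 A^2 (strict), the DSSP-based
#' convention used for cluster and template selection.
#'
#' @slot chainId chain identifier.
#' @slot resno integer residue numbers.
#' @slot area numeric accessible areas in A^2, >= 0.
#'
#' @seealso [readAccessibility()], [approximateAccessibility()],
#'   [isSurface()]
#' @exportClass SurfaceAnnotation
setClass("SurfaceAnnotation",
  representation(chainId = "character", resno = "integer", area = "numeric"))

setValidity("SurfaceAnnotation", function(object) {
  if (length(object@resno) != length(object@area))
    return("resno and area must have equal length")
  if (anyDuplicated(object@resno))
    return("duplicate residue numbers in accessibility table")
  if (length(object@area) && any(object@area < 0))
    return("areas must be non-negative")
  TRUE
})

#' Chain-to-EC annotation table
#'
#' Maps chain identifiers to sets of full EC numbers ("a.b.c.d", four
#' numeric fields). A chain may carry several ECs or none (an
#' unannotated / test node).
#'
#' @slot labels named list; each element a character vector of EC
#'   strings (possibly empty).
#'
#' @seealso [readAnnotationTable()], [ecOf()]
#' @exportClass AnnotationTable
setClass("AnnotationTable", representation(labels = "list"))

setValidity("AnnotationTable", function(object) {
  if (length(object@labels) && is.null(names(object@labels)))
    return("labels must be a named list")
  ecs <- unlist(object@labels, use.names = FALSE)
  if (length(ecs) && !all(grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", ecs)))
    return("every EC number must have four numeric fields 'a.b.c.d'")
  TRUE
})

#' Cluster of evolutionarily important residues
#'
#' A single-linkage component of important residues at some rank
#' coverage. `bestRank` is the best (smallest) rank among its surface
#' members; `cm` is the arithmetic mean of all member C-alpha
#' coordinates.
#'
#' @slot members integer residue numbers of all members.
#' @slot surfaceMembers integer residue numbers of members flagged as
#'   surface.
#' @slot formationThreshold rank coverage at which the cluster was
#'   taken.
#' @slot bestRank minimum rank among surface members (`Inf` if none).
#' @slot cm numeric(3) centre of mass of member coordinates.
#'
#' @seealso [identifyClusters()], [selectPrimaryCluster()]
#' @exportClass ResidueCluster
setClass("ResidueCluster",
  representation(members = "integer", surfaceMembers = "integer",
                 formationThreshold = "numeric", bestRank = "numeric",
                 cm = "numeric"))

setValidity("ResidueCluster", function(object) {
  if (length(object@members) < 1L) return("a cluster has at least one member")
  if (!all(object@surfaceMembers %in% object@members))
    return("surface members must be members")
  if (length(object@cm) != 3L) return("cm must be a 3-vector")
  TRUE
})

#' Functional-site search template
#'
#' An ordered set of 5 or 6 residue positions from a source chain, with
#' C-alpha coordinates and per-position sets of allowed residue types,
#' used as a geometric probe by the paired-distance search.
#'
#' @slot sourceChain chain the template was picked from.
#' @slot modeTag one of `"6R"`, `"5R"`, `"M6R"`, `"M5R"`.
#' @slot positions ordered integer residue numbers (5 or 6, distinct).
#' @slot coords matching C-alpha coordinates, one row per position.
#' @slot nativeTypes one-letter types of the template residues.
#' @slot allowedTypes list of character vectors, allowed types per
#'   position; always contains the native type.
#'
#' @seealso [pickTemplate()], [makeTemplates()], [pdmSearch()]
#' @exportClass Template
setClass("Template",
  representation(sourceChain = "character", modeTag = "character",
                 positions = "integer", coords = "matrix",
                 nativeTypes = "character", allowedTypes = "list"))

setValidity("Template", function(object) {
  k <- length(object@positions)
  if (!(k %in% c(5L, 6L))) return("a template has 5 or 6 positions")
  if (anyDuplicated(object@positions)) return("positions must be distinct")
  if (nrow(object@coords) != k || length(object@nativeTypes) != k ||
      length(object@allowedTypes) != k)
    return("coords, nativeTypes and allowedTypes must match positions")
  ok <- vapply(seq_len(k), function(i)
    object@nativeTypes[i] %in% object@allowedTypes[[i]], logical(1))
  if (!all(ok)) return("native type must be allowed at every position")
  TRUE
})

#' A geometric match of a template into a target chain
#'
#' Residue correspondence between a query template and a target chain.
#' `rankDiffs` are per-position absolute percentile-rank differences;
#' `etScore` is their sum; `rmsd` is the least-squares superposition
#' RMSD of the matched C-alpha sets. `significant` is set by the
#' SVM / threshold filter.
#'
#' @slot queryChain,targetChain chain identifiers.
#' @slot templatePositions,matchedPositions ordered residue numbers in
#'   query and target, equal length.
#' @slot rmsd superposition RMSD in A (`NA` until scored).
#' @slot rankDiffs numeric per-position |delta percentile| in \[0, 1\].
#' @slot etScore sum of `rankDiffs`.
#' @slot direction string `"query->target"`.
#' @slot significant logical, `NA` until classified.
#'
#' @seealso [pdmSearch()], [scoreMatches()], [classifyMatches()]
#' @exportClass TemplateMatch
setClass("TemplateMatch",
  representation(queryChain = "character", targetChain = "character",
                 templatePositions = "integer", matchedPositions = "integer",
                 rmsd = "numeric", rankDiffs = "numeric", etScore = "numeric",
                 direction = "character", significant = "logical"),
  prototype(rmsd = NA_real_, etScore = NA_real_, significant = NA))

setValidity("TemplateMatch", function(object) {
  if (length(object@templatePositions) != length(object@matchedPositions))
    return("template and matched positions must have equal length")
  if (anyDuplicated(object@matchedPositions))
    return("a target residue may fill only one template position")
  if (!is.na(object@rmsd) && object@rmsd < 0) return("rmsd must be >= 0")
  if (length(object@rankDiffs) &&
      (any(object@rankDiffs < 0) || any(object@rankDiffs > 1)))
    return("rank differences must lie in [0, 1]")
  if (length(object@rankDiffs) && !is.na(object@etScore) &&
      abs(object@etScore - sum(object@rankDiffs)) > 1e-9)
    return("etScore must equal the sum of rankDiffs")
  TRUE
})

#' Trained match classifier
#'
#' Binary classifier over 7-dimensional match feature vectors
#' `[rmsd, r1..r6]` deciding match significance, with hyperparameters
#' and training provenance recorded. `fit` holds an [e1071::svm] model
#' (RBF kernel, internally standardized features) or, for the
#' transparent fallback rule, a list of thresholds.
#'
#' @slot fit fitted classifier object.
#' @slot kind `"svm"` or `"threshold"`.
#' @slot hyper named list of hyperparameters.
#' @slot provenance free-text training provenance.
#'
#' @seealso [trainMatchSvm()], [thresholdClassifier()],
#'   [classifyMatches()]
#' @exportClass MatchClassifier
setClass("MatchClassifier",
  representation(fit = "ANY", kind = "character", hyper = "list",
                 provenance = "character"))

#' Weighted network of reciprocal template matches
#'
#' Nodes are protein chains; one undirected edge per reciprocal match
#' pair, carrying the minimum-RMSD match's (rmsd, ETScore). The raw
#' edge score `s = 1/2[(rmsd - mu_r)/sd_r + (ET - mu_ET)/sd_ET]`
#' (population standard deviations over all network matches) is mapped
#' to a non-negative weight, by default `W = exp(-s)` so that
#' better-than-average matches weigh more than 1.
#'
#' @slot nodes ordered chain identifiers.
#' @slot labels named list of known EC sets per node (empty = unknown).
#' @slot W symmetric non-negative weight matrix, zero diagonal.
#' @slot edges data.frame with columns a, b, rmsd, etScore, s, w.
#' @slot stats named numeric: muRmsd, sdRmsd, muEt, sdEt.
#'
#' @seealso [buildNetwork()], [networkFromEdges()],
#'   [competitiveDiffusion()]
#' @exportClass MatchNetwork
setClass("MatchNetwork",
  representation(nodes = "character", labels = "list", W = "matrix",
                 edges = "data.frame", stats = "numeric"))

setValidity("MatchNetwork", function(object) {
  n <- length(object@nodes)
  if (anyDuplicated(object@nodes)) return("node ids must be unique")
  if (!all(dim(object@W) == c(n, n))) return("W must be n x n")
  if (length(object@labels) != n) return("one label set per node")
  if (n > 0L) {
    if (any(abs(object@W - t(object@W)) > 1e-9)) return("W must be symmetric")
    if (any(object@W < 0)) return("weights must be non-negative")
    if (any(diag(object@W) != 0)) return("W must have zero diagonal")
  }
  TRUE
})

#' Result of competitive label diffusion
#'
#' Per function: the label vector `y` (+1 has / -1 has another known
#' function / 0 unknown) diffused to scores `f` by solving
#' `(I + alpha L) f = y`; per unknown node the z-score of `f` across
#' unknown nodes, the argmax-z label and its confidence.
#'
#' @slot nodes node identifiers (network order).
#' @slot functions function labels diffused (columns of `f`/`z`).
#' @slot f numeric matrix, nodes x functions, diffused scores.
#' @slot z numeric matrix, nodes x functions; `NA` for known nodes.
#' @slot unknown logical, which nodes were unlabeled.
#' @slot bestLabel predicted label per node (`NA` for known nodes).
#' @slot bestZ confidence of the prediction (`NA` for known nodes).
#' @slot alpha diffusion trade-off parameter used.
#'
#' @seealso [competitiveDiffusion()], [confidenceBands()]
#' @exportClass DiffusionResult
setClass("DiffusionResult",
  representation(nodes = "character", functions = "character",
                 f = "matrix", z = "matrix", unknown = "logical",
                 bestLabel = "character", bestZ = "numeric",
                 alpha = "numeric"))

#' A self-contained structure/ranking/annotation study set
#'
#' Bundles the per-chain inputs of the annotation pipeline: C-alpha
#' chains, evolutionary rankings, accessibility annotations, the EC
#' annotation table, and (optionally) per-chain multiple sequence
#' alignments for template type variants.
#'
#' @slot chains named list of [ProteinChain-class] objects.
#' @slot rankings named list of [ETRanking-class] objects.
#' @slot surfaces named list of [SurfaceAnnotation-class] objects.
#' @slot annotations an [AnnotationTable-class].
#' @slot msas named list of aligned `AAStringSet`s (may be empty).
#'
#' @seealso [etaDataset()], [generateBenchmark()], [readBenchmark()]
#' @exportClass EtaDataset
setClass("EtaDataset",
  representation(chains = "list", rankings = "list", surfaces = "list",
                 annotations = "AnnotationTable", msas = "list"))

setValidity("EtaDataset", function(object) {
  ids <- names(object@chains)
  if (length(ids) == 0L) return("dataset must contain at least one chain")
  if (!identical(sort(ids), sort(names(object@rankings))) ||
      !identical(sort(ids), sort(names(object@surfaces))))
    return("chains, rankings and surfaces must cover the same ids")
  TRUE
})
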