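#' Assemble a study dataset
#'
#' @param chains list of [ProteinChain-class] (named, or names taken
#'   from the chain ids).
#' @param rankings,surfaces matching lists of [ETRanking-class] and
#'   [SurfaceAnnotation-class].
#' @param annotations an [AnnotationTable-class] (may omit chains --
#'   they are then unannotated).
#' @param msas optional named list of aligned `AAStringSet`s.
#' @return an [EtaDataset-class].
#' @export
etaDataset <- function(chains, rankings, surfaces,
                       annotations = annotationTable(), msas = list()) {
  if (is.null(names(chains)))
    names(chains) <- vapply(chains, function(ch) ch@id, character(1))
  if (is.null(names(rankings)))
    names(rankings) <- vapply(rankings, function(r) r@chainId, character(1))
  if (is.null(names(surfaces)))
    names(surfaces) <- vapply(surfaces, function(s) s@chainId, character(1))
  new("EtaDataset", chains = chains, rankings = rankings,
      surfaces = surfaces, annotations = annotations, msas = msas)
}

#' Read a benchmark directory written by generateBenchmark
#'
#' Expects `manifest.json` plus, per chain, `<id>.pdb`,
#' `<id>.ranks.tsv` and `<id>.acc.tsv`, and `annotations.tsv`.
#'
#' @param dir benchmark directory.
#' @return list with `dataset` (an [EtaDataset-class]) and the parsed
#'   `manifest`.
#' @seealso [generateBenchmark()]
#' @export
readBenchmark <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ids <- manifest$ids
  chains <- lapply(ids, function(id) {
    ch <- readPdbChain(file.path(dir, paste0(id, ".pdb")),
                       chain = substr(id, nchar(id), nchar(id)))
    ch@id <- id  # file stem already carries the chain letter
    ch
  })
  rankings <- lapply(ids, function(id)
    readEtRanks(file.path(dir, paste0(id, ".ranks.tsv")), chainId = id))
  surfaces <- lapply(ids, function(id)
    readAccessibility(file.path(dir, paste0(id, ".acc.tsv")),
                      chainId = id))
  names(chains) <- names(rankings) <- names(surfaces) <- ids
  annotations <- readAnnotationTable(file.path(dir, "annotations.tsv"))
  list(dataset = etaDataset(chains, rankings, surfaces, annotations),
       manifest = manifest)
}
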