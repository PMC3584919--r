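#' Construct, read and write chain-to-EC annotation tables
#'
#' The annotation dialect is one line per chain,
#' `chain_id<TAB>EC[,EC...]`; a line with an empty second field (or no
#' second field) records an unannotated chain. Every EC number must
#' have four numeric fields `a.b.c.d`.
#'
#' @param labels named list of character vectors of EC numbers.
#' @param path file to read or write.
#' @param table an [AnnotationTable-class] (writer).
#' @return an [AnnotationTable-class]; the writer returns `path`
#'   invisibly.
#' @examples
#' tab <- annotationTable(list(aA = "1.1.1.1", bA = c("1.1.1.2", "2.7.1.1"),
#'                             cA = character(0)))
#' ecOf(tab, "bA")
#' @export
annotationTable <- function(labels = list()) {
  labels <- lapply(labels, as.character)
  new("AnnotationTable", labels = labels)
}

#' @rdname annotationTable
#' @export
readAnnotationTable <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  labels <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(trimws(p[2L]))) character(0)
    else trimws(strsplit(p[2L], ",", fixed = TRUE)[[1L]])
  })
  names(labels) <- ids
  annotationTable(labels)
}

#' @rdname annotationTable
#' @export
writeAnnotationTable <- function(table, path) {
  stopifnot(is(table, "AnnotationTable"))
  lines <- vapply(names(table@labels), function(id)
    paste0(id, "\t", paste(table@labels[[id]], collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict an annotation table to full four-field EC numbers
#'
#' Votes and diffusion labels only use complete EC annotations; this
#' helper drops anything else (already enforced by the class validity,
#' kept as an explicit guard for externally built tables).
#'
#' @param table an [AnnotationTable-class].
#' @return the filtered table.
#' @keywords internal
fullEcOnly <- function(table) {
  annotationTable(lapply(table@labels, function(e)
    e[grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", e)]))
}
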