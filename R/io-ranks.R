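#' Construct an evolutionary ranking
#'
#' Computes percentile ranks from real-valued evolutionary ranks:
#' `percentile(i) = #\{j : rank(j) <= rank(i)\} / N`, the fraction of
#' residues at least as important. Ties share the maximal coverage
#' value; percentiles therefore lie in (0, 1] and are invariant under
#' strictly monotone transforms of the ranks.
#'
#' @param chainId chain identifier.
#' @param resno integer residue numbers.
#' @param rank numeric ranks >= 1 (lower = more important).
#' @return an [ETRanking-class].
#' @examples
#' r <- newETRanking("toyA", 1:4, c(1, 2, 3, 4))
#' percentileOf(r)  # 0.25 0.50 0.75 1.00
#' @export
newETRanking <- function(chainId, resno, rank) {
  resno <- as.integer(resno)
  rank <- as.numeric(rank)
  if (anyDuplicated(resno)) stop("duplicate residue numbers in ranking")
  n <- length(rank)
  pct <- vapply(rank, function(r) sum(rank <= r), numeric(1)) / n
  new("ETRanking", chainId = as.character(chainId), resno = resno,
      rank = rank, percentile = pct)
}

#' Read / write per-residue evolutionary ranks
#'
#' The rank dialect is whitespace-separated lines `resno aa rank`,
#' with optional comment lines starting `#`. Percentiles are derived
#' on read (see [newETRanking()]); the writer emits the same dialect
#' so the two are mutually inverse on valid data.
#'
#' @param path file to read or write.
#' @param chainId chain identifier to attach (defaults to the file
#'   stem).
#' @param ranking an [ETRanking-class] (writer).
#' @param aa optional residue types for the writer's middle column
#'   (defaults to `"X"`).
#' @return [readEtRanks()] returns an [ETRanking-class];
#'   [writeEtRanks()] returns `path` invisibly.
#' @export
readEtRanks <- function(path, chainId = sub("\\.[^.]*$", "", basename(path))) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  parts <- strsplit(trimws(ln), "\\s+")
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed rank line(s): ", ln[which(bad)[1]])
  resno <- as.integer(vapply(parts, `[`, character(1), 1L))
  rank <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3L)))
  if (anyNA(rank)) stop("non-numeric rank in ", path)
  if (anyNA(resno)) stop("non-integer residue number in ", path)
  if (anyDuplicated(resno)) stop("duplicate residue number in ", path)
  newETRanking(chainId, resno, rank)
}

#' @rdname readEtRanks
#' @export
writeEtRanks <- function(ranking, path, aa = NULL) {
  stopifnot(is(ranking, "ETRanking"))
  if (is.null(aa)) aa <- rep("X", length(ranking@resno))
  writeLines(c("# resno aa rank",
               sprintf("%d\t%s\t%.6g", ranking@resno, aa, ranking@rank)),
             path)
  invisible(path)
}
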