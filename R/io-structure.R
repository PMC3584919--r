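#' Construct a ProteinChain
#'
#' @param id chain identifier (e.g. `"3f0nA"`).
#' @param resno integer author residue numbers, strictly increasing.
#' @param aa one-letter residue types.
#' @param coords numeric n x 3 matrix of C-alpha coordinates (A).
#' @param fullLength full sequence length, or `NA` when unknown.
#' @return a [ProteinChain-class].
#' @examples
#' newProteinChain("toyA", 1:3, c("G", "A", "S"),
#'                 matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, byrow = TRUE))
#' @export
newProteinChain <- function(id, resno, aa, coords, fullLength = NA) {
  coords <- matrix(as.numeric(coords), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  new("ProteinChain", id = as.character(id), resno = as.integer(resno),
      aa = as.character(aa), coords = coords,
      fullLength = as.integer(fullLength))
}

#' Read one chain's C-alpha trace from a PDB file
#'
#' Parses ATOM records with [bio3d::read.pdb()] and extracts the CA
#' atoms of the requested chain. Alternate locations are resolved to
#' the highest occupancy (first on ties); insertion-coded residues are
#' skipped with a warning.
#'
#' @param path PDB file.
#' @param chain one-letter chain identifier.
#' @param fullLength optional full sequence length to attach (for
#'   [truncationRatio()]).
#' @return a [ProteinChain-class] named `"<pdbstem><chain>"`.
#' @seealso [writePdbChain()]
#' @export
readPdbChain <- function(path, chain, fullLength = NA) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  have <- sort(unique(at$chain[at$type == "ATOM"]))
  if (!chain %in% have)
    stop("chain '", chain, "' not found in ", path,
         "; available chains: ", paste(have, collapse = ", "))
  at <- at[at$type == "ATOM" & at$chain == chain & at$elety == "CA", ,
           drop = FALSE]
  if (nrow(at) == 0L) stop("no CA atoms for chain '", chain, "' in ", path)
  ins <- !is.na(at$insert) & nzchar(at$insert)
  if (any(ins)) {
    warning(sum(ins), " insertion-coded residue(s) skipped in ",
            basename(path), " chain ", chain)
    at <- at[!ins, , drop = FALSE]
  }
  # altloc: keep highest occupancy, then first occurrence
  o <- order(at$resno, -replace(at$o, is.na(at$o), 1))
  at <- at[o, , drop = FALSE]
  at <- at[!duplicated(at$resno), , drop = FALSE]
  aa <- bio3d::aa321(at$resid)
  aa[is.na(aa) | !aa %in% AA_ALPHABET1] <- "X"
  id <- paste0(sub("\\.pdb$", "", basename(path)), chain)
  newProteinChain(id, at$resno, aa,
                  cbind(at$x, at$y, at$z), fullLength = fullLength)
}

#' Write a C-alpha-only PDB file
#'
#' Emits standard fixed-width ATOM records (CA only, occupancy 1.00),
#' chain letter taken from the last character of the chain id.
#' Coordinates are written at 3 decimals, so chains whose coordinates
#' are already rounded to 3 decimals round-trip exactly through
#' [readPdbChain()].
#'
#' @param chain a [ProteinChain-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePdbChain <- function(chain, path) {
  ch <- substr(chain@id, nchar(chain@id), nchar(chain@id))
  aa3 <- bio3d::aa123(chain@aa)
  aa3[is.na(aa3)] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(chain@resno), aa3, ch, chain@resno,
    chain@coords[, 1], chain@coords[, 2], chain@coords[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Structure completeness (truncation ratio)
#'
#' Ratio of resolved residues to the full sequence length. Target
#' structures are conventionally kept when the ratio is strictly
#' greater than 0.95.
#'
#' @param chain a [ProteinChain-class] with `fullLength` set.
#' @return a number in \[0, 1\].
#' @examples
#' ch <- newProteinChain("tA", 1:95, rep("A", 95),
#'                       cbind(seq(0, by = 3.8, length.out = 95), 0, 0),
#'                       fullLength = 100)
#' truncationRatio(ch)  # 0.95 -- fails the strict > 0.95 filter
#' @export
truncationRatio <- function(chain) {
  stopifnot(is(chain, "ProteinChain"))
  if (is.na(chain@fullLength))
    stop("fullLength is not recorded for chain ", chain@id)
  length(chain@resno) / chain@fullLength
}
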