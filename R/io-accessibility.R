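#' Read / write solvent-accessibility tables
#'
#' The accessibility dialect is whitespace-separated `resno area`
#' lines (areas in A^2, as computed by DSSP or equivalent), optional
#' `#` comments. Residues with area strictly greater than 2 A^2 count
#' as surface.
#'
#' @param path file to read or write.
#' @param chainId chain identifier (defaults to the file stem).
#' @param surface a [SurfaceAnnotation-class] (writer).
#' @return [readAccessibility()] returns a [SurfaceAnnotation-class];
#'   [writeAccessibility()] returns `path` invisibly.
#' @export
readAccessibility <- function(path,
                              chainId = sub("\\.[^.]*$", "", basename(path))) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  parts <- strsplit(trimws(ln), "\\s+")
  resno <- as.integer(vapply(parts, `[`, character(1), 1L))
  area <- as.numeric(vapply(parts, `[`, character(1), 2L))
  if (any(area < 0)) stop("negative accessible area in ", path)
  new("SurfaceAnnotation", chainId = chainId, resno = resno, area = area)
}

#' @rdname readAccessibility
#' @export
writeAccessibility <- function(surface, path) {
  stopifnot(is(surface, "SurfaceAnnotation"))
  writeLines(c("# resno area",
               sprintf("%d\t%.6g", surface@resno, surface@area)),
             path)
  invisible(path)
}

#' Coarse surface approximation from C-alpha packing
#'
#' A stand-in for measured accessibility when no DSSP-style table is
#' available: residues with few C-alpha neighbours within `radius` are
#' taken as exposed. A residue is flagged surface when its neighbour
#' count is at or below the `quantile` quantile of all neighbour
#' counts; flagged residues receive a pseudo-area above the 2 A^2
#' cutoff, buried ones 0. This is a packing proxy, not a
#' solvent-accessible-area computation, and synthetic benchmarks ship
#' explicit areas so nothing downstream depends on it.
#'
#' @param chain a [ProteinChain-class] with at least 2 residues.
#' @param radius neighbour radius in A (default 10).
#' @param quantile fraction of least-buried residues to flag (default
#'   0.6).
#' @return a [SurfaceAnnotation-class].
#' @export
approximateAccessibility <- function(chain, radius = 10, quantile = 0.6) {
  stopifnot(is(chain, "ProteinChain"))
  n <- length(chain@resno)
  if (n < 2L) stop("approximation requires at least 2 residues")
  d <- as.matrix(stats::dist(chain@coords))
  counts <- rowSums(d <= radius) - 1L
  cutoff <- stats::quantile(counts, probs = quantile, names = FALSE,
                            type = 1)
  area <- ifelse(counts <= cutoff, 2 * SURFACE_AREA_CUTOFF, 0)
  new("SurfaceAnnotation", chainId = chain@id, resno = chain@resno,
      area = as.numeric(area))
}
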