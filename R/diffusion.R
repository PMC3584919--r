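#' Diffuse labels over a weighted graph
#'
#' Minimizes the regularized-Laplacian objective
#' `H(f) = sum_i (f_i - y_i)^2 + alpha * sum_{i<j} w_ij (f_i - f_j)^2`
#' whose unique minimizer solves the symmetric positive-definite
#' system `(I + alpha L) f = y`, with `L = D - W` the graph Laplacian.
#' As `alpha -> 0`, `f -> y`; on a connected graph with constant `y`,
#' `f = y` exactly (the Laplacian annihilates constants).
#'
#' @param W symmetric non-negative weight matrix with zero diagonal.
#' @param y numeric label vector (+1 has the function, -1 known not
#'   to, 0 unknown).
#' @param alpha trade-off parameter > 0 between fidelity and
#'   smoothness (default 1).
#' @return numeric vector `f` of diffused scores.
#' @examples
#' W <- matrix(c(0, 1, 1, 0), 2)
#' diffuseLabels(W, c(1, 0), alpha = 1)  # (2/3, 1/3)
#' @export
diffuseLabels <- function(W, y, alpha = 1) {
  W <- as.matrix(W)
  n <- nrow(W)
  stopifnot(alpha > 0, length(y) == n)
  if (any(abs(W - t(W)) > 1e-9)) stop("W must be symmetric")
  if (any(W < 0)) stop("weights must be non-negative")
  if (n == 0L) return(numeric(0))
  if (n >= 500L) {
    Ws <- Matrix::Matrix(W, sparse = TRUE)
    L <- Matrix::Diagonal(x = Matrix::rowSums(Ws)) - Ws
    A <- Matrix::Diagonal(n) + alpha * L
    as.numeric(Matrix::solve(A, y))
  } else {
    L <- diag(rowSums(W), n) - W
    as.numeric(solve(diag(n) + alpha * L, y))
  }
}

#' Confidence z-scores over unknown nodes
#'
#' Standardizes diffused scores across the unknown nodes only:
#' `z_i = (f_i - mean(f_unknown)) / sd(f_unknown)` with the
#' *population* standard deviation, so valid z-vectors have mean 0
#' and standard deviation 1. When the diffused scores are constant
#' over the unknowns the z-score is undefined; all zeros are returned
#' with a warning.
#'
#' @param f numeric diffused scores for all nodes.
#' @param unknown logical mask of unknown nodes (at least 2).
#' @return numeric z-scores, one per unknown node.
#' @export
confidenceZ <- function(f, unknown) {
  stopifnot(length(f) == length(unknown))
  fu <- f[unknown]
  if (length(fu) < 2L)
    stop("confidence z-scores need at least 2 unknown nodes")
  s <- sqrt(mean((fu - mean(fu))^2))
  if (s == 0) {
    warning("diffused scores constant over unknown nodes; z set to 0")
    return(rep(0, length(fu)))
  }
  (fu - mean(fu)) / s
}

#' Competitive label diffusion with z-score confidences
#'
#' For every function label present in the network, builds the label
#' vector `y` (+1 nodes annotated with the function, -1 nodes
#' annotated only with other functions, 0 unannotated), diffuses it
#' with [diffuseLabels()], and standardizes the diffused scores over
#' the unknown nodes. Each unknown node is assigned the function with
#' the largest z-score; exact z ties break by larger `f`, then by
#' lexicographic label order.
#'
#' @param network a [MatchNetwork-class] whose `labels` slot holds the
#'   known annotations.
#' @param alpha diffusion parameter (default 1).
#' @return a [DiffusionResult-class].
#' @export
competitiveDiffusion <- function(network, alpha = 1) {
  labels <- network@labels
  funs <- sort(unique(unlist(labels)))
  if (length(funs) == 0L) stop("no labeled function in the network")
  nodes <- network@nodes
  n <- length(nodes)
  unknown <- lengths(labels) == 0L
  f <- matrix(NA_real_, n, length(funs), dimnames = list(nodes, funs))
  z <- matrix(NA_real_, n, length(funs), dimnames = list(nodes, funs))
  for (j in seq_along(funs)) {
    y <- ifelse(vapply(labels, function(l) funs[j] %in% l, logical(1)), 1,
                ifelse(unknown, 0, -1))
    f[, j] <- diffuseLabels(network@W, y, alpha)
    if (sum(unknown) >= 2L)
      z[unknown, j] <- suppressWarnings(confidenceZ(f[, j], unknown))
  }
  bestLabel <- rep(NA_character_, n)
  bestZ <- rep(NA_real_, n)
  for (i in which(unknown)) {
    zi <- z[i, ]
    if (all(is.na(zi))) next
    best <- which(zi == max(zi, na.rm = TRUE))
    if (length(best) > 1L) {
      fi <- f[i, best]
      best <- best[fi == max(fi)]
      best <- best[order(funs[best])]
    }
    bestLabel[i] <- funs[best[1L]]
    bestZ[i] <- zi[best[1L]]
  }
  new("DiffusionResult", nodes = nodes, functions = funs, f = f, z = z,
      unknown = unknown, bestLabel = bestLabel, bestZ = bestZ,
      alpha = alpha)
}

#' Diffusion predictions as a table
#'
#' @param result a [DiffusionResult-class].
#' @return data.frame with one row per unknown node: `query`, `label`,
#'   `z`.
#' @export
diffusionPredictions <- function(result) {
  i <- which(result@unknown)
  data.frame(query = result@nodes[i], label = result@bestLabel[i],
             z = result@bestZ[i], stringsAsFactors = FALSE)
}

#' Cumulative accuracy by confidence band
#'
#' For each confidence threshold, the accuracy of all predictions at
#' or above that z value -- the banded report used to read off how
#' trustworthy high-confidence diffusion predictions are. Cumulative
#' accuracy is reported as-is and need not be monotone.
#'
#' @param predictions data.frame with `query`, `label`, `z` (e.g.
#'   from [diffusionPredictions()]).
#' @param truth an [AnnotationTable-class] of true labels.
#' @param thresholds z thresholds, conventionally `c(2, 0.5)`.
#' @return data.frame with columns `threshold`, `n`, `accuracy`.
#' @export
confidenceBands <- function(predictions, truth, thresholds = c(2, 0.5)) {
  rows <- lapply(thresholds, function(th) {
    keep <- predictions[!is.na(predictions$z) & predictions$z >= th, ,
                        drop = FALSE]
    correct <- vapply(seq_len(nrow(keep)), function(i)
      keep$label[i] %in% ecOf(truth, keep$query[i]), logical(1))
    data.frame(threshold = th, n = nrow(keep),
               accuracy = if (nrow(keep)) mean(correct) else NA_real_)
  })
  do.call(rbind, rows)
}
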