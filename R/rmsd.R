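#' Least-squares superposition RMSD of two coordinate sets
#'
#' Root-mean-square deviation after optimal rigid superposition
#' (rotation plus translation, no reflection) of two equally sized
#' point sets -- the field convention for judging template matches;
#' the downstream filter removes matches with RMSD strictly greater
#' than 2 A. Kabsch's SVD solution: both sets are centered, the
#' covariance `t(A) B` is decomposed, and the sign of the smallest
#' singular direction is flipped when the optimal orthogonal map
#' would be a reflection.
#'
#' @param a,b numeric n x 3 coordinate matrices, n >= 3, equal sizes.
#' @return RMSD in A; 0 (to numerical precision) iff the sets are
#'   congruent. Symmetric in its arguments and invariant to rigid
#'   motion of either.
#' @examples
#' a <- matrix(rnorm(15), 5, 3)
#' superposeRmsd(a, a + 10)  # pure translation: ~0
#' @export
superposeRmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("coordinate sets must have identical dimensions")
  if (nrow(a) < 3L) stop("superposition needs at least 3 points")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("coordinates must be finite")
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(t(ac) %*% bc)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1  # degenerate (e.g. collinear) sets: either sign
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((ac %*% t(R) - bc)^2)))
}
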