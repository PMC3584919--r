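#' RMSD / self-match prefilter
#'
#' Removes self-matches (query chain equals target chain) and matches
#' whose superposition RMSD is strictly greater than `maxRmsd`
#' (default 2 A; a match at exactly 2 A is kept). Idempotent.
#'
#' @param matches scored list of [TemplateMatch-class].
#' @param maxRmsd RMSD cutoff in A (default 2).
#' @return the surviving matches.
#' @export
prefilterMatches <- function(matches, maxRmsd = 2) {
  Filter(function(m) {
    if (is.na(m@rmsd)) stop("matches must be scored before filtering")
    m@queryChain != m@targetChain && m@rmsd <= maxRmsd
  }, matches)
}

#' Match feature vector for significance classification
#'
#' Seven features per match: the superposition RMSD and six absolute
#' percentile-rank differences `r1..r6`. Five-residue matches reuse
#' the six-residue classifier by adding a virtual sixth residue whose
#' difference is the mean of the other five.
#'
#' @param match a scored [TemplateMatch-class] (or its `rankDiffs`
#'   recomputed from `queryRanks`/`targetRanks` when given).
#' @param queryRanks,targetRanks optional [ETRanking-class] objects to
#'   recompute the percentile differences from.
#' @return named numeric vector `c(rmsd, r1..r6)`.
#' @export
matchFeatures <- function(match, queryRanks = NULL, targetRanks = NULL) {
  diffs <- match@rankDiffs
  if (!is.null(queryRanks) && !is.null(targetRanks)) {
    qp <- percentileOf(queryRanks, match@templatePositions)
    tp <- percentileOf(targetRanks, match@matchedPositions)
    if (anyNA(qp) || anyNA(tp))
      stop("missing percentile rank for a matched residue")
    diffs <- abs(qp - tp)
  }
  if (length(diffs) == 0L || is.na(match@rmsd))
    stop("match must be scored before featurization")
  if (length(diffs) == 5L) diffs <- c(diffs, mean(diffs))
  if (length(diffs) != 6L)
    stop("expected 5 or 6 rank differences, got ", length(diffs))
  stats::setNames(c(match@rmsd, diffs),
                  c("rmsd", paste0("r", 1:6)))
}

#' Feature matrix for a list of matches
#'
#' @param matches scored list of [TemplateMatch-class].
#' @return numeric matrix, one row per match, columns `rmsd, r1..r6`.
#' @rdname matchFeatures
#' @export
matchFeatureMatrix <- function(matches) {
  if (length(matches) == 0L)
    return(matrix(numeric(0), 0, 7,
                  dimnames = list(NULL, c("rmsd", paste0("r", 1:6)))))
  do.call(rbind, lapply(matches, matchFeatures))
}

#' Train the match-significance SVM
#'
#' Fits an RBF-kernel support vector machine on labeled match feature
#' vectors (columns `rmsd, r1..r6`), with features standardized
#' internally and `cost`/`gamma` chosen by cross-validated accuracy on
#' a small grid. Deterministic for a fixed `seed`.
#'
#' @param features numeric matrix of 7 columns.
#' @param labels logical (or coercible) significance labels; both
#'   classes must be present.
#' @param costs,gammas hyperparameter grids.
#' @param cross folds for grid selection (default 5).
#' @param seed RNG seed controlling fold assignment (default 1).
#' @param provenance free-text note on the training data recorded in
#'   the model.
#' @return a [MatchClassifier-class] of kind `"svm"`.
#' @seealso [classifyMatches()], [thresholdClassifier()]
#' @export
trainMatchSvm <- function(features, labels, costs = c(1, 10, 100),
                          gammas = c(0.05, 0.2, 1), cross = 5,
                          seed = 1L,
                          provenance = "trained on synthetic benchmark matches") {
  features <- as.matrix(features)
  y <- factor(as.logical(labels), levels = c(FALSE, TRUE))
  if (nlevels(droplevels(y)) < 2L)
    stop("training data must contain both significant and insignificant matches")
  best <- NULL
  bestAcc <- -Inf
  for (co in costs) for (ga in gammas) {
    set.seed(seed)
    fit <- e1071::svm(features, y, kernel = "radial", cost = co,
                      gamma = ga, scale = TRUE, cross = cross)
    if (fit$tot.accuracy > bestAcc) {
      bestAcc <- fit$tot.accuracy
      best <- list(cost = co, gamma = ga)
    }
  }
  set.seed(seed)
  fit <- e1071::svm(features, y, kernel = "radial", cost = best$cost,
                    gamma = best$gamma, scale = TRUE)
  new("MatchClassifier", fit = fit, kind = "svm",
      hyper = list(kernel = "radial", cost = best$cost,
                   gamma = best$gamma, cvAccuracy = bestAcc / 100),
      provenance = provenance)
}

#' Transparent threshold fallback classifier
#'
#' Accepts a match when its RMSD is at most `maxRmsd` and the mean of
#' its six rank differences is at most `maxMeanDiff`. Provided as an
#' interpretable alternative to the SVM with the same feature
#' contract.
#'
#' @param maxRmsd RMSD acceptance bound in A (default 1.5).
#' @param maxMeanDiff mean percentile-difference bound (default 0.25).
#' @return a [MatchClassifier-class] of kind `"threshold"`.
#' @export
thresholdClassifier <- function(maxRmsd = 1.5, maxMeanDiff = 0.25) {
  new("MatchClassifier", fit = list(maxRmsd = maxRmsd,
                                    maxMeanDiff = maxMeanDiff),
      kind = "threshold",
      hyper = list(maxRmsd = maxRmsd, maxMeanDiff = maxMeanDiff),
      provenance = "rule: rmsd and mean rank difference thresholds")
}

#' @rdname classifyMatches
setMethod("classifyMatches", "MatchClassifier", function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (nrow(features) == 0L) return(logical(0))
  if (model@kind == "svm") {
    as.logical(stats::predict(model@fit, features))
  } else {
    features[, 1] <= model@fit$maxRmsd &
      rowMeans(features[, 2:7, drop = FALSE]) <= model@fit$maxMeanDiff
  }
})

#' Apply a significance classifier to scored matches
#'
#' Sets the `significant` slot of every match from the classifier's
#' decision on its feature vector.
#'
#' @param matches scored list of [TemplateMatch-class].
#' @param model a [MatchClassifier-class].
#' @return the matches with `significant` filled.
#' @export
flagSignificant <- function(matches, model) {
  if (length(matches) == 0L) return(matches)
  sig <- classifyMatches(model, matchFeatureMatrix(matches))
  mapply(function(m, s) { m@significant <- s; m }, matches, sig,
         SIMPLIFY = FALSE)
}

#' Reciprocal match pairs
#'
#' A protein pair \{A, B\} is reciprocal when some significant match
#' runs A -> B *and* some significant match runs B -> A (any template
#' on either side suffices). The two argument lists are pooled, so
#' the result is independent of which direction is passed first.
#'
#' @param fwd,rev lists of classified [TemplateMatch-class] (typically
#'   the two directions).
#' @return data.frame with columns `a`, `b` (sorted within pair and by
#'   pair), and per-direction best statistics `rmsdAB`, `etAB`,
#'   `rmsdBA`, `etBA`, plus `rmsd`/`etScore` of the overall
#'   minimum-RMSD significant match of the pair.
#' @export
reciprocalMatches <- function(fwd, rev = list()) {
  pool <- c(fwd, rev)
  pool <- Filter(function(m) isTRUE(m@significant), pool)
  if (length(pool) == 0L)
    return(data.frame(a = character(0), b = character(0),
                      rmsdAB = numeric(0), etAB = numeric(0),
                      rmsdBA = numeric(0), etBA = numeric(0),
                      rmsd = numeric(0), etScore = numeric(0)))
  qs <- vapply(pool, function(m) m@queryChain, character(1))
  ts <- vapply(pool, function(m) m@targetChain, character(1))
  dirKeys <- paste(qs, ts, sep = "\r")
  a <- pmin(qs, ts); b <- pmax(qs, ts)
  pairKeys <- unique(paste(a, b, sep = "\r"))
  rows <- lapply(pairKeys, function(key) {
    ab <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    iFwd <- which(qs == ab[1L] & ts == ab[2L])
    iRev <- which(qs == ab[2L] & ts == ab[1L])
    if (length(iFwd) == 0L || length(iRev) == 0L) return(NULL)
    pick <- function(i) {
      r <- vapply(pool[i], function(m) m@rmsd, numeric(1))
      j <- i[which.min(r)]
      c(pool[[j]]@rmsd, pool[[j]]@etScore)
    }
    fw <- pick(iFwd); rv <- pick(iRev)
    best <- if (fw[1] <= rv[1]) fw else rv
    data.frame(a = ab[1L], b = ab[2L], rmsdAB = fw[1], etAB = fw[2],
               rmsdBA = rv[1], etBA = rv[2], rmsd = best[1],
               etScore = best[2])
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    return(data.frame(a = character(0), b = character(0),
                      rmsdAB = numeric(0), etAB = numeric(0),
                      rmsdBA = numeric(0), etBA = numeric(0),
                      rmsd = numeric(0), etScore = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$a, out$b), , drop = FALSE]
}
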