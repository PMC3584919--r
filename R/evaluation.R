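#' Score predictions against truth
#'
#' A prediction is a true positive when the predicted EC agrees with
#' some true EC of the query at all four fields, a false positive
#' when it disagrees, and a false negative when the query received no
#' prediction. Accuracy = TP/(TP+FP) (0 with a warning when nothing
#' was predicted); Sensitivity = TP/(TP+FN), following the printed
#' convention in which false positives do not enter the sensitivity
#' denominator -- `coverage = (TP+FP)/N` is reported alongside for
#' the complementary reading.
#'
#' @param predictions data.frame with columns `query` and `label`
#'   (`NA` = no prediction; comma-joined labels count as correct when
#'   any agrees).
#' @param truth an [AnnotationTable-class]; every query must appear.
#' @param beta F-measure weight (default 0.5, emphasizing accuracy).
#' @return list with `TP`, `FP`, `FN`, `accuracy`, `sensitivity`,
#'   `coverage`, `fMeasure` and the per-query `tags` vector
#'   (`"correct"`, `"incorrect"`, `"none"`).
#' @export
scorePredictions <- function(predictions, truth, beta = 0.5) {
  missing <- setdiff(predictions$query, chainIds(truth))
  if (length(missing))
    stop("no truth annotation for: ", paste(missing, collapse = ", "))
  tags <- vapply(seq_len(nrow(predictions)), function(i) {
    lab <- predictions$label[i]
    if (is.na(lab)) return("none")
    labs <- strsplit(lab, ",", fixed = TRUE)[[1L]]
    if (any(labs %in% ecOf(truth, predictions$query[i]))) "correct"
    else "incorrect"
  }, character(1))
  tp <- sum(tags == "correct")
  fp <- sum(tags == "incorrect")
  fn <- sum(tags == "none")
  if (tp + fp == 0L) {
    warning("no predictions made; accuracy undefined, reported as 0")
    acc <- 0
  } else acc <- tp / (tp + fp)
  sens <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  list(TP = tp, FP = fp, FN = fn, accuracy = acc, sensitivity = sens,
       coverage = (tp + fp) / nrow(predictions),
       fMeasure = fMeasure(acc, sens, beta = beta),
       tags = stats::setNames(tags, predictions$query))
}

#' Weighted F-measure of accuracy and sensitivity
#'
#' `F = (1 + beta^2) * accuracy * sensitivity /
#' (beta^2 * accuracy + sensitivity)`, with `beta = 0.5` by default
#' to weight accuracy more than sensitivity. Returns 0 when both
#' inputs are 0.
#'
#' @param accuracy,sensitivity values in \[0, 1\].
#' @param beta weighting parameter (default 0.5).
#' @return the F-measure in \[0, 1\].
#' @examples
#' fMeasure(0.9, 0.5)  # 0.77586...
#' @export
fMeasure <- function(accuracy, sensitivity, beta = 0.5) {
  stopifnot(accuracy >= 0, accuracy <= 1,
            sensitivity >= 0, sensitivity <= 1)
  if (accuracy == 0 && sensitivity == 0) return(0)
  (1 + beta^2) * accuracy * sensitivity /
    (beta^2 * accuracy + sensitivity)
}

#' Agreement between two prediction tag vectors
#'
#' Each query carries one of three tags -- correct, incorrect, or no
#' prediction -- under each method; the similarity is the fraction of
#' queries with identical tags (a normalized scalar product of
#' indicator vectors). Symmetric, reflexive (diagonal 1), bounded in
#' \[0, 1\].
#'
#' @param tags1,tags2 character vectors of equal length over
#'   `{"correct", "incorrect", "none"}`.
#' @return agreement fraction in \[0, 1\].
#' @export
predictionSimilarity <- function(tags1, tags2) {
  if (length(tags1) != length(tags2))
    stop("tag vectors must have equal length")
  if (length(tags1) == 0L) stop("empty tag vectors")
  allowed <- c("correct", "incorrect", "none")
  if (!all(tags1 %in% allowed) || !all(tags2 %in% allowed))
    stop("tags must be 'correct', 'incorrect' or 'none'")
  mean(tags1 == tags2)
}

#' Accuracy-sensitivity sweep over confidence and its AUC
#'
#' Sorts confident predictions by descending z; at each distinct z
#' threshold, predictions below the threshold are treated as
#' abstentions and (sensitivity, accuracy) is recomputed. The curve
#' is anchored at sensitivity 0 with the accuracy of the single top
#' prediction, and the AUC is the trapezoid over sensitivity. The
#' AUC is invariant to strictly monotone transforms of z.
#'
#' @param predictions data.frame with `query`, `label`, `z` (all z
#'   present).
#' @param truth an [AnnotationTable-class].
#' @return list with `points` (data.frame `threshold`, `sensitivity`,
#'   `accuracy`) and `auc`.
#' @export
rocSweep <- function(predictions, truth) {
  if (nrow(predictions) == 0L) stop("no predictions to sweep")
  if (anyNA(predictions$z)) stop("all predictions must carry a z value")
  n <- nrow(predictions)
  correct <- vapply(seq_len(n), function(i) {
    lab <- predictions$label[i]
    !is.na(lab) &&
      any(strsplit(lab, ",", fixed = TRUE)[[1L]] %in%
            ecOf(truth, predictions$query[i]))
  }, logical(1))
  thresholds <- sort(unique(predictions$z), decreasing = TRUE)
  pts <- lapply(thresholds, function(th) {
    keep <- predictions$z >= th
    tp <- sum(correct & keep)
    fp <- sum(!correct & keep)
    fn <- n - tp - fp  # below threshold = abstention
    data.frame(threshold = th,
               sensitivity = if (tp + fn == 0) 0 else tp / (tp + fn),
               accuracy = if (tp + fp == 0) 0 else tp / (tp + fp))
  })
  pts <- do.call(rbind, pts)
  anchor <- data.frame(threshold = Inf, sensitivity = 0,
                       accuracy = pts$accuracy[1L])
  curve <- rbind(anchor, pts)
  curve <- curve[order(curve$sensitivity), , drop = FALSE]
  xs <- curve$sensitivity; ys <- curve$accuracy
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  list(points = pts, auc = auc)
}
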