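mkMatch <- function(q = "aA", t = "bA", rmsd = 0.5,
                    diffs = rep(0.05, 6)) {
  new("TemplateMatch", queryChain = q, targetChain = t,
      templatePositions = seq_along(diffs),
      matchedPositions = seq_along(diffs) + 100L, rmsd = rmsd,
      rankDiffs = diffs, etScore = sum(diffs),
      direction = paste0(q, "->", t), significant = NA)
}

test_that("prefilter removes self-matches and rmsd > 2 strictly", {
  ms <- list(mkMatch(rmsd = 2.0),            # exactly 2: kept
             mkMatch("aA", "aA", rmsd = 0),  # self: removed
             mkMatch(rmsd = 2.001),          # removed
             mkMatch(rmsd = 1.2),
             mkMatch(rmsd = 3.5))
  kept <- prefilterMatches(ms)
  expect_length(kept, 2L)
  # predicate oracle and idempotence
  oracle <- Filter(function(m) m@queryChain != m@targetChain &&
                     m@rmsd <= 2, ms)
  expect_identical(kept, oracle)
  expect_identical(prefilterMatches(kept), kept)
})

test_that("featurization builds the 7-vector with the virtual residue", {
  perfect <- mkMatch(rmsd = 0.4, diffs = rep(0, 6))
  expect_equal(unname(matchFeatures(perfect)), c(0.4, rep(0, 6)))
  five <- mkMatch(rmsd = 1, diffs = c(0.1, 0.1, 0.1, 0.1, 0.6))
  f5 <- matchFeatures(five)
  expect_equal(unname(f5[7]), 0.2)   # virtual sixth = mean of the five
  six <- mkMatch(rmsd = 1, diffs = c(0.05, 0.1, 0, 0.2, 0.15, 0.1))
  expect_equal(sum(matchFeatures(six)[2:7]), six@etScore)
})

test_that("SVM separates planted from decoy matches and is deterministic", {
  tr <- generateSvmTraining(fixtureSpec(nProteins = 12, nFunctions = 3,
                                        seed = 99), nTrue = 60, nFalse = 60)
  expect_identical(sum(tr$labels), 60L)
  expect_identical(sum(!tr$labels), 60L)
  expect_true(all(tr$features[, "rmsd"] >= 0))
  expect_true(all(tr$features[, 2:7] >= 0 & tr$features[, 2:7] <= 1))
  model <- trainedSvm()
  pred <- classifyMatches(model, tr$features)
  expect_equal(mean(pred == tr$labels), 1)   # separable by construction
  expect_identical(pred, classifyMatches(model, tr$features))
  expect_error(trainMatchSvm(tr$features, rep(TRUE, nrow(tr$features))),
               "both")
})

test_that("label shuffling destroys cross-validated accuracy", {
  tr <- generateSvmTraining(fixtureSpec(nProteins = 12, nFunctions = 3,
                                        seed = 99), nTrue = 60, nFalse = 60)
  set.seed(500)
  shuffled <- sample(tr$labels)
  y <- factor(shuffled, levels = c(FALSE, TRUE))
  set.seed(501)
  fit <- e1071::svm(tr$features, y, kernel = "radial", cost = 10,
                    gamma = 0.2, scale = TRUE, cross = 5)
  expect_lt(abs(fit$tot.accuracy / 100 - 0.5), 0.15)
})

test_that("increasing rmsd alone never turns a rejection into an accept", {
  model <- trainedSvm()
  base <- c(0.3, rep(0.04, 6))
  sweep <- t(vapply(seq(0, 3, by = 0.1), function(r) {
    v <- base; v[1] <- r; v
  }, numeric(7)))
  colnames(sweep) <- c("rmsd", paste0("r", 1:6))
  dec <- classifyMatches(model, sweep)
  expect_false(any(diff(dec) > 0))  # monotone non-increasing decisions
})

test_that("threshold fallback classifier applies its stated rule", {
  rule <- thresholdClassifier(maxRmsd = 1.5, maxMeanDiff = 0.25)
  f <- rbind(c(1.4, rep(0.2, 6)), c(1.6, rep(0.2, 6)),
             c(1.0, rep(0.3, 6)))
  colnames(f) <- c("rmsd", paste0("r", 1:6))
  expect_identical(classifyMatches(rule, f), c(TRUE, FALSE, FALSE))
})

test_that("reciprocity requires significance in both directions", {
  sig <- function(m) { m@significant <- TRUE; m }
  ab <- sig(mkMatch("aA", "bA", 0.5))
  ba <- sig(mkMatch("bA", "aA", 0.7))
  cb <- sig(mkMatch("cA", "bA", 0.4))  # one-directional only
  rec <- reciprocalMatches(list(ab, cb), list(ba))
  expect_identical(rec$a, "aA")
  expect_identical(rec$b, "bA")
  expect_equal(rec$rmsd, 0.5)          # overall minimum-RMSD statistics
  # symmetric in argument order
  rec2 <- reciprocalMatches(list(ba), list(ab, cb))
  expect_identical(rec[c("a", "b", "rmsd", "etScore")],
                   rec2[c("a", "b", "rmsd", "etScore")])
  expect_identical(nrow(reciprocalMatches(list(), list())), 0L)
  # an insignificant reverse match does not make a pair
  baBad <- mkMatch("bA", "aA", 0.7); baBad@significant <- FALSE
  expect_identical(nrow(reciprocalMatches(list(ab), list(baBad))), 0L)
})

test_that("multiple templates can only widen the reciprocal pair set", {
  train <- trainedSvm()
  bench <- generateBenchmark(fixtureSpec(nProteins = 12, nFunctions = 3,
                                         sitesPerProtein = 2,
                                         decoyResidues = 26,
                                         primaryAbsentFraction = 0.25,
                                         seed = 23))
  r6 <- runMode(bench$dataset, mode = "6R", model = train)
  rM <- runMode(bench$dataset, mode = "M6R", model = train)
  pairKey <- function(res) if (is.null(res$pairs)) character(0)
             else unique(paste(res$pairs$a, res$pairs$b))
  expect_true(all(pairKey(r6) %in% pairKey(rM)))
})
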