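test_that("plurality voting counts unique partners once and abstains on ties", {
  single <- pluralityVote("3f0nA", list(`2hk3B` = "4.1.1.33"))
  expect_identical(single$label, "4.1.1.33")
  expect_identical(single$votes, 1L)
  multi <- pluralityVote("3f0nA", list(`2hk3B` = "4.1.1.33",
                                       `3d4jB` = "4.1.1.33"), "M6R")
  expect_identical(multi$label, "4.1.1.33")
  expect_identical(multi$votes, 2L)
  # four-against-four tie: no prediction
  partners <- c(setNames(as.list(rep("1.1.1.1", 4)), paste0("x", 1:4)),
                setNames(as.list(rep("1.1.1.2", 4)), paste0("y", 1:4)))
  tie <- pluralityVote("2b83A", partners)
  expect_true(is.na(tie$label))
  expect_identical(tie$votes, 4L)
  # the same partner via several templates still casts one vote
  dup <- pluralityVote("qA", list(pA = "1.2.3.4", pA = "1.2.3.4",
                                  pA = "1.2.3.4"))
  expect_identical(dup$votes, 1L)
  # invariant to partner order
  expect_identical(pluralityVote("qA", rev(partners))$label, tie$label)
  expect_identical(pluralityVote("qA", list())$votes, 0L)
})

test_that("planted single-site benchmark is annotated perfectly by 6R", {
  model <- trainedSvm()
  bench <- generateBenchmark(fixtureSpec(nProteins = 12, nFunctions = 3,
                                         seed = 29))
  res <- runMode(bench$dataset, mode = "6R", model = model)
  sc <- scorePredictions(res$predictions, bench$truth)
  expect_equal(sc$accuracy, 1)
  expect_equal(sc$sensitivity, 1)
  # every query found its 3 same-function partners
  expect_true(all(res$predictions$votes == 3L))
})

test_that("geometrically unrelated proteins yield no predictions", {
  model <- trainedSvm()
  # every protein its own function: no shared motifs anywhere
  bench <- generateBenchmark(fixtureSpec(nProteins = 6, nFunctions = 6,
                                         seed = 41))
  res <- runMode(bench$dataset, mode = "6R", model = model)
  expect_true(all(is.na(res$predictions$label)))
})

test_that("secondary sites rescue queries whose primary site is private", {
  model <- trainedSvm()
  bench <- generateBenchmark(fixtureSpec(nProteins = 8, nFunctions = 2,
                                         sitesPerProtein = 2,
                                         decoyResidues = 26,
                                         primaryAbsentFraction = 0.25,
                                         seed = 31))
  affected <- bench$manifest$affected
  expect_gt(length(affected), 0L)
  r6 <- runMode(bench$dataset, mode = "6R", model = model)
  rM <- runMode(bench$dataset, mode = "M6R", model = model)
  p6 <- r6$predictions; pM <- rM$predictions
  expect_true(all(is.na(p6$label[p6$query %in% affected])))
  expect_false(any(is.na(pM$label[pM$query %in% affected])))
  truthEc <- vapply(affected, function(q) ecOf(bench$truth, q),
                    character(1))
  expect_identical(pM$label[match(affected, pM$query)], unname(truthEc))
})

test_that("iterative combination backfills abstentions in stated order", {
  p6 <- data.frame(query = c("q1", "q2", "q3"), mode = "6R",
                   label = c("1.1.1.1", NA, NA), votes = c(2L, 0L, 0L),
                   runnerUpVotes = 0L, stringsAsFactors = FALSE)
  p5 <- data.frame(query = c("q1", "q2", "q3"), mode = "5R",
                   label = c("9.9.9.9", "2.2.2.2", NA),
                   votes = c(1L, 1L, 0L), runnerUpVotes = 0L,
                   stringsAsFactors = FALSE)
  comb <- iterativeCombine(list(`6R` = p6, `5R` = p5))
  expect_identical(comb$label, c("1.1.1.1", "2.2.2.2", NA))
  expect_identical(comb$sourceMode, c("6R", "5R", NA))
  expect_true(all(comb$mode == "ALL"))
  # single-mode order reproduces that mode's labels
  only6 <- iterativeCombine(list(`6R` = p6), order = "6R")
  expect_identical(only6$label, p6$label)
  # combined coverage dominates every individual mode
  expect_gte(sum(!is.na(comb$label)), sum(!is.na(p6$label)))
  expect_gte(sum(!is.na(comb$label)), sum(!is.na(p5$label)))
})

test_that("sequence identity counts identical aligned non-gap positions", {
  expect_equal(sequenceIdentity("ACDE", "ACDE"), 1)
  expect_equal(sequenceIdentity("ACDE", "ACDF"), 0.75)
  expect_equal(sequenceIdentity("PAWHEAE", "PAWHEAE"), 1)
})

test_that("SeqID baseline transfers the closest target's annotation", {
  set.seed(51)
  seqA <- paste(sample(c("A", "C", "D", "E", "F", "G", "H"), 40,
                       replace = TRUE), collapse = "")
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    i <- sample(length(v), k)
    v[i] <- sample(c("K", "L", "M", "N"), k, replace = TRUE)
    paste(v, collapse = "")
  }
  mkChain <- function(id, s) {
    v <- strsplit(s, "")[[1]]
    newProteinChain(id, seq_along(v), v,
                    cbind(seq_along(v) * 3.8, 0, 0))
  }
  chains <- list(qA = mkChain("qA", seqA),
                 tA = mkChain("tA", mut(seqA, 2)),   # near-identical
                 dA = mkChain("dA", mut(seqA, 30)))  # heavily mutated
  surf <- lapply(chains, approximateAccessibility)
  rks <- lapply(chains, function(ch)
    newETRanking(chainId(ch), residueNumbers(ch),
                 seq_along(residueNumbers(ch))))
  ds <- etaDataset(chains, rks, surf,
                   annotationTable(list(tA = "7.7.7.7", dA = "8.8.8.8")))
  pred <- seqidBaseline(ds, queries = "qA", targets = c("tA", "dA"))
  expect_identical(pred$label, "7.7.7.7")
  expect_gt(pred$identity, 0.9)
  empty <- seqidBaseline(ds, queries = "qA", targets = character(0))
  expect_true(is.na(empty$label))
})
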