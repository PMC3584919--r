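test_that("edge weights standardize both match statistics and stay positive", {
  edges <- data.frame(a = c("n1", "n3"), b = c("n2", "n4"),
                      rmsd = c(1, 2), etScore = c(4, 8))
  net <- networkFromEdges(paste0("n", 1:4), edges)
  # hand z-scores with population sd: s = {-1, +1}, W = {e, 1/e}
  expect_equal(net@edges$s, c(-1, 1))
  expect_equal(net@edges$w, c(exp(1), exp(-1)))
  expect_equal(mean(net@edges$s), 0)
  expect_equal(net@W["n1", "n2"], exp(1))
  expect_equal(net@W, t(net@W))
  # match sitting at both means: s = 0, W = 1
  edges3 <- rbind(edges, data.frame(a = "n1", b = "n3", rmsd = 1.5,
                                    etScore = 6))
  net3 <- networkFromEdges(paste0("n", 1:4), edges3)
  expect_equal(net3@edges$w[3], 1)
  # strictly better on both statistics => strictly larger weight
  expect_gt(net3@edges$w[1], net3@edges$w[3])
  # degenerate spread errors, unit transform is the advertised fallback
  one <- edges[1, , drop = FALSE]
  expect_error(networkFromEdges(c("n1", "n2"), one), "unit")
  expect_equal(networkFromEdges(c("n1", "n2"), one,
                                weightTransform = "unit")@edges$w, 1)
  expect_error(networkFromEdges("n1", data.frame(a = "n1", b = "n1",
                                                 rmsd = 1, etScore = 1)),
               "self-edges")
})

test_that("diffusion solves the regularized-Laplacian system exactly", {
  W <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(diffuseLabels(W, c(1, 0), alpha = 1), c(2 / 3, 1 / 3))
  # alpha -> 0 recovers the labels
  y <- c(1, -1, 0, 0)
  W4 <- randomGraph(4); set.seed(61); W4 <- randomGraph(4)
  expect_equal(diffuseLabels(W4, y, alpha = 1e-9), y, tolerance = 1e-6)
  # constant labels are a fixed point on any graph
  expect_equal(diffuseLabels(W4, rep(1, 4), alpha = 3), rep(1, 4))
  expect_error(diffuseLabels(matrix(c(0, 1, 0, 0), 2), c(1, 0)),
               "symmetric")
})

test_that("diffusion equals a generic numerical minimizer of H", {
  set.seed(62)
  for (rep in 1:25) {
    n <- sample(3:20, 1)
    W <- randomGraph(n)
    y <- sample(c(-1, 0, 1), n, replace = TRUE)
    alpha <- sample(c(0.1, 1, 10), 1)
    f <- diffuseLabels(W, y, alpha)
    expect_equal(f, minimizeH(y, W, alpha), tolerance = 1e-6)
    # the solve's objective is no worse than any random perturbation
    expect_lte(objectiveH(f, y, W, alpha),
               objectiveH(f + rnorm(n, sd = 0.05), y, W, alpha))
  }
})

test_that("diffusion is equivariant under node relabeling", {
  set.seed(63)
  n <- 12
  W <- randomGraph(n)
  y <- sample(c(-1, 0, 1), n, replace = TRUE)
  p <- sample(n)
  f <- diffuseLabels(W, y, 0.7)
  fp <- diffuseLabels(W[p, p], y[p], 0.7)
  expect_equal(fp, f[p])
})

test_that("strengthening a tie to a labeled node raises the diffused score", {
  set.seed(64)
  W <- randomGraph(8, density = 0.5)
  y <- c(1, rep(0, 7))
  f0 <- diffuseLabels(W, y, 1)
  for (w in c(0.5, 1, 2)) {
    W2 <- W
    W2[1, 5] <- W2[5, 1] <- W[1, 5] + w
    expect_gte(diffuseLabels(W2, y, 1)[5], f0[5])
  }
})

test_that("confidence z-scores standardize over unknown nodes only", {
  f <- c(0.9, 0.2, 0.4, -0.5)
  unknown <- c(FALSE, TRUE, TRUE, FALSE)
  expect_equal(confidenceZ(f, unknown), c(-1, 1))  # hand z, population sd
  set.seed(65)
  f2 <- rnorm(10)
  u <- rep(TRUE, 10)
  z <- confidenceZ(f2, u)
  expect_equal(mean(z), 0)
  expect_equal(popSd(z), 1)
  expect_warning(zc <- confidenceZ(rep(0.3, 5), rep(TRUE, 5)), "constant")
  expect_equal(zc, rep(0, 5))
  expect_error(confidenceZ(f, c(FALSE, TRUE, FALSE, FALSE)), "at least 2")
})

test_that("competitive diffusion assigns the attached clique's label", {
  # two labeled cliques; unknown node u1 attached to clique A only
  nodes <- c("u1", "u2", paste0("a", 1:3), paste0("b", 1:3))
  edges <- rbind(
    expand.grid(a = paste0("a", 1:3), b = paste0("a", 1:3)),
    expand.grid(a = paste0("b", 1:3), b = paste0("b", 1:3)))
  edges <- edges[as.character(edges$a) < as.character(edges$b), ]
  edges$rmsd <- 0.5; edges$etScore <- 0.4
  edges <- rbind(edges,
                 data.frame(a = "u1", b = "a1", rmsd = 0.4, etScore = 0.3),
                 data.frame(a = "u2", b = "b1", rmsd = 1.4, etScore = 1.2))
  ann <- annotationTable(c(setNames(as.list(rep("1.1.1.1", 3)),
                                    paste0("a", 1:3)),
                           setNames(as.list(rep("2.2.2.2", 3)),
                                    paste0("b", 1:3))))
  net <- networkFromEdges(nodes, edges, ann)
  res <- competitiveDiffusion(net, alpha = 1)
  pred <- diffusionPredictions(res)
  expect_identical(pred$label[pred$query == "u1"], "1.1.1.1")
  expect_identical(pred$label[pred$query == "u2"], "2.2.2.2")
  # z-scores over unknowns are standardized per function
  expect_equal(mean(res@z[res@unknown, 1]), 0)
  expect_equal(popSd(res@z[res@unknown, 1]), 1)
})

test_that("edge weights break exact voting ties toward the stronger side", {
  fix <- generateTieNetwork()
  # template voting abstains on every tied query
  for (q in fix$queries)
    expect_true(is.na(pluralityVote(q, fix$partners)$label))
  res <- competitiveDiffusion(fix$network, alpha = 1)
  pred <- diffusionPredictions(res)
  pred <- pred[pred$query %in% fix$queries, ]
  truth <- vapply(pred$query, function(q) ecOf(fix$truth, q), character(1))
  expect_false(anyNA(pred$label))
  expect_identical(pred$label, unname(truth))
})

test_that("confidence bands report cumulative accuracy at-or-above z", {
  pred <- data.frame(query = paste0("q", 1:6),
                     label = c("1.1.1.1", "1.1.1.1", "2.2.2.2", "1.1.1.1",
                               "2.2.2.2", "2.2.2.2"),
                     z = c(3, 2.5, 1.2, 0.8, 0.4, -0.5))
  truth <- annotationTable(setNames(
    as.list(c("1.1.1.1", "1.1.1.1", "1.1.1.1", "1.1.1.1", "2.2.2.2",
              "9.9.9.9")), paste0("q", 1:6)))
  bands <- confidenceBands(pred, truth, thresholds = c(2, 0.5))
  expect_equal(bands$n, c(2L, 4L))
  expect_equal(bands$accuracy, c(1, 3 / 4))
})
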