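# Independent oracles and small builders used across the suite.

# Independent superposition-RMSD oracle: Horn's closed-form quaternion
# solution via the eigen-decomposition of the 4x4 key matrix (no SVD,
# no shared code with the packaged Kabsch fit; proper rotations only).
kabschRmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  S <- t(ac) %*% bc
  N <- rbind(
    c(S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2],
      S[3, 1] - S[1, 3], S[1, 2] - S[2, 1]),
    c(S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3],
      S[1, 2] + S[2, 1], S[3, 1] + S[1, 3]),
    c(S[3, 1] - S[1, 3], S[1, 2] + S[2, 1],
      -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2]),
    c(S[1, 2] - S[2, 1], S[3, 1] + S[1, 3],
      S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]))
  lmax <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, sum(ac^2) + sum(bc^2) - 2 * lmax) / nrow(a))
}

# exhaustive paired-distance enumeration: every ordered, injective,
# type-compatible tuple checked against ALL pairwise distances
bruteForcePdm <- function(template, target, tol = 2.5) {
  k <- length(template@positions)
  tmplD <- as.matrix(dist(template@coords))
  targD <- as.matrix(dist(target@coords))
  cand <- lapply(template@allowedTypes, function(ty)
    which(target@aa %in% ty))
  if (any(lengths(cand) == 0L)) return(character(0))
  grid <- as.matrix(expand.grid(cand, KEEP.OUT.ATTRS = FALSE))
  keep <- apply(grid, 1L, function(idx) {
    if (anyDuplicated(idx)) return(FALSE)
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      if (abs(targD[idx[i], idx[j]] - tmplD[i, j]) > tol) return(FALSE)
    }
    TRUE
  })
  apply(grid[keep, , drop = FALSE], 1L, function(idx)
    paste(target@resno[idx], collapse = ","))
}

assignmentKeys <- function(matches) {
  vapply(matches, function(m) paste(m@matchedPositions, collapse = ","),
         character(1))
}

# random toy chain: n residues, small type alphabet, coords in a box
randomToyChain <- function(n, id = "toyA", alphabet = c("A", "C", "D", "E"),
                           box = 20) {
  newProteinChain(id, seq_len(n), sample(alphabet, n, replace = TRUE),
                  matrix(runif(3 * n, 0, box), n, 3))
}

randomToyTemplate <- function(size = 5L, alphabet = c("A", "C", "D", "E"),
                              source = "tplA") {
  coords <- matrix(runif(3 * size, 0, 12), size, 3)
  types <- sample(alphabet, size, replace = TRUE)
  allowed <- lapply(types, function(t)
    unique(c(t, sample(alphabet, sample(0:1, 1)))))
  new("Template", sourceChain = source, modeTag = "5R",
      positions = seq_len(size), coords = coords, nativeTypes = types,
      allowedTypes = allowed)
}

popSd <- function(x) sqrt(mean((x - mean(x))^2))

# quadratic diffusion objective; pairwise term over unordered pairs
objectiveH <- function(f, y, W, alpha) {
  ut <- upper.tri(W)
  sum((f - y)^2) + alpha * sum(W[ut] * (outer(f, f, "-")[ut])^2)
}

minimizeH <- function(y, W, alpha) {
  gr <- function(f, y, W, alpha) {
    L <- diag(rowSums(W)) - W
    2 * (f - y) + 2 * alpha * as.numeric(L %*% f)
  }
  optim(y, objectiveH, gr, y = y, W = W, alpha = alpha,
        method = "BFGS",
        control = list(maxit = 2000, reltol = 1e-15))$par
}

randomGraph <- function(n, density = 0.4) {
  W <- matrix(0, n, n)
  m <- n * (n - 1) / 2
  w <- runif(m) * (runif(m) < density)
  W[upper.tri(W)] <- w
  W + t(W)
}

# shared small training fixture for the match SVM (built once per run)
trainedSvm <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      tr <- generateSvmTraining(
        fixtureSpec(nProteins = 12, nFunctions = 3, seed = 99),
        nTrue = 60, nFalse = 60)
      model <<- trainMatchSvm(tr$features, tr$labels)
    }
    model
  }
})
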