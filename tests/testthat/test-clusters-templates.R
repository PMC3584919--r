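allSurface <- function(id, resno)
  new("SurfaceAnnotation", chainId = id, resno = resno,
      area = rep(10, length(resno)))

test_that("single-linkage clusters match brute-force transitive closure", {
  # one tight group
  set.seed(21)
  xyz <- matrix(runif(18, 0, 6), 6, 3)
  ch <- newProteinChain("clA", 1:6, rep("A", 6), xyz)
  rk <- newETRanking("clA", 1:6, 1:6)
  cls <- identifyClusters(ch, rk, allSurface("clA", 1:6), coverage = 1)
  expect_length(cls, 1L)
  expect_identical(cls[[1]]@members, 1:6)
  expect_equal(cls[[1]]@cm, colMeans(xyz))
  # two groups 50 A apart: rank-1 group first
  xyz2 <- rbind(xyz, sweep(xyz, 2, c(50, 0, 0), "+"))
  ch2 <- newProteinChain("clB", 1:12, rep("A", 12), xyz2)
  rk2 <- newETRanking("clB", 1:12, c(7:12, 1:6))  # best ranks in far group
  cls2 <- identifyClusters(ch2, rk2, allSurface("clB", 1:12), coverage = 1)
  expect_length(cls2, 2L)
  expect_identical(cls2[[1]]@members, 7:12)
  # random points vs union-find oracle over the <= 8 A relation
  for (rep in 1:5) {
    n <- 30
    pts <- matrix(runif(3 * n, 0, 25), n, 3)
    chr <- newProteinChain("clC", 1:n, rep("A", n), pts)
    rkr <- newETRanking("clC", 1:n, sample(n))
    cls <- identifyClusters(chr, rkr, allSurface("clC", 1:n), 1,
                            linkCutoff = 8)
    # oracle: transitive closure by repeated boolean matrix products
    adj <- as.matrix(dist(pts)) <= 8
    reach <- adj
    for (k in 1:n) reach <- reach | (reach %*% adj > 0)
    oracleComp <- apply(reach, 1, function(r) min(which(r)))
    got <- integer(n)
    for (i in seq_along(cls)) got[cls[[i]]@members] <- i
    expect_equal(length(unique(oracleComp)), length(cls))
    expect_true(all(tapply(oracleComp, got, function(x)
      length(unique(x))) == 1))
  }
})

test_that("cluster membership grows monotonically with coverage", {
  set.seed(31)
  n <- 40
  ch <- newProteinChain("mcA", 1:n, rep("A", n),
                        matrix(runif(3 * n, 0, 30), n, 3))
  rk <- newETRanking("mcA", 1:n, sample(n))
  surf <- allSurface("mcA", 1:n)
  prev <- integer(0)
  for (cov in seq(0.1, 1, by = 0.1)) {
    members <- sort(unlist(lapply(
      identifyClusters(ch, rk, surf, cov), function(cl) cl@members)))
    expect_true(all(prev %in% members))
    prev <- members
  }
})

test_that("primary cluster appears at the smallest qualifying coverage", {
  bench <- generateBenchmark(fixtureSpec(nProteins = 2, nFunctions = 1,
                                         seed = 5))
  ds <- bench$dataset
  id <- chainIds(ds)[1]
  cl <- selectPrimaryCluster(ds@chains[[id]], ds@rankings[[id]],
                             ds@surfaces[[id]])
  expect_s4_class(cl, "ResidueCluster")
  # the planted 12-residue patch holds the top ranks; 11 of them become
  # important at rank coverage 11/32, i.e. the 0.35 grid step
  expect_length(cl@surfaceMembers, 11L)
  expect_equal(cl@formationThreshold, 0.35)
  expect_true(all(unlist(bench$manifest$sites[[id]][[1]]) %in% cl@members))
  # a chain with fewer than 11 surface residues can never qualify
  few <- newProteinChain("fsA", 1:10, rep("A", 10),
                         matrix(runif(30, 0, 6), 10, 3))
  rkf <- newETRanking("fsA", 1:10, 1:10)
  expect_null(selectPrimaryCluster(few, rkf, allSurface("fsA", 1:10)))
})

test_that("additional clusters demand non-overlap and better surface ranks", {
  bench <- generateBenchmark(fixtureSpec(nProteins = 2, nFunctions = 1,
                                         sitesPerProtein = 2,
                                         decoyResidues = 26, seed = 5))
  ds <- bench$dataset
  id <- chainIds(ds)[1]
  args <- list(ds@chains[[id]], ds@rankings[[id]], ds@surfaces[[id]])
  primary <- do.call(selectPrimaryCluster, args)
  expect_true(all(unlist(bench$manifest$sites[[id]][[1]]) %in%
                    primary@members))
  extra <- do.call(selectAdditionalClusters,
                   c(args, list(primary, minSurface = 6)))
  expect_length(extra, 1L)
  expect_true(all(unlist(bench$manifest$sites[[id]][[2]]) %in%
                    extra[[1]]@members))
  expect_length(intersect(extra[[1]]@members, primary@members), 0L)
  # interleaved ranks: the secondary indeed beats the primary's median
  expect_lt(min(rankOf(ds@rankings[[id]], extra[[1]]@surfaceMembers)),
            median(rankOf(ds@rankings[[id]], primary@surfaceMembers)))
  # under the strictest comparator (better than the primary's best,
  # i.e. the global rank 1) nothing can qualify
  expect_length(do.call(selectAdditionalClusters,
                        c(args, list(primary, comparator = "best"))), 0L)
})

test_that("template picker is deterministic, rank-first, prefix-stable", {
  # symmetric square of equal-rank corners + better-ranked centre
  xyz <- rbind(c(0, 0, 0), c(4, 4, 0), c(-4, 4, 0), c(-4, -4, 0),
               c(4, -4, 0), c(0, 8, 0))
  ch <- newProteinChain("sqA", 1:6, c("A", "C", "D", "E", "F", "G"), xyz)
  rk <- newETRanking("sqA", 1:6, c(1, 2, 2, 2, 2, 3))
  cl <- identifyClusters(ch, rk, allSurface("sqA", 1:6), 1,
                         linkCutoff = 10)[[1]]
  tpl <- pickTemplate(cl, ch, rk, 5L)
  expect_identical(tpl@positions[1], 1L)            # best rank at centre
  # corners tie on rank and on distance to the midpoint: resno breaks it
  expect_identical(tpl@positions, c(1L, 2L, 3L, 4L, 5L))
  expect_identical(pickTemplate(cl, ch, rk, 5L)@positions, tpl@positions)
  tpl6 <- pickTemplate(cl, ch, rk, 6L)
  expect_identical(tpl6@positions[1:5], tpl@positions)
  # exhaustion: 5-member cluster yields its 5 members
  cl5 <- identifyClusters(newProteinChain("exA", 1:5, rep("A", 5),
                                          xyz[1:5, ]),
                          newETRanking("exA", 1:5, 1:5),
                          allSurface("exA", 1:5), 1, linkCutoff = 10)[[1]]
  expect_error(pickTemplate(cl5, ch, rk, 6L), "cannot pick")
})

test_that("five-residue templates are prefixes of six-residue ones", {
  bench <- generateBenchmark(fixtureSpec(nProteins = 6, nFunctions = 2,
                                         seed = 13))
  ds <- bench$dataset
  for (id in chainIds(ds)) {
    t5 <- makeTemplates(ds@chains[[id]], ds@rankings[[id]],
                        ds@surfaces[[id]], "5R")
    t6 <- makeTemplates(ds@chains[[id]], ds@rankings[[id]],
                        ds@surfaces[[id]], "6R")
    expect_identical(t5[[1]]@positions, t6[[1]]@positions[1:5])
  }
})

test_that("MSA variants require non-gapped patterns seen at least twice", {
  ch <- newProteinChain("msA", 1:6, c("A", "C", "D", "E", "F", "G"),
                        matrix(c(0, 0, 0, 4, 0, 0, 8, 0, 0, 0, 4, 0,
                                 4, 4, 0, 8, 4, 0), 6, 3, byrow = TRUE))
  rk <- newETRanking("msA", 1:6, 1:6)
  cl <- identifyClusters(ch, rk, allSurface("msA", 1:6), 1,
                         linkCutoff = 10)[[1]]
  tpl <- pickTemplate(cl, ch, rk, 5L)
  # rows all equal to native: no widening
  msaSame <- Biostrings::AAStringSet(rep("ACDEFG", 4))
  same <- templateTypeVariants(tpl, msaSame, ch)
  expect_identical(same@allowedTypes, as.list(same@nativeTypes))
  # S at position 1 in 3 rows -> allowed; T in 1 row -> not;
  # a gapped row never counts
  msa <- Biostrings::AAStringSet(c("ACDEFG", "SCDEFG", "SCDEFG", "SCDEFG",
                                   "TCDEFG", "S-DEFG"))
  wide <- templateTypeVariants(tpl, msa, ch)
  pos1 <- which(wide@positions == 1L)
  expect_true("S" %in% wide@allowedTypes[[pos1]])
  expect_false("T" %in% wide@allowedTypes[[pos1]])
})

test_that("multiple-template mode degenerates to single without extra sites", {
  bench <- generateBenchmark(fixtureSpec(nProteins = 2, nFunctions = 1,
                                         seed = 3))
  ds <- bench$dataset
  id <- chainIds(ds)[1]
  expect_length(makeTemplates(ds@chains[[id]], ds@rankings[[id]],
                              ds@surfaces[[id]], "M6R"), 1L)
  two <- generateBenchmark(fixtureSpec(nProteins = 2, nFunctions = 1,
                                       sitesPerProtein = 2,
                                       decoyResidues = 26, seed = 3))
  id2 <- chainIds(two$dataset)[1]
  ds2 <- two$dataset
  expect_length(makeTemplates(ds2@chains[[id2]], ds2@rankings[[id2]],
                              ds2@surfaces[[id2]], "M5R"), 2L)
  expect_length(makeTemplates(ds2@chains[[id2]], ds2@rankings[[id2]],
                              ds2@surfaces[[id2]], "6R"), 1L)
})
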