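#' Specification of a synthetic benchmark
#'
#' Describes a toy structure set with planted, geometry-shared
#' functional sites. Each function owns a rigid "site motif"
#' (`siteSize` C-alpha points with distinct residue types); every
#' protein of that function embeds the motif (randomly rotated,
#' translated, and jittered by N(0, jitterSigma) per coordinate)
#' surrounded by a halo of `patchSize - siteSize` nearby residues --
#' so a surface cluster of `patchSize` residues forms around the site
#' -- plus `decoyResidues` decoy residues kept at least `decoySep` A
#' from everything else. Evolutionary ranks put the site residues at
#' the top (motif order), the halo next, decoys last, each perturbed
#' by Uniform(0, rankNoise). With `sitesPerProtein = 2` a second
#' function-specific motif is planted and the two patches' ranks are
#' interleaved so the secondary cluster genuinely contains surface
#' residues ranked better than the primary's median.
#' `primaryAbsentFraction` replaces the primary-site motif of that
#' fraction of proteins with a private motif no other protein shares,
#' the regime in which only multiple-template matching can succeed.
#'
#' Identical specs generate bit-identical benchmarks.
#'
#' @param nProteins,nFunctions counts; proteins are assigned to
#'   functions round-robin.
#' @param siteSize residues per site motif (>= 5, default 6).
#' @param sitesPerProtein 1 or 2.
#' @param jitterSigma coordinate noise in A (default 0.2).
#' @param decoyResidues decoys per protein (default 20).
#' @param rankNoise rank perturbation amplitude (default 0.1).
#' @param seed RNG seed.
#' @param patchSize important-surface-patch size around each site
#'   (default 12, one more than the 11-residue cluster rule).
#' @param boxSide decoy placement box side in A (default 40).
#' @param decoySep minimum decoy separation in A (default 5).
#' @param primaryAbsentFraction fraction of proteins whose primary
#'   site is private (default 0).
#' @param buriedFraction fraction of decoys marked buried (default 0).
#' @return a `FixtureSpec` list.
#' @seealso [generateBenchmark()]
#' @export
fixtureSpec <- function(nProteins, nFunctions, siteSize = 6L,
                        sitesPerProtein = 1L, jitterSigma = 0.2,
                        decoyResidues = 20L, rankNoise = 0.1, seed = 1L,
                        patchSize = 12L, boxSide = 40,
                        decoySep = 5, primaryAbsentFraction = 0,
                        buriedFraction = 0) {
  stopifnot(nProteins >= 2, nFunctions >= 1, siteSize >= 5,
            sitesPerProtein %in% c(1L, 2L), jitterSigma >= 0,
            rankNoise >= 0, patchSize > siteSize,
            primaryAbsentFraction >= 0, primaryAbsentFraction <= 1)
  structure(list(nProteins = as.integer(nProteins),
                 nFunctions = as.integer(nFunctions),
                 siteSize = as.integer(siteSize),
                 sitesPerProtein = as.integer(sitesPerProtein),
                 jitterSigma = jitterSigma,
                 decoyResidues = as.integer(decoyResidues),
                 rankNoise = rankNoise, seed = as.integer(seed),
                 patchSize = as.integer(patchSize), boxSide = boxSide,
                 decoySep = decoySep,
                 primaryAbsentFraction = primaryAbsentFraction,
                 buriedFraction = buriedFraction),
            class = "FixtureSpec")
}

# proper rotation matrix, uniform via QR of a Gaussian matrix
randomRotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# connected motif: each point 3.9-7.0 A from some previous point and
# >= 3.8 A from all, so single linkage at 8 A always joins the site
sampleMotifGeometry <- function(k, maxTries = 500L) {
  pts <- matrix(0, 1, 3)
  while (nrow(pts) < k) {
    placed <- FALSE
    for (tries in seq_len(maxTries)) {
      base <- pts[sample.int(nrow(pts), 1L), ]
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      p <- base + stats::runif(1, 3.9, 7.0) * dir
      if (min(sqrt(colSums((t(pts) - p)^2))) >= 3.8) {
        pts <- rbind(pts, p); placed <- TRUE; break
      }
    }
    if (!placed) stop("could not sample a motif geometry")
  }
  unname(pts)
}

sampleMotif <- function(siteSize, types) {
  list(coords = sampleMotifGeometry(siteSize), types = types)
}

# halo points 4-6 A from a random site point, >= 3.5 A from the patch
sampleHalo <- function(siteXyz, count, maxTries = 500L) {
  pts <- siteXyz
  halo <- matrix(numeric(0), 0, 3)
  for (j in seq_len(count)) {
    placed <- FALSE
    for (tries in seq_len(maxTries)) {
      base <- siteXyz[sample.int(nrow(siteXyz), 1L), ]
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      p <- base + stats::runif(1, 4.0, 6.0) * dir
      if (min(sqrt(colSums((t(pts) - p)^2))) >= 3.5) {
        pts <- rbind(pts, p); halo <- rbind(halo, p); placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place halo residues")
  }
  halo
}

sampleDecoys <- function(existing, count, center, boxSide, sep,
                         maxTries = 2000L) {
  pts <- existing
  dec <- matrix(numeric(0), 0, 3)
  for (j in seq_len(count)) {
    placed <- FALSE
    for (tries in seq_len(maxTries)) {
      p <- center + stats::runif(3, -boxSide / 2, boxSide / 2)
      if (nrow(pts) == 0L ||
          min(sqrt(colSums((t(pts) - p)^2))) >= sep) {
        pts <- rbind(pts, p); dec <- rbind(dec, p); placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("overcrowded geometry: cannot place decoy residues; ",
           "increase boxSide or reduce decoyResidues")
  }
  dec
}

#' Generate a synthetic benchmark with planted functional sites
#'
#' Builds the toy structure/ranking/accessibility/annotation set
#' described by a [fixtureSpec()]. All coordinates are rounded to
#' 3 decimals so written PDB files round-trip exactly through
#' [readPdbChain()]. When `outdir` is given, every chain is written
#' in the package's standard dialects (`<id>.pdb`,
#' `<id>.ranks.tsv`, `<id>.acc.tsv`), together with
#' `annotations.tsv` and a `manifest.json` listing ids, functions,
#' planted site positions and affected (private-primary) proteins.
#'
#' @param spec a `FixtureSpec`.
#' @param outdir optional directory to write the benchmark to.
#' @return list with `dataset` (an [EtaDataset-class]), `truth` (the
#'   [AnnotationTable-class]) and `manifest`.
#' @export
generateBenchmark <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed)
  aa <- AA_ALPHABET1
  nSites <- spec$sitesPerProtein
  motifs <- lapply(seq_len(spec$nFunctions), function(f) {
    types <- sample(aa, spec$siteSize * nSites)
    lapply(seq_len(nSites), function(s)
      sampleMotif(spec$siteSize,
                  types[(s - 1L) * spec$siteSize + seq_len(spec$siteSize)]))
  })
  haloCount <- spec$patchSize - spec$siteSize
  nRes <- nSites * spec$patchSize + spec$decoyResidues
  funOf <- ((seq_len(spec$nProteins) - 1L) %% spec$nFunctions) + 1L
  ecOfFun <- sprintf("%d.1.1.%d", seq_len(spec$nFunctions),
                     seq_len(spec$nFunctions))
  nAffected <- round(spec$primaryAbsentFraction * spec$nProteins)
  ids <- sprintf("syn%02dA", seq_len(spec$nProteins))
  chains <- list(); rankings <- list(); surfaces <- list()
  sites <- list()
  for (i in seq_len(spec$nProteins)) {
    f <- funOf[i]
    prot <- motifs[[f]]
    if (i <= nAffected) {
      # private primary-site motif: geometry and types unique to i
      prot[[1L]] <- sampleMotif(spec$siteSize, sample(aa, spec$siteSize))
    }
    coords <- matrix(numeric(0), 0, 3)
    types <- character(0)
    baseRank <- numeric(0)
    siteRows <- list()
    centers <- list(c(0, 0, 0), c(32, 0, 0))
    for (s in seq_len(nSites)) {
      R <- randomRotation()
      xyz <- prot[[s]]$coords %*% t(R)
      xyz <- sweep(xyz, 2, centers[[s]] - colMeans(xyz), "+")
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$jitterSigma),
                          nrow(xyz))
      halo <- sampleHalo(xyz, haloCount)
      siteRows[[s]] <- nrow(coords) + seq_len(spec$siteSize)
      coords <- rbind(coords, xyz, halo)
      types <- c(types, prot[[s]]$types,
                 sample(aa, haloCount, replace = TRUE))
      # interleaved patch ranks in two-site mode keep the secondary
      # cluster's surface residues ahead of the primary's median
      patchRank <- if (nSites == 1L) seq_len(spec$patchSize)
                   else (seq_len(spec$patchSize) - 1L) * nSites + s
      baseRank <- c(baseRank, patchRank)
    }
    boxCenter <- if (nSites == 1L) c(0, 0, 0) else c(16, 0, 0)
    boxSide <- if (nSites == 1L) spec$boxSide else spec$boxSide + 24
    dec <- sampleDecoys(coords, spec$decoyResidues, boxCenter, boxSide,
                        spec$decoySep)
    coords <- rbind(coords, dec)
    types <- c(types, sample(aa, spec$decoyResidues, replace = TRUE))
    baseRank <- c(baseRank,
                  nSites * spec$patchSize + sample(spec$decoyResidues))
    rank <- baseRank + stats::runif(nRes, 0, spec$rankNoise)
    area <- rep(10, nRes)
    if (spec$buriedFraction > 0) {
      decIdx <- nSites * spec$patchSize + seq_len(spec$decoyResidues)
      nBury <- round(spec$buriedFraction * spec$decoyResidues)
      if (nBury > 0) area[sample(decIdx, nBury)] <- 0
    }
    perm <- sample(nRes)  # residue order along the chain
    id <- ids[i]
    chains[[id]] <- newProteinChain(
      id, seq_len(nRes), types[perm], round(coords[perm, ], 3),
      fullLength = nRes)
    rankings[[id]] <- newETRanking(id, seq_len(nRes), rank[perm])
    surfaces[[id]] <- new("SurfaceAnnotation", chainId = id,
                          resno = seq_len(nRes), area = area[perm])
    invPerm <- match(seq_len(nRes), perm)  # original row -> resno
    sites[[id]] <- lapply(siteRows, function(rows) invPerm[rows])
  }
  truth <- annotationTable(stats::setNames(
    as.list(ecOfFun[funOf]), ids))
  manifest <- list(ids = ids, functions = funOf, ecs = ecOfFun[funOf],
                   sites = sites,
                   affected = if (nAffected) ids[seq_len(nAffected)]
                              else character(0),
                   spec = unclass(spec))
  dataset <- etaDataset(chains, rankings, surfaces, truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (id in ids) {
      writePdbChain(chains[[id]], file.path(outdir, paste0(id, ".pdb")))
      writeEtRanks(rankings[[id]],
                   file.path(outdir, paste0(id, ".ranks.tsv")),
                   aa = chains[[id]]@aa)
      writeAccessibility(surfaces[[id]],
                         file.path(outdir, paste0(id, ".acc.tsv")))
    }
    writeAnnotationTable(truth, file.path(outdir, "annotations.tsv"))
    manifest$files <- c(paste0(ids, ".pdb"), paste0(ids, ".ranks.tsv"),
                        paste0(ids, ".acc.tsv"), "annotations.tsv")
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(dataset = dataset, truth = truth, manifest = manifest)
}

#' Planted-correspondence match between two proteins
#'
#' The ground-truth residue correspondence of a shared site, scored
#' (RMSD, rank differences, ETScore); the backbone of SVM training
#' data and of oracle checks.
#'
#' @param bench a benchmark as returned by [generateBenchmark()].
#' @param q,t chain ids sharing the site.
#' @param site site index (1 = primary).
#' @return a scored [TemplateMatch-class].
#' @export
plantedMatch <- function(bench, q, t, site = 1L) {
  ds <- bench$dataset
  qpos <- bench$manifest$sites[[q]][[site]]
  tpos <- bench$manifest$sites[[t]][[site]]
  qa <- ds@chains[[q]]; ta <- ds@chains[[t]]
  m <- new("TemplateMatch", queryChain = q, targetChain = t,
           templatePositions = as.integer(qpos),
           matchedPositions = as.integer(tpos),
           direction = paste0(q, "->", t))
  qp <- percentileOf(ds@rankings[[q]], qpos)
  tp <- percentileOf(ds@rankings[[t]], tpos)
  m@rmsd <- superposeRmsd(qa@coords[match(qpos, qa@resno), ],
                          ta@coords[match(tpos, ta@resno), ])
  m@rankDiffs <- abs(qp - tp)
  m@etScore <- sum(m@rankDiffs)
  m
}

#' Labeled match features for SVM training
#'
#' Generates a benchmark from `spec` and derives labeled feature
#' vectors: true examples are planted-site correspondences between
#' same-function proteins; false examples are geometry-relaxed
#' paired-distance matches of site templates against the decoy
#' residues of other-function proteins (type constraint lifted,
#' tolerance `tolFalse`), i.e. spurious geometric matches with
#' uninformative evolutionary profiles.
#'
#' @param spec a [fixtureSpec()] (use a different seed than the
#'   evaluation benchmark).
#' @param nTrue,nFalse class sizes (each >= 10).
#' @param tolFalse paired-distance tolerance for decoy matches
#'   (default 8 A).
#' @param cap search-node budget per decoy search.
#' @return list with `features` (matrix, columns `rmsd, r1..r6`) and
#'   logical `labels`.
#' @export
generateSvmTraining <- function(spec, nTrue, nFalse, tolFalse = 8,
                                cap = 2e4) {
  stopifnot(nTrue >= 10, nFalse >= 10)
  bench <- generateBenchmark(spec)
  ds <- bench$dataset
  man <- bench$manifest
  ids <- man$ids
  set.seed(spec$seed + 1L)
  sameFun <- which(outer(man$functions, man$functions, "==") &
                     outer(ids, ids, "!="), arr.ind = TRUE)
  if (nrow(sameFun) == 0L) stop("no same-function pairs in the fixture")
  pick <- rep_len(sample(nrow(sameFun)), nTrue)
  trueFeat <- t(vapply(pick, function(r)
    matchFeatures(plantedMatch(bench, ids[sameFun[r, 1]],
                               ids[sameFun[r, 2]])),
    numeric(7)))
  diffFun <- which(outer(man$functions, man$functions, "!="),
                   arr.ind = TRUE)
  falseFeat <- matrix(numeric(0), 0, 7)
  for (r in sample(nrow(diffFun))) {
    if (nrow(falseFeat) >= nFalse) break
    q <- ids[diffFun[r, 1]]; t <- ids[diffFun[r, 2]]
    qpos <- man$sites[[q]][[1L]]
    qa <- ds@chains[[q]]
    tmpl <- new("Template", sourceChain = q, modeTag = "6R",
                positions = as.integer(qpos),
                coords = qa@coords[match(qpos, qa@resno), , drop = FALSE],
                nativeTypes = qa@aa[match(qpos, qa@resno)],
                allowedTypes = rep(list(AA_ALPHABET1), length(qpos)))
    ta <- ds@chains[[t]]
    keep <- !ta@resno %in% unlist(man$sites[[t]])
    sub <- newProteinChain(t, ta@resno[keep], ta@aa[keep],
                           ta@coords[keep, , drop = FALSE])
    found <- pdmSearch(tmpl, sub, tol = tolFalse, cap = cap)
    if (length(found) == 0L) next
    found <- found[sample.int(length(found),
                              min(length(found),
                                  ceiling(nFalse / 10)))]
    found <- scoreMatches(found, tmpl, sub, ds@rankings[[q]],
                          ds@rankings[[t]])
    falseFeat <- rbind(falseFeat, matchFeatureMatrix(found))
  }
  if (nrow(falseFeat) < nFalse)
    stop("found only ", nrow(falseFeat), " decoy matches; ",
         "increase decoyResidues or tolFalse")
  falseFeat <- falseFeat[seq_len(nFalse), , drop = FALSE]
  features <- rbind(trueFeat, falseFeat)
  colnames(features) <- c("rmsd", paste0("r", 1:6))
  list(features = features,
       labels = rep(c(TRUE, FALSE), c(nTrue, nFalse)))
}

#' Synthetic multiple sequence alignment for a chain
#'
#' Rows are mutated copies of the chain's sequence; positions listed
#' in `sitePositions` mutate at a tenth of the background
#' `substitutionRate`, emulating the conservation of functional
#' sites. Gaps replace non-site residues at `gapRate`. The first row
#' is the unmutated chain, so columns map one-to-one onto residues.
#'
#' @param chain a [ProteinChain-class].
#' @param nRows alignment depth (default 8).
#' @param substitutionRate background per-position substitution
#'   probability in \[0, 1).
#' @param gapRate per-position gap probability for non-site columns
#'   (default 0.05).
#' @param seed RNG seed.
#' @param sitePositions residue numbers to conserve.
#' @return an aligned `AAStringSet`, first row named after the chain.
#' @export
generateMsa <- function(chain, nRows = 8L, substitutionRate = 0.1,
                        gapRate = 0.05, seed = 1L,
                        sitePositions = integer(0)) {
  stopifnot(substitutionRate >= 0, substitutionRate < 1)
  set.seed(seed)
  n <- length(chain@resno)
  isSite <- chain@resno %in% sitePositions
  rate <- ifelse(isSite, substitutionRate / 10, substitutionRate)
  rows <- matrix(rep(chain@aa, each = nRows), nRows, n)
  for (r in seq_len(nRows)[-1L]) {
    mut <- stats::runif(n) < rate
    rows[r, mut] <- vapply(which(mut), function(j)
      sample(setdiff(AA_ALPHABET1, chain@aa[j]), 1L), character(1))
    gap <- !isSite & stats::runif(n) < gapRate
    rows[r, gap] <- "-"
  }
  seqs <- apply(rows, 1L, paste, collapse = "")
  names(seqs) <- c(chain@id, paste0("homolog", seq_len(nRows - 1L)))
  Biostrings::AAStringSet(seqs)
}

#' Tied-vote network fixture for diffusion rescue
#'
#' Builds a match network in which every query is reciprocally matched
#' to `nLabeled` proteins of EC 1.1.1.1 and `nLabeled` of EC 1.1.1.2
#' -- an exact plurality-vote tie, so template voting abstains on all
#' of them -- but with strictly better match statistics (lower rmsd
#' and ETScore) toward the true function, so that edge weights can
#' break the tie under competitive diffusion. Half the queries get a
#' strongly discriminative weight contrast, half only a mild one;
#' weakly attached background unknowns anchor the confidence
#' z-scores, so the strongly discriminative queries come out on top.
#'
#' @param nTied tied queries (even, default 8; first half truly
#'   1.1.1.1, second half 1.1.1.2).
#' @param nLabeled labeled partners per function (default 4).
#' @param nBackground weakly attached unknown nodes (default 8).
#' @return list with `network` (a [MatchNetwork-class]), `truth` (an
#'   [AnnotationTable-class] for the queries), `queries`, and
#'   `partners` (the named EC list each query votes over).
#' @export
generateTieNetwork <- function(nTied = 8L, nLabeled = 4L,
                               nBackground = 8L) {
  stopifnot(nTied >= 2L, nTied %% 2L == 0L, nLabeled >= 1L)
  queries <- sprintf("q%02d", seq_len(nTied))
  labA <- sprintf("a%02d", seq_len(nLabeled))
  labB <- sprintf("b%02d", seq_len(nLabeled))
  bg <- if (nBackground) sprintf("u%02d", seq_len(nBackground))
        else character(0)
  nodes <- c(queries, labA, labB, bg)
  half <- nTied %/% 2L
  rows <- list()
  add <- function(a, b, rmsd, et)
    rows[[length(rows) + 1L]] <<- data.frame(a = a, b = b, rmsd = rmsd,
                                             etScore = et)
  for (i in seq_len(nTied)) {
    strong <- i <= ceiling(half / 2) || (i > half && i <= half + half %/% 2)
    trueA <- i <= half
    good <- if (strong) c(0.4, 0.3) else c(0.95, 0.85)
    bad <- if (strong) c(1.6, 1.4) else c(1.1, 1.0)
    for (x in labA) add(queries[i], x, if (trueA) good[1] else bad[1],
                        if (trueA) good[2] else bad[2])
    for (x in labB) add(queries[i], x, if (trueA) bad[1] else good[1],
                        if (trueA) bad[2] else good[2])
  }
  anchors <- rep(c(labA, labB), length.out = nBackground)
  for (i in seq_len(nBackground))
    add(bg[i], anchors[i], 1.0, 0.9)
  edges <- do.call(rbind, rows)
  ann <- annotationTable(c(
    stats::setNames(as.list(rep("1.1.1.1", nLabeled)), labA),
    stats::setNames(as.list(rep("1.1.1.2", nLabeled)), labB)))
  truth <- annotationTable(stats::setNames(
    as.list(rep(c("1.1.1.1", "1.1.1.2"), each = half)), queries))
  partners <- c(stats::setNames(as.list(rep("1.1.1.1", nLabeled)), labA),
                stats::setNames(as.list(rep("1.1.1.2", nLabeled)), labB))
  list(network = networkFromEdges(nodes, edges, ann), truth = truth,
       queries = queries, partners = partners)
}
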