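# etanet

Function annotation of protein structures from local evolutionary
similarity: 3D templates of evolutionarily important surface
residues are matched between C-alpha structures, filtered, accepted
only when reciprocal, voted over, and finally diffused as labels
over the weighted network of matches.

## Who this is for

Structural bioinformaticians who want to transfer Enzyme Commission
(EC) annotations to unannotated chains when sequence similarity is
too weak to trust — the regime where a conserved catalytic site in a
possibly unrelated fold is the only reliable signal. The package
also serves as a reference implementation of the full pipeline with
a self-contained synthetic benchmark, so every stage can be
exercised and verified without any external database.

## The method

Per chain, the inputs are the C-alpha trace, per-residue
evolutionary-importance ranks (Evolutionary Trace style; lower =
more important), accessibility (surface = area > 2 Å²), and EC
annotations for the reference chains.

1. **Templates.** Percentile rank `p(i) = #{j : r_j ≤ r_i}/N`;
   sweeping coverage upward, the first single-linkage cluster
   (C-alpha ≤ 8 Å) with ≥ 11 important surface residues is the
   primary site, and a 5- or 6-residue template is picked from it
   rank-first, geometry-second. Multiple-template modes (`M6R`,
   `M5R`) add one template per additional qualifying cluster.
2. **Paired-distance matching.** Depth-first placement of template
   residues onto type-compatible target residues with all pairwise
   distances agreeing within 2.5 Å.
3. **Filtering.** Kabsch superposition RMSD; self-matches and
   RMSD > 2 Å discarded; an RBF SVM over
   `[rmsd, |Δpercentile|₁..₆]` keeps the significant matches
   (5-residue matches use a virtual sixth residue = mean of five).
4. **Reciprocity and voting.** Pairs must match significantly in
   both directions; each unique reciprocal partner casts one vote
   per full EC; plurality wins, ties abstain.
5. **Network diffusion.** Edges carry
   `s = ½[(rmsd−μ_r)/σ_r + (ET−μ_ET)/σ_ET]`, weighted `w = e^{−s}`;
   per function, labels `y ∈ {+1, −1, 0}` are diffused by solving
   `(I + αL)f = y` (`L = D − W`), and z-scores of `f` over the
   unknown nodes give each prediction a confidence. Edge weights can
   break exact vote ties; `z` thresholds separate reliable
   predictions from guesses.

## Worked example

```r
library(etanet)

## train the match-significance SVM on a synthetic fixture
train <- generateSvmTraining(
  fixtureSpec(nProteins = 12, nFunctions = 3, seed = 102),
  nTrue = 60, nFalse = 60)
svm <- trainMatchSvm(train$features, train$labels)
svm
#> MatchClassifier (svm): trained on synthetic benchmark matches

## a 20-protein benchmark with 4 planted functions, 0.2 A jitter
bench <- generateBenchmark(
  fixtureSpec(nProteins = 20, nFunctions = 4, seed = 203))
res <- runMode(bench$dataset, mode = "6R", model = svm)
head(res$predictions, 4)
#>    query mode   label votes runnerUpVotes
#> 1 syn01A   6R 1.1.1.1     4             0
#> 2 syn02A   6R 2.1.1.2     4             0
#> 3 syn03A   6R 3.1.1.3     4             0
#> 4 syn04A   6R 4.1.1.4     4             0

sc <- scorePredictions(res$predictions, bench$truth)
unlist(sc[c("TP", "FP", "FN", "accuracy", "sensitivity", "fMeasure")])
#>          TP          FP          FN    accuracy sensitivity    fMeasure
#>          20           0           0           1           1           1
```

Each query found its four same-function partners (4 votes), and all
20 planted annotations are recovered: accuracy and sensitivity 1.0
under 0.2 Å coordinate noise. Every vote rests on a reciprocal,
SVM-significant, sub-2 Å template match.

The same machinery runs from the shell:

```sh
Rscript inst/scripts/eta.R generate --out bench --n 20 --functions 4
Rscript inst/scripts/eta.R predict  --dir bench --mode M6R
Rscript inst/scripts/eta.R diffuse  --dir bench --mode 6R \
    --hide syn01A,syn02A --alpha 1
```

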