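# ddiProp

Label propagation prediction of drug–drug interactions (DDIs) over drug
similarity networks.

## The problem

Most adverse DDIs surface only after a drug reaches the market. Given binary
feature profiles for a set of drugs — chemical substructure fingerprints,
side-effect terms from package inserts, side-effect signals mined from
adverse-event reports — and a list of known interacting pairs, ddiProp ranks
the remaining pairs by how likely they are to interact. It is aimed at
pharmacovigilance and drug-safety researchers who want a transparent,
network-based screen rather than a black-box classifier.

## The method

Each profile source yields a Tanimoto similarity matrix
`A` (`TC(a, b) = |a ∩ b| / |a ∪ b|`), normalized to a symmetric doubly
stochastic propagation operator `W` by a Frobenius-divergence
bi-stochastication (Dykstra alternating projections). Known interaction
labels `Y` (binary, symmetric, zero diagonal) are spread over the network:
the propagation fixed point

    F = (1 − μ)(I − μW)⁻¹ Y,   0 < μ < 1

minimizes `μ·tr(Fᵀ(I − W)F) + (1 − μ)‖F − Y‖²_F`, trading smoothness on the
network against fidelity to the known labels. Because `ρ(W) ≤ 1`, the
iterative update `F ← μWF + (1 − μ)Y` contracts to the same solution.
Propagation uses *high-order* similarity: evidence travels multiple hops,
unlike the nearest-neighbour baseline (`nnScores()`), which scores a pair by
the single best similarity to a known interactor.

With several sources, `fitAllSim()` (LP-AllSim) jointly learns predictions
and simplex-constrained source weights `α` by block coordinate descent on

    μ Σₖ αₖ tr(Fᵀ(I − Wₖ)F) + (1 − μ)‖F − Y‖²_F + δ‖α‖²₂

alternating a closed-form propagation step on `W = Σₖ αₖWₖ` with an exact
simplex-projected weight update. The learned `α` ranks the information
sources by their contribution.

Evaluation follows a drug-level hold-out: a fraction of drugs lose *all*
their interactions from training, and held-out pairs are ranked and scored
by AUROC/AUPR over repeated random divisions (`repeatedHoldout()`). A
seeded synthetic benchmark (`generateBenchmark()`) with cluster-structured
profiles and pure-noise decoy sources supports end-to-end testing without
any external data.

## Worked example

```r
library(ddiProp)

bench <- generateBenchmark(synthConfig(seed = 1))
bench$interactions
#> InteractionMatrix: 60 drugs, 446 interacting pairs (25.2% of pairs)

a <- similarityMatrix(bench$informative, diagonal = "zero")
w <- bbsNormalize(a)
wNoise <- bbsNormalize(similarityMatrix(bench$noise[[1]], diagonal = "zero"))

fit <- fitAllSim(list(informative = w, noise = wNoise),
                 bench$interactions, mu = 0.5)
fit
#> AllSimFit: 60 drugs, 2 sources, mu = 0.5, delta = 1
#>   BCD iterations: 3, final objective: 117.59
#> SourceWeights (alpha):
#> informative       noise
#>           1           0

res <- rbind(
  repeatedHoldout(list(y = bench$interactions, w = w), "lp",
                  fraction = 0.25, nRepeats = 15, baseSeed = 1000),
  repeatedHoldout(list(y = bench$interactions, similarity = a), "nn",
                  fraction = 0.25, nRepeats = 15, baseSeed = 1000))
res[, c("method", "fraction", "aurocMean", "aurocSd", "auprMean", "auprSd")]
#>   method fraction aurocMean aurocSd auprMean auprSd
#> 1     lp     0.25     0.733  0.0182    0.524 0.0284
#> 2     nn     0.25     0.640  0.0216    0.362 0.0204
```

The weight vector puts all mass on the informative source (the noise decoy
carries no signal about the interaction structure), and label propagation
clearly outranks the one-hop nearest-neighbour score on the same similarity
network — the two qualitative behaviours the method is built around.

A thin command-line wrapper over the same functions ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "ddiprop.R", package = "ddiProp"))')" \
    simulate --seed 4 --out-dir bench/
```

with subcommands `similarity`, `normalize`, `propagate`, `baseline-nn`,
`integrate`, `evaluate`, `simulate` (all I/O as drug-ID-labelled TSV).

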