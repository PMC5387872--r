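---
title: "Predicting drug-drug interactions by label propagation over similarity networks"
author: "ddiProp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-drug interactions by label propagation over similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddiProp)
```

## The problem and the model

Adverse drug-drug interactions (DDIs) are mostly discovered after a drug is
on the market. Computational screening ranks candidate drug pairs before
clinical evidence accumulates. The premise of this package is the similarity
assumption: *similar drugs tend to share interaction partners*. Each drug is
described by one or more binary feature profiles — chemical substructure
fingerprints, side-effect terms from package inserts, side-effect signals
mined from spontaneous reports — and each profile source yields a drug-drug
Tanimoto similarity network.

Given an $n \times n$ symmetric affinity matrix $A$ ($A_{ij} \ge 0$) and a
binary symmetric interaction matrix $Y$ (zero diagonal), we first normalize
$A$ to a symmetric doubly stochastic $W$ and then score all pairs by label
propagation. Every drug absorbs a fraction $\mu$ of its neighbours' current
scores and retains a fraction $1-\mu$ of its initial labels. The fixed point
minimizes

$$J(F) \;=\; \mu\,\mathrm{tr}\!\left(F^\top (I - W) F\right)
  \;+\; (1-\mu)\,\lVert F - Y\rVert_F^2 ,$$

a smoothness term (predictions should vary little across strong edges) plus
a fitting term (predictions should stay close to known labels), and equals
$F = (1-\mu)(I - \mu W)^{-1} Y$. `propagateClosedForm()` computes this by a
single linear solve with the matrix right-hand side $Y$, handling all $n$
per-drug prediction tasks at once; `propagateIterative()` exposes the
fixed-point iteration, and the two agree to high precision because
$\rho(W) \le 1$ makes the iteration a contraction for any $\mu \in (0,1)$.

Unlike a nearest-neighbour score (implemented in `nnScores()` as the maximum
similarity to a known interactor — one hop, no transitivity), propagation
exploits higher-order similarity: a drug two hops away from the labelled
neighbourhood along strong edges still receives evidence.

## Bi-stochastic normalization

`bbsNormalize()` projects $A$ onto the symmetric doubly stochastic matrices
under the squared Frobenius divergence:
$\min_W \lVert W - A\rVert_F^2$ s.t. $W \ge 0$, $W\mathbf{1} = \mathbf{1}$,
$W = W^\top$. The affine part (row and column sums, symmetry) has a
closed-form orthogonal projection; the nonnegativity constraint is handled
by Dykstra's alternating projection with its correction term, which
converges to the true joint projection rather than just a feasible point.
Symmetry is re-imposed after every sweep. Defaults: tolerance `1e-8` on the
worst row/column-sum deviation, at most `10000` sweeps; failure to converge
is a hard error, never a warning. The output's spectral radius is at most 1
(eigenvalues of a symmetric doubly stochastic matrix lie in $[-1, 1]$),
which is exactly what the propagation convergence argument needs. The test
suite cross-checks the projection against an independent quadratic-program
solver.

A Kullback-Leibler (Sinkhorn-style) variant is deliberately not provided:
fixing one divergence keeps a single canonical $W$ per input.

## Integrating several similarity sources (LP-AllSim)

With $K$ normalized networks $W_1, \dots, W_K$, predictions and a
simplex-constrained weight vector $\alpha$ are learned jointly by

$$J(F, \alpha) = \mu \sum_k \alpha_k\,
  \mathrm{tr}\!\left(F^\top (I - W_k) F\right)
  + (1-\mu)\lVert F - Y\rVert_F^2 + \delta\lVert\alpha\rVert_2^2 ,$$

minimized by block coordinate descent in `fitAllSim()`. With $\alpha$ fixed
the problem is single-network propagation with
$W = \sum_k \alpha_k W_k$ (a convex combination of symmetric doubly
stochastic matrices is again one); with $F$ fixed the weight step is a
quadratic program over the simplex whose exact solution is the Euclidean
projection of $-\frac{\mu}{2\delta} C$ onto the simplex, where
$c_k = \mathrm{tr}(F^\top (I - W_k) F)$ (`updateAlpha()`,
`projectSimplex()` with the sort-and-threshold algorithm). Both block steps
are global minimizers of their sub-problems, so the objective trace is
non-increasing; `fitAllSim()` treats any increase beyond `1e-9` as an
implementation fault and stops with an error. $\alpha$ starts uniform (no
prior preference among sources), and the learned $\alpha$ ranks the
information sources.

When drugs have unequal source coverage, `predictStratified()` fits the
model per source-availability stratum — for each distinct set of sources
shared by a pair, on the sub-universe of drugs covered by all of them — and
each pair takes its score from the largest source set covering both drugs.
Nothing is imputed.

## Parameters

* **$\mu \in (0,1)$** — influence of the network relative to the known
  labels. Larger $\mu$ leans on network structure, which helps when
  training labels are scarce. Default in the examples: `0.5`; the
  evaluation module can tune it per split by inner drug-level
  cross-validation over a grid (`tuneMu()`, default 5 folds), using
  training drugs only.
* **$\delta > 0$** — ridge penalty on $\alpha$; `1` by default. Large
  $\delta$ pulls weights toward uniform, small $\delta$ lets the smoothest
  source take all the weight. Its effect is relative to the magnitude of
  the costs $c_k$, which grow with the number of labelled pairs (see
  *Limitations*).
* **Tolerances** — propagation `1e-9` (max-abs change), bi-stochastication
  `1e-8` (sum deviation), BCD relative objective decrease `1e-7` with at
  most 200 outer iterations.
* **`diagonal` in `similarityMatrix()`** — `"keep"` (default) retains
  Tanimoto self-similarity 1; `"zero"` removes self-loops before
  normalization. The benchmark experiments in this package use `"zero"`:
  a self-loop is a trivially "smooth" edge, and keeping it lets a network
  with hardly any cross-drug similarity normalize to nearly the identity
  matrix, whose smoothness cost $\mathrm{tr}(F^\top(I - W)F) \approx 0$
  would win the weight update regardless of information content. Removing
  self-loops makes the source weights compare genuine cross-drug structure.

## Evaluation protocol

`holdoutSplit()` holds out a fixed *fraction of drugs* (not of pairs):
every interaction touching a held-out drug is removed from training by
`maskLabels()`, mimicking prediction for a drug with no interaction record.
Scored test pairs (all pairs with at least one held-out drug; a
`"test-train"` mode excludes test-test pairs) are ranked and summarized by
rank-based AUROC (ties count 1/2) and average-precision AUPR, both verified
against brute-force enumeration. `repeatedHoldout()` repeats the protocol
over consecutive seeds and reports means and sample standard deviations;
every split derives from one explicit base seed and reruns are
bit-identical. A decision cutoff for calling discrete interactions is
selected by `selectCutoffF1()` (best F1 over candidate thresholds, ties
toward the smaller predicted-positive set). The test-set size uses
banker's rounding with a floor of one drug.

## The synthetic benchmark

`generateBenchmark()` emulates the structure the method assumes, at desk
scale: 60 drugs in 3 round-robin clusters; each cluster owns a disjoint
block of signature features (present in members with probability 0.8,
elsewhere 0.05); cluster mates interact with probability 0.6 against a 0.08
background, so similar drugs both interact with each other and share
partners (realized density roughly a quarter of pairs, of the order of
dense adverse-event-derived DDI reference sets). Decoy sources are pure
background noise of the same shape. 240 features are used so that a drug
with an empty profile — which would be disconnected and make normalization
ill-posed — is vanishingly unlikely. Each component draws from its own
derived seed, so adding a decoy never perturbs the informative source.

What the benchmark does *not* emulate: side-effect vocabulary structure
(synonyms, term frequencies), reporting biases of spontaneous-report
mining, heavy class imbalance of real DDI screens, or heterogeneous
cluster sizes. Passing tests therefore demonstrate algorithmic
correctness and the expected qualitative orderings (propagation above
nearest neighbour; informative sources above noise), not field performance
on curated pharmacovigilance data.

## Numerical choices and degenerate inputs

* Tanimoto of two all-zero profiles is defined as 0 (never NaN); an
  all-zero profile has self-similarity 0 under `diagonal = "keep"`.
* Drugs and features are ordered lexicographically after loading, so
  downstream matrices do not depend on file row order.
* The iterative solver starts at $F^0 = Y$; the fixed point is unique, so
  this choice only affects the iteration count. Known labels are not
  clamped during iteration — the fitting term handles them.
* Scores are symmetrized as $(F_{ij} + F_{ji})/2$ only at pair-scoring
  time, keeping the solver faithful to the closed form.
* `bbsNormalize()` on a $1 \times 1$ input returns $[1]$; an all-zero row
  is a hard error naming the drug.
* Identical source costs split the weight symmetrically through the
  projection; no tie-breaking noise is added.
* A hold-out repetition whose test pairs are single-class is redrawn with
  the next unused seed and recorded.

## Limitations

* With very few training drugs the costs $c_k$ shrink while $\delta$ stays
  fixed, so the weight update enters a ridge-dominated regime and $\alpha$
  shrinks toward uniform: source *ordering* is preserved, but the weight
  *spread* contracts as the hold-out fraction grows. At full-data scale
  the costs dwarf $\delta$ and weights sit at or near a vertex of the
  simplex.
* Negative (known-safe) co-prescriptions are not modelled; all non-edges
  are treated as unlabelled.
* The learned $\alpha$ is global, not per drug or per pair.
* Interaction *types* are out of scope; labels are binary.

## Worked example

```{r example, eval = FALSE}
bench <- generateBenchmark(synthConfig(seed = 1))
a <- similarityMatrix(bench$informative, diagonal = "zero")
w <- bbsNormalize(a)
fit <- fitAllSim(list(informative = w,
                      noise = bbsNormalize(similarityMatrix(
                        bench$noise[[1]], diagonal = "zero"))),
                 bench$interactions, mu = 0.5)
sourceAlpha(fit)
repeatedHoldout(list(y = bench$interactions, w = w), "lp",
                fraction = 0.25, nRepeats = 15, baseSeed = 1000)
```
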