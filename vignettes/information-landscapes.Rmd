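---
title: "Simplicial information landscapes: model, estimation and caveats"
author: "infoLattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simplicial information landscapes: model, estimation and caveats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infoLattice)
```

## The model

infoLattice quantifies how information distributes over all subsets of a
set of `n` measured variables (genes, cells, channels) observed in `m`
samples. Each variable is reduced to a finite alphabet by equal-width
binning; probabilities are estimated by elementary counting; and two
families of Shannon quantities are evaluated on every face (variable
subset) of the simplicial lattice, in bits:

* the joint entropies `H_k(X_I) = H(X_{i1}, ..., X_{ik})`, and
* the multivariate mutual informations (interaction informations)
  `I_k(X_I) = sum over non-empty T subset of I of (-1)^(|T|+1) H(X_T)`.

`I_1 = H`, `I_2` is Shannon's mutual information, and for `k >= 3` the
sign of `I_k` is informative: positive values flag co-varying modules,
negative values flag synergy — variables that are collectively but not
pairwise dependent, the extreme case being the "Borromean" parity
(XOR) triple, pairwise independent with `I_3 = -1` bit. The total
correlation `G_k = sum H(X_i) - H_k` is carried along as the standard
non-negative alternative; `G_2 = I_2`.

Two global theorems organize the analysis. First, the `2^n - n - 1`
quantities `I_k, k >= 2` vanish together exactly when the variables are
statistically independent (`independenceCheck()`). Second, every
Shannon quantity (conditional entropies, conditional mutual
informations) is an integer combination of the pure `H_k` or `I_k`; the
finest additive pieces are the eta values
`eta_J = (complement of J).I_{|J|}(X_J)` from which every `H_k` and
`I_k` on the lattice reassembles (`etaValue()`,
`etaFromEntropies()`).

A note on the eta inversion: inverting the superset decomposition
`I_k(X_I) = sum over J containing I of eta_J` by Moebius inversion and
expanding in entropies collapses, after cancellation, to

```
eta_J = sum over A subset of J, A + comp non-empty, of
        (-1)^(|A|+1) H(X_{A union comp}),   comp = [n] \ J,
```

an inclusion–exclusion over the faces *containing the complement* of
`J`. For `J = [n]` this is the usual inclusion–exclusion for `I_n`; for
`n = 2` it gives `eta_{12} = H_1 + H_2 - H_12 = I_2` and
`eta_{1} = H_12 - H_2 = H(X1 | X2)`. The package implements this form;
it is cross-checked against the conditioning definition on
Dirichlet-sampled joints in the test suite.

## Landscapes and paths

The *landscape* of a measure is its value on every face, organized by
degree `k` (`computeLandscape()`, capped at `kmax` because the lattice
grows as `2^n`). The *mean path* averages each degree
(`meanPath()`). An *information path* follows a nested chain of faces,
one variable added per step; by the chain rule the step slope is

```
I_{k+1} - I_k = - (conditional mutual information of the added variable)
```

so a path keeps decreasing exactly while positive conditional
dependence remains. `extremalPaths()` searches for the longest strictly
decreasing paths and stops at the *first minimum* — the point where no
candidate step has positive conditional mutual information (a sign
change). Direction `"max"` keeps `I` as high as possible per step
(minimal conditional MI — co-variation modules); `"min"` drives `I`
down fastest (maximal conditional MI — synergistic clusters).

Design choices that the description of the method leaves open, resolved
here:

* **Search strategy.** The permutation space is `n!`; the default is a
  greedy best-first walk from every starting variable (beam width 1,
  configurable), with exhaustive enumeration available for `n <= 12`.
  On planted-module data the greedy walk provably-in-tests matches the
  exhaustive optimum while structure dominates; in the noise tail past
  the structured regime it can terminate a step early, which is why
  paths should be capped at the undersampling dimension (below).
* **Stopping.** "Change of sign of conditional mutual information" is
  operationalized as: stop before step `k+1` when the best candidate
  has `I_{k+1} >= I_k`. Ties between candidates break to the lowest
  variable index, making runs deterministic.
* **Ranking and components.** Paths are ranked by length, then terminal
  value; permutations of the same support are deduplicated. Components
  (e.g. two cell populations) are read off by greedily collecting
  ranked paths with disjoint supports (`pathComponents()`), not by
  clustering values. Note that an unconstrained path happily *crosses*
  into an unrelated block — the step to an independent variable still
  has positive conditional MI — so block recovery requires capping
  `kmax` near the expected module size or at `ku`.

## Estimation and its limits

**Binning.** Equal-width bins on `[min, max]` per variable
(`computeBins()`), code `min(floor((x - lo) N / (hi - lo)), N - 1)`:
half-open cells, maximum in the last bin, boundary values to the upper
bin (forced by the floor rule; documented, not configurable). Constant
variables collapse to one bin with entropy 0 rather than erroring —
silent genes are data, not defects. The default graining is `N = 9`
per variable, a choice motivated in the source analyses by the
stability of the resulting landscapes; `landscapeSweep()` exists
precisely to re-examine that choice per dataset (iso-graining and
iso-sample-size mean paths with their critical dimensions).

**Undersampling.** An empirical joint entropy can never exceed
`log2 m`. Once a face reaches that ceiling every extension stays on it,
and the measure reflects the sample size, not the system.
`undersamplingDimension()` reports, per degree, the fraction of faces
saturated at `log2 m` (within 1e-9, since the comparison is floating
point) and defines `ku` as one less than the first degree where the
fraction exceeds `pU = 0.05`. Landscapes and paths above `ku` are
computed on request but should not be interpreted; `runAnalysis()` caps
its outputs at `min(kmax, ku)`.

**Dependence test.** Column-wise shuffling preserves every marginal
exactly while randomizing the joint structure. The test pools the
shuffled `I_k` of all same-degree faces (`nShuffles` x `C(n, k)`
values; 17 shuffles by default) into one null per degree rather than
building per-face nulls, which would need orders of magnitude more
shuffles. Degree 2 is one-sided upper at `p2 = 0.05` (`I_2 >= 0`);
degrees `>= 3` are two-sided at total `pk = 0.1`, split evenly between
tails; thresholds are type-1 empirical quantiles. A flag means the
observed dependence is *specific* against randomly generated
marginal-preserving dependence at this `m` — not a strict independence
rejection; the shuffled nulls are themselves biased away from zero at
finite `m`, which is exactly why they, and not 0, are the reference.

## Numerical conventions

Base-2 logarithms everywhere; `0 log 0 = 0`; zero-probability
conditioning branches are dropped. Joints are stored sparsely (support
never exceeds `m` atoms when estimated from data, against product
alphabets like `9^20`). `I_k` is computed by the alternating sum over a
cached entropy table — each `H` value is shared by the `2^(n-k)` faces
above it — rather than by recursive conditioning. Conditional mutual
information uses the equivalent alternating sum of conditional
entropies; the branch-averaging definition is retained as the
independent oracle in the tests. Identity checks use absolute
tolerance 1e-10 on analytic distributions and 1e-9 on empirical ones.
The analytic continuation of the measures to unnormalized mass
functions (the cone extension) is not implemented: normalization is
enforced at validity time, and no supported analysis needs the
extension.

## What the synthetic generators emulate — and what they do not

The generators provide data with *known* information structure:
extremal binary triples (closed-form `I_3 = +/-1`), exact product and
Markov-chain laws, flat-Dirichlet simplex draws, and sampled matrices
with planted modules (noisy copies of a latent uniform source) or two
latent-source blocks, passed through the full continuous-binning path.
They reproduce the features the method is sensitive to: higher-order
dependence, block structure, undersampling saturation. They do not
emulate real expression data's marginal shapes (zero inflation,
heavy tails), between-sample heterogeneity, or measurement noise that
correlates across variables. Passing tests therefore certify the
estimator and search machinery, not the biological interpretability of
any particular dataset.

Problem sizes used in the shipped checks were chosen so the full suite
runs comfortably on a laptop: identity suites on 150 three-variable and
50 four-variable Dirichlet joints; bound sweeps of 1e4 (entropy) and
1e5 (triple information) draws; planted-module and two-population
fixtures with `n <= 8`, `m <= 1500`; shuffle-test calibration on
`n = 12, m = 80` with 17 shuffles. All scale linearly in draws and
samples if heavier confirmation is wanted.

## A worked miniature

```{r example}
set.seed(1)
tp <- twoPopulationSamples(4, 400, blockNoise = c(0.05, 0.05), seed = 11)
dm <- discretize(tp$data, N = 3)

undersamplingDimension(dm, kmax = 6)

ls <- computeLandscape(dm, "I", kmax = 4)
maxTuple(ls, 4)            # the dominant 4-tuple: one block

paths <- extremalPaths(dm, "max", kmax = 4)
pathComponents(paths)      # the two blocks, recovered blindly
```

## Known limitations

* Equal-width binning only; no adaptive or equal-frequency graining,
  kernel density estimation, or grid-optimized pairwise screens.
* The lattice is exhaustive up to `kmax`; `n` beyond ~25 at `kmax = 3`,
  or any `n` at large `kmax`, hits the `O(2^n)` wall the face-count
  guard enforces.
* The greedy path search is a heuristic: optimal on strongly structured
  fixtures (verified against exhaustive search), but it can stop one
  step short in noise-dominated regions.
* The shuffle null is pooled across faces of equal degree; individual
  faces with unusual marginals inherit a slightly mis-calibrated
  threshold.
* No partial-information decomposition (unique/shared/synergistic
  atoms); `I_k` negativity is reported as synergy without further
  decomposition.
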