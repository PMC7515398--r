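# infoLattice

Higher-order dependence analysis for sample-by-variable matrices via
simplicial information landscapes.

## The problem

Pairwise statistics miss collective structure. Three variables can be
pairwise independent yet perfectly dependent as a triple — the XOR
("Borromean") configuration — and real biological data (gene modules,
cell types in expression matrices) contain both co-varying clusters and
such synergistic ones. infoLattice is for analysts who want to quantify
dependence at *every* order on an `m x n` measurement matrix: which
k-tuples of variables share information, how much, with which sign, and
up to which order the sample size supports the estimate at all.

## The quantities

Variables are discretized into `N` equal-width bins on `[min, max]`
(default `N = 9`), joint probabilities estimated by counting, and two
families computed on every face (variable subset) of the simplicial
lattice, in bits:

* joint entropy `H_k(X_I) = H(X_{i1}, ..., X_{ik})`;
* interaction information
  `I_k(X_I) = sum_{T ⊆ I, T ≠ ∅} (-1)^{|T|+1} H(X_T)`, with `I_1 = H`,
  `I_2` ordinary mutual information, and for `k ≥ 3` a sign:
  `I_k > 0` flags co-variation, `I_k < 0` synergy;
* total correlation `G_k = Σ H(X_i) − H_k` as the non-negative
  companion (`G_2 = I_2`).

All `I_k (k ≥ 2)` vanish together iff the variables are independent,
which turns the `I`-landscape into a complete dependence fingerprint.
On top of the landscapes the package extracts *extremal information
paths* (nested chains of faces whose `I_k` decreases while positive
conditional mutual information remains, stopped at the first minimum),
an *undersampling dimension* `ku` (the degree beyond which empirical
entropies saturate at `log2 m` and stop meaning anything), and a
marginal-preserving *shuffle test* of k-dependence.

## Worked example

Two blocks of four variables, each a noisy copy of its own latent
source — an unsupervised two-population recovery problem:

```r
library(infoLattice)
tp <- twoPopulationSamples(4, 400, blockNoise = c(0.05, 0.05), seed = 11)
dm <- discretize(tp$data, N = 3)

undersamplingDimension(dm, kmax = 6)
#> UndersamplingReport: ku = 6 (pU = 0.05, m = 400, n = 8)
#>   saturated fraction by degree: 0.000 0.000 0.000 0.000 0.000 0.000

maxTuple(computeLandscape(dm, "I", kmax = 4), 4)
#> [1] 5 6 7 8

paths <- extremalPaths(dm, "max", kmax = 4)
paths[[1]]
#> InfoPath (max): 5 -> 8 -> 7 -> 6 | values 1.584, 1.203, 1.095, 1.007 | stop: kmax-reached

pathComponents(paths)
#> [[1]]
#> [1] 5 6 7 8
#>
#> [[2]]
#> [1] 1 2 3 4
```

No degree saturates at `log2 400`, so all computed orders are usable
(`ku = 6`). The dominant degree-4 face and the top-ranked information
path both recover one planted block; the best disjoint path recovers
the other — the two populations, found blindly. The path values are
bits: the path enters at `I_1 = H(X_5) = 1.584 = log2 3` (a full
3-level variable) and decays slowly, the signature of a tight module.
The shuffle test then flags exactly the 12 within-block pairs (observed
`I_2 ≈ 1.1–1.25` bits against a null threshold of `0.018`) and none of
the 16 cross-block pairs:

```r
dep <- dependenceTest(dm, kRange = 2, nShuffles = 17, seed = 5)
subset(dependenceTable(dep), significant)[, c("face", "observed", "upper")]
#>    face observed  upper
#> 1   1;2     1.06 0.0175
#> ...                       # all 12 within-block pairs, nothing else
```

Closed-form sanity anchors:

```r
mutualInfo(extremalTriple("identical"), 1:3)    #  1 bit
mutualInfo(extremalTriple("parity-even"), 1:3)  # -1 bit (synergy)
jointEntropy(extremalTriple("parity-even"), 1:3) # 2 bits, pairs independent
```

See `vignettes/information-landscapes.Rmd` for the model, the design
decisions and the estimation caveats.

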