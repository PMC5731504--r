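# ComplexSampler

Predicts protein complexes — including complexes that share subunits —
from a weighted protein–protein interaction (PPI) network, by simulated
annealing over sets of clusters. It is aimed at systems-biology users
who have an edge list of interactions with reliability weights (a
WI-PHI-style compendium, an affinity-purification score matrix dump, or
a synthetic benchmark) and want a catalogue-like set of predicted
complexes plus the standard size-stratified evaluation against a gold
standard.

## The method

A state is a pair (X, γ): a set of clusters X = {x ⊆ V, |x| ≥ 2} that
may overlap, and a power-law scaling exponent γ for cluster sizes.
States are scored by

f(X, γ) = b(X) − Σₓ w(x)/√|x| + c_dis·h_dis(X)
  + c_size·Σₛ (ψ_X(s) − ψ_γ(s))² + c_hy·(γ − γ₀)² + c_pro·|∪ₓ x|²

where b(X) forbids disconnected or oversized clusters, w(x)/√|x| is a
generalized density rewarding internal interaction weight, h_dis sums
Jaccard penalties over overlapping cluster pairs (and forbids large
overlaps outright), ψ_γ(s) ∝ s^(−γ) is a truncated power law matched
against the empirical size distribution ψ_X, γ has a quadratic prior
centered on γ₀ = 2.5, and the squared clustered-protein count restrains
total coverage. A Metropolis–Hastings chain with four moves
(add/remove a two-protein cluster, add/remove one protein of a
cluster, each with weight-proportional selection rules and the
proposal-ratio correction) plus a Gaussian γ update samples from
exp(−f/T), while T decays geometrically — simulated annealing. The
lowest-scoring state visited is returned.

The package also provides the size-stratified evaluation measure
(exact match for size-2/3 clusters, Jaccard ≥ 0.5 for size ≥ 4;
precision / recall / F), catalogue overlap statistics, and a
planted-complex benchmark generator with power-law sizes and
single-protein overlaps.

## Worked example

```r
library(ComplexSampler)

bench <- generateBenchmark(seed = 1)   # 30 planted complexes, exponent 2.02
bench@network
#> PPINetwork with 229 proteins and 2698 interactions
#>   weights in [0.05024, 0.9997]

res <- runSampler(bench@network,
                  benchmarkScoreParams(),           # rescaled coefficients
                  samplerParams(L = 2e5, seed = 2,
                                coolingFactor = benchmarkCooling(2e5)))
evaluateClusters(bestClusters(res), bench@truth)
#> EvalReport: 46 predictions vs 30 known complexes
#>   precision 0.4565 | recall 0.6667 | F 0.5419
#>   matched predictions (2 / 3 / >=4): 12 / 1 / 8
#>   matched complexes   (2 / 3 / >=4): 12 / 1 / 7
bestGamma(res)
#> [1] 2.406
```

Precision counts predictions that hit a planted complex within their
size stratum; recall counts planted complexes recovered. Small and
mid-size complexes are recovered reliably at this desk-scale iteration
count, the recovered exponent sits near the planted 2.02 under its
prior at 2.5, and the very largest planted complexes are typically
returned as fragments — they need longer annealing (see the methods
vignette for the iteration-count discussion).

A thin command-line wrapper exposes the same pipeline:

```sh
Rscript inst/cli/complexsampler.R simulate --n-complexes 30 --seed 1 \
    --out-network net.tsv --out-truth truth.txt
Rscript inst/cli/complexsampler.R predict --network net.tsv \
    --iterations 200000 --seed 2 --out pred.txt
Rscript inst/cli/complexsampler.R evaluate --predicted pred.txt --known truth.txt
```

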