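# IsingZ

Fast, accurate normalization of **stimulus-driven Ising models** of binned
population spike trains.

Pairwise maximum-entropy (Ising) models describe the probability of a
population spike pattern σ ∈ {0,1}ᴺ in a time bin as

    P(σ | s) = exp( h(s)·σ + σᵀJσ ) / Z(s),      h(s) = C(s) β

with C(s) an L×R stimulus design matrix, β the stimulus weights and J a
symmetric, zero-diagonal coupling matrix. Including stimulus drive makes the
partition function Z(s) stimulus dependent: it must be evaluated for every
unique stimulus, and each evaluation sums 2ᴺ terms. For anyone comparing
coupled and independent population codes, computing entropies, or decoding
from normalized pattern probabilities, this normalization is the
computational bottleneck.

IsingZ implements the **missing-mass approximation**: split
Z(s) = X(s) + Y(s), where X(s) sums the (few) patterns observed in the
training data exactly, and recover the (many, individually negligible)
unobserved patterns through the missing mass M(s) — the total model
probability of everything never observed — via Z(s) = X(s) / (1 − M(s)).
M(s) is estimated either by

* **Good–Turing counting** — singletons/L, a model-free estimate of the
  average missing mass (removes the bias of X but not its
  stimulus-driven variance), or
* a **rate-ordered conditional-logistic chain** — a normalized product of
  logistic regressions P(σ₍ₖ₎ | σ₍ₖ₊₁..ₙ₎; s) that tracks the stimulus
  modulation of M(s) (removes bias *and* variance).

The cost is O(L·N·N_pat) instead of O(L·2ᴺ). The package also provides the
baselines the method is judged against — exact Gray-code enumeration
(N ≤ 24), Monte Carlo importance sampling with an independent-neuron
proposal, naive and TAP mean field, the Bethe approximation via loopy
belief propagation, and a low-firing-rate expansion — plus
pseudo-likelihood fitting, a seeded Gibbs simulator of trial-structured
stimulus-driven populations (B-spline or Zernike drive), and
ratio-distribution evaluation utilities.

## Worked example

Simulate a 20-neuron population (40 trials of 2500 ms at 5 ms bins,
B-spline drive, ~5 Hz rates, couplings uniform in ±0.5), fit it by
pseudo-likelihood, and compare partition-function estimates:

```r
library(IsingZ)

proto <- TrialProtocol(nNeurons = 20, nTrials = 40, jMax = 0.5, seed = 5)
sim <- simulateProtocol(proto)

tab   <- buildPatternTable(sim$raster)
tab
#> PatternTable: 572 unique patterns over 20000 bins; 284 singletons
#>   (Good-Turing missing mass 0.0142)

fitPL <- fitPseudolikelihood(sim$raster, sim$covariates)   # joint model
fitCL <- fitConditionalChain(sim$raster, sim$covariates)   # chain

X   <- observedSumX(fitPL$model, tab, sim$covariates)
Zcl <- zFromMissingMass(X, missingMass(fitCL$chain, tab, sim$covariates))
Zgt <- zFromMissingMass(X, goodTuringSeries(tab, nBins(X)))
Zex <- exactPartition(fitPL$model, sim$covariates)  # 500 unique stimuli

ratioDistribution(X, Zex)
#> RatioSummary over 20000 bins: mean 0.98584
#>   99% band { 0.965446 , 0.997525 }
ratioDistribution(Zgt, Zex)
#> RatioSummary over 20000 bins: mean 1.00004
#>   99% band { 0.979353 , 1.01189 }
ratioDistribution(Zcl, Zex)
#> RatioSummary over 20000 bins: mean 0.999959
#>   99% band { 0.999498 , 1.00047 }
```

Read bottom-up: the raw observed-pattern sum X under-estimates Z by the
missing mass (~1.4% here, band entirely below 1); the Good–Turing constant
removes the bias but leaves the stimulus-driven variance (band ±1.2%); the
conditional-logistic chain removes both, normalizing every pattern
probability to within ±0.05% across all 20,000 bins — at a cost linear in
the number of observed patterns rather than exponential in N.

A thin CLI over the same functions lives at `inst/cli/isingZ.R`
(subcommands `simulate`, `fit`, `partition`, `evaluate`, `experiment`).
The methods vignette (`vignettes/missing-mass-partition.Rmd`) documents the
model, the estimators, the numerical conventions and the generator's
assumptions.

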