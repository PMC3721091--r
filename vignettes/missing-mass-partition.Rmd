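---
title: "Normalizing stimulus-driven Ising models with the missing mass"
author: "IsingZ package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing stimulus-driven Ising models with the missing mass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IsingZ)
```

## The model and the problem

A pairwise maximum-entropy (Ising) model assigns to each binary population
spike pattern $\sigma \in \{0,1\}^N$ in a time bin the probability

$$P(\sigma \mid s) \;=\; \frac{\exp\!\big(h(s)\cdot\sigma +
\sigma^\top J \sigma\big)}{Z(s)},
\qquad h(s) = C(s)\,\beta,$$

where $C(s)$ is an $L \times R$ stimulus design matrix (B-splines in trial
time, Zernike polynomials on a spatial disc, or any user basis), $\beta$ an
$R \times N$ weight matrix, and $J$ an $N \times N$ symmetric coupling
matrix with zero diagonal. We use the $\{0,1\}$ spin coding throughout, so
$\sigma^\top J \sigma = 2\sum_{i<j} J_{ij}\sigma_i\sigma_j$; models in the
$\{-1,+1\}$ convention are refused rather than silently converted, because
the two parameterizations are easily confused and the factor-2 neighbor
coding below depends on this choice. Whether $J$ carries a diagonal is a
genuine ambiguity of the parameterization; we fix $\mathrm{diag}(J)=0$ (a
self-coupling $J_{ii}\sigma_i^2 = J_{ii}\sigma_i$ is just a constant field
and is absorbed into $\beta$ at construction, with a warning), which makes
the full conditionals exactly logistic with predictor
$h_i(s) + 2\sum_{j\neq i}\sigma_j J_{ji}$.

The normalizer $Z(s) = \sum_{\sigma} e^{h(s)\cdot\sigma +
\sigma^\top J\sigma}$ runs over $2^N$ patterns *per stimulus value*: with
stimulus drive the partition function must be recomputed for every unique
covariate row. Exact enumeration is exponential in $N$; for a recording of
$L$ bins the naive cost is $O(L\,2^N)$.

## The missing-mass decomposition

Sparsely spiking populations visit few patterns: the high-probability
patterns appear in the training data, the remaining $2^N - N_\mathrm{pat}$
patterns are individually negligible but collectively non-trivial. Split

$$Z(s) = X(s) + Y(s),$$

with $X(s)$ the sum over the $N_\mathrm{pat}$ observed patterns (computed
exactly: one precomputed quadratic energy per pattern plus one matrix
product against the unique covariate rows, $O(L\,N\,N_\mathrm{pat})$
overall) and $Y(s)$ the sum over everything else. Writing $M(s)$ for the
*missing mass* — the model probability of all unobserved patterns — gives
$M(s) = Y(s)/(X(s)+Y(s))$ and hence the inversion

$$Z(s) \;=\; \frac{X(s)}{1 - M(s)},$$

implemented in `zFromMissingMass()` in log space (algebraically identical
to $X + X\,M/(1-M)$, with one fewer operation). Any bin with $M \ge 1$
aborts with the offending bins named: it can only arise from a badly broken
missing-mass fit, and clipping it would silently corrupt every downstream
ratio. Tiny negative $M$ from floating-point cancellation is clipped to 0
and counted on the returned object.

Two estimators of $M(s)$ are provided:

* **Good–Turing** (`goodTuring()`): the number of patterns seen exactly
  once divided by $L$. It estimates the *stimulus-averaged* missing mass
  without any model, and assuming $M(s)$ constant corrects the bias of
  $X(s)$ but not its stimulus-driven variance.
* **Conditional-logistic chain** (`fitConditionalChain()` +
  `missingMass()`): factorize the joint as a chain
  $P(\sigma_{(1)},\dots,\sigma_{(N)} \mid s) = \prod_k
  P(\sigma_{(k)} \mid \sigma_{(k+1..N)}; s)$ and fit each conditional as a
  logistic regression on $[C(s),\ 2\sigma_j]$ for the neurons later in the
  ordering. The product is normalized *by construction*, so
  $M_{CL}(s) = 1 - \sum_{\sigma \in T} P_{CL}(\sigma\mid s)$ needs only a
  sum over observed patterns. The chain conditionals are *not* the Ising
  model's subset conditionals (exponential-family models are not
  projective — the marginals of an Ising model do not retain the logistic
  form), but the missing mass only needs decent conditional probability
  estimates, not matching parameters.

Neurons are ordered by descending mean firing rate, ties broken by
ascending index: low-rate neurons carry too few spikes to support a
regression on many neighbors, so the lowest-rate neuron gets the
stimulus-only position at the end of the chain. The printed form of the
chain conditional in the source material indexes neighbors as $j \neq i$;
we condition strictly on $j > i$ in the rate ordering, since the chain-rule
factorization requires it (the looser subscript cannot yield a normalized
product).

## Fitting

`fitPseudolikelihood()` estimates $(\beta, J)$ by the Besag construction:
each neuron's spikes are regressed on $[C(s), \{2\sigma_j\}_{j\neq i}]$ —
with the factor-2 coding the neighbor coefficients estimate $J_{ji}$
directly — and the two per-pair estimates are averaged to produce an
exactly symmetric $\hat J$ with zero diagonal. Averaging (rather than a
jointly constrained fit) is the standard choice and keeps the $N$
regressions independent.

All regressions run through `fitLogistic()`, a deterministic
ridge-penalized IRLS with step halving:

* **ridge = 1e-4** by default on every coefficient. The penalty exists to
  keep estimates finite under separation — with 5 Hz rates and 5 ms bins,
  pairs of neurons that never co-spike are common and their unpenalized
  coupling estimates diverge. No intercept is added: the stimulus basis is
  required to span a constant (B-spline bases do, by partition of unity),
  which keeps the penalty interpretation uniform.
* **tol = 1e-8** on the per-observation gradient
  $\max_k |X^\top(y-p) - \lambda w|_k / n$, **maxIter = 100**.
  Non-convergence is flagged on the `FitReport` and warned about; weights
  are still returned.

## Baselines

`importanceSamplingZ()` draws patterns from an independent-Bernoulli
proposal (stimulus-only logistic fits, which give nonzero probability to
every pattern) and averages the target/proposal weight ratios in the
linear domain with log-sum-exp stabilization; per-bin standard errors come
from the sample variance of the ratios. Samples are drawn fresh per
*unique* stimulus row and broadcast, matching the deduplication convention
used everywhere (`nSamples` is therefore per unique row).

`deterministicZ()` implements four standard closed-form/fixed-point
approximations, all exact at $J = 0$:

* **nmf** — naive mean field, the variational lower bound
  $\log Z \ge h\cdot m + H(m) + m^\top J m$ at the damped fixed point of
  $m_i = \mathrm{logistic}(h_i + 2(Jm)_i)$;
* **tap** — the TAP correction, adding the Onsager term
  $\chi^\top (J\circ J)\chi$ with $\chi_i = m_i(1-m_i)$ and the matching
  reaction term in the fixed-point equation. TAP is exact through second
  order in the couplings and therefore *not* a bound: at weak coupling its
  residual has data-dependent sign, and with noisily estimated couplings
  the quadratic correction can overshoot substantially;
* **bethe** — the Bethe free energy at a loopy-belief-propagation fixed
  point on the fully connected pairwise graph (parallel messages,
  damping 0.5, tolerance 1e-8, cap 500 iterations);
* **low_rate** — the independent-pair low-firing-rate form
  $\log Z \approx \sum_i \log(1+e^{h_i}) + \sum_{i<j}
  \log\!\big(1 + m_i m_j (e^{2J_{ij}}-1)\big)$ with
  $m = \mathrm{logistic}(h)$. We chose this form over the truncated
  ($K\le2$-spike) pattern sum because it is exact in the uncoupled limit
  while agreeing with the truncated sum to second order in the firing
  probabilities.

Fixed points for nmf/tap start from $m = \mathrm{logistic}(h)$ with
damping 0.5; non-convergence is flagged per unique stimulus row and values
are returned anyway.

## Numerical conventions

* Everything is carried in log space; ratios of partition series are
  $\exp(\log Z_a - \log Z_b)$; sums use max-subtracted log-sum-exp.
* Exact enumeration (`exactPartition()`) uses a Gray-code sweep: the
  quadratic energies of all $2^N$ patterns are computed once with $O(N)$
  work per step and reused across stimulus rows; per row only the field
  dot product changes, by $\pm h_i$ per step. The default refusal cap is
  $N = 24$.
* Unique-stimulus deduplication: all per-bin methods hash covariate rows
  and compute once per unique row. Trial protocols have at most
  bins-per-trial unique rows, which is what makes 20-neuron exact
  enumeration a desk-scale computation (500 enumerations, not 20,000).
* Pattern keys are little-endian bit-packed (neuron 1 = least significant
  bit), exact in a double for $N \le 52$, packed character keys above;
  tables are ordered by ascending key so serialized tables are portable.
* Ratio summaries use type-7 quantiles (linear interpolation of order
  statistics). The convention matters in the fourth decimal of the 99%
  bounds, so it is fixed and documented rather than left to defaults.
* Error is reported as the distribution over bins of
  $Z_\mathrm{est}(s)/Z_\mathrm{exact}(s)$, summarized by its mean and
  0.005/0.995 quantiles; this ratio equals the factor by which every
  pattern probability is mis-normalized in that bin.

## The synthetic generator

`TrialProtocol()` + `simulateProtocol()` emulate a repeated-trial
population recording: trials of 2500 ms at 5 ms bins (500 bins per trial),
per-neuron drive $h_n(t)$ a linear sum of order-4 B-splines on knots every
100 ms, weights drawn uniformly in $[-6, -2]$ (the partition of unity then
confines $h_n(t)$ to that band) and shifted per neuron by a root-found
constant so the uncoupled mean rate hits 5 Hz within 10%; couplings uniform
on $[-J_{max}, J_{max}]$, symmetrized, zero diagonal. Rasters come from a
single-site Gibbs sampler using the exact logistic conditionals, 20 burn-in
plus 10 recorded sweeps per bin, warm-started from the previous bin's
state (consecutive bins share similar fields, so warm starts mix fast; the
choice is validated by a total-variation test against exact enumeration at
small $N$). The generator is seeded end to end: the same protocol yields a
bitwise-identical raster.

`calibrateMissingMass()` stages experiments at a prescribed Good–Turing
missing mass. The missing mass is not monotone in $J_{max}$ alone — beyond
roughly $J_{max} = 1.2$ the simulated network falls into a saturated
high-rate attractor and the pattern repertoire collapses — so the search
bisects a single excitability path: couplings grow to a cap (default 0.5,
low enough that every coupling draw stays in the stimulus-driven regime
where realized rates track the intended target), beyond which the target
rate is scaled up instead. Large missing masses are therefore reached
through elevated firing rates, which is also how large missing masses
arise in real recordings.

What the generator does *not* emulate: refractoriness and spike-history
dependence (the model is memoryless across bins), non-stationarity across
trials, electrode artifacts, and the heavy-tailed rate heterogeneity of
real populations. Passing tests on these simulations validate the
estimators under the model's own assumptions; they do not certify
performance on data that violate them.

## Problem sizes and checks

The validation suite runs entirely on synthetic data at desk scale:
20-neuron, 100-s (40-trial) experiments staged at roughly 2% and 7%
missing mass for the headline ratio checks, with exact $Z(s)$ over the
$\le 500$ unique stimulus rows; 50 random models up to $N = 12$ for the
enumeration oracle; 20 replicates of a 10-neuron, 300-trial protocol for
coupling recovery; and 21 fitted instances at $J_{max} \in
\{0.25, 0.5, 1\}$ for the deterministic-baseline comparison. Complexity
claims are checked through operation counts (inner-loop terms actually
evaluated: $U \cdot N_\mathrm{pat} \cdot N$ for the missing-mass path
versus $U \cdot 2^N$ for enumeration), not wall-clock times.

## A worked example

```{r example, eval = FALSE}
proto <- TrialProtocol(nNeurons = 20, nTrials = 40, jMax = 0.5, seed = 5)
sim <- simulateProtocol(proto)

tab   <- buildPatternTable(sim$raster)
fitPL <- fitPseudolikelihood(sim$raster, sim$covariates)
fitCL <- fitConditionalChain(sim$raster, sim$covariates)

X   <- observedSumX(fitPL$model, tab, sim$covariates)
Zcl <- zFromMissingMass(X, missingMass(fitCL$chain, tab, sim$covariates))
Zgt <- zFromMissingMass(X, goodTuringSeries(tab, nBins(X)))
Zex <- exactPartition(fitPL$model, sim$covariates)

ratioDistribution(Zcl, Zex)
ratioDistribution(Zgt, Zex)
```

## Known limitations

* The chain's accuracy degrades as the missing mass grows: at ~7% missing
  mass (high-rate regimes) the 99% band of $Z_{CL}/Z_\mathrm{exact}$ is
  roughly an order of magnitude wider than at ~2%, with the residual error
  concentrated in bins where the drive peaks. Stagings that drift into the
  saturated attractor regime degrade it much further, which is why the
  calibration path avoids that regime by construction.
* Good–Turing corrects bias only; with strong stimulus modulation the
  constant-missing-mass assumption leaves all of the stimulus-driven
  variance in place.
* Pseudo-likelihood coupling estimates for sparsely co-active pairs are
  ridge-bounded but noisy; downstream TAP estimates amplify that noise
  quadratically.
* No L1 coupling selection, no minimum-probability-flow or Monte Carlo
  gradient fitting, no annealed importance sampling, no cluster
  expansions, and no triplet or higher-order interactions: the model is
  strictly pairwise in the $\{0,1\}$ coding.
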