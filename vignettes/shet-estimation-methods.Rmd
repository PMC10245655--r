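---
title: "Estimating s_het from LOF frequencies: models and methods"
author: "shetboost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating s_het from LOF frequencies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shetboost)
```

# The estimation problem

A gene's constraint against loss-of-function (LOF) is summarized by
`s_het`, the reduction in fitness per heterozygous LOF copy. Counting-based
metrics (observed/expected unique LOFs and their confidence bounds) conflate
low statistical power with low constraint for short genes; `shetboost`
instead models the frequency of every individual candidate LOF site with an
explicit population-genetic likelihood and shares information across genes
through an empirical Bayes prior learned from gene features.

The pipeline has four stages:

1. **Curation** (`curateSites()`): filter annotated variants to
   high-confidence LOFs, enumerate invariant sites, impute missing allele
   numbers, and attach per-site mutation rates.
2. **Likelihood** (`siteLikelihoodCurve()`, `geneCompositeLoglik()`): a
   discrete-time Wright-Fisher (DTWF) likelihood of each site's allele
   count over a grid of `s_het` values, combined per gene by composite
   likelihood with a misannotation mixture.
3. **Prior** (`fitPrior()`): gradient-boosted trees map gene features to
   the parameters of a per-gene prior over `s_het`, trained by maximizing
   the marginal likelihood of the LOF data.
4. **Posterior** (`computePosterior()`): per-gene posterior weights over
   the grid, posterior-mean point estimates, equal-tailed 95% credible
   intervals, and selection-regime labels.

# The population-genetic likelihood

## Dynamics

Each site evolves as a DTWF chain on allele counts $0..2N$. One generation
applies, in order:

* **Selection** (genic approximation of additive diploid fitness
  $1, 1-s, 1-2s$, floored at zero):
  $f' = f\,\max(0, 1-s) \,/\, (f\,\max(0, 1-s) + (1-f))$. The degenerate
  source state $f = 1$ with zero allele weight is defined to remain at
  $f' = 1$; it is unreachable under default parameters.
* **Mutation** (one-way, wild-type to LOF): $f'' = f' + (1-f')\mu$. Back
  mutation is omitted: LOF-creating changes dominate at these rates, and
  only forward rates are specified per site.
* **Drift**: binomial resampling of $2N_{t+1}$ alleles at frequency $f''$.

The demography is piecewise constant
(`demographicModel()`/`readDemography()`): an oldest burn-in epoch followed
by epochs with explicit durations. `defaultDemography()` is the desk-scale
default used throughout the tests: burn-in at diploid $N = 100$, then 20
generations at $N = 1000$. Real analyses should supply their own demography
file; computation is exact but $O((2N)^2)$ per generation, so the
population size trades directly against speed.

## Initialization: conditioning on non-fixation

With one-way mutation the fixed class ($f = 1$) is absorbing, so the
unconditioned chain's stationary law is a point mass at fixation and
carries no information. `stationaryDistribution()` therefore computes the
**quasi-stationary distribution conditioned on the LOF not having fixed**
— the equilibrium actually attained by segregating-or-absent sites — by
power iteration of the substochastic transition matrix over doubling
horizons, followed by a single-generation polish. On return, a conditioned
one-generation update moves the distribution by less than `tol` (default
$10^{-12}$ total variation); exceeding the cap of $50 \times 2N$
generations is an error naming the parameters, never a silent return.

## Sampling layer and caching

The sample of `AN` alleles is drawn binomially (with replacement) from the
population frequency; `AN` above the haploid population count is permitted
under this convention but flagged. Present-day allele-count distributions
are cached keyed by (mutation-rate bin, demography hash, grid hash);
rates are binned to three significant digits, which bounds the cache with
negligible likelihood error. An optional `cacheDir` persists the cache as
versioned tab-delimited tables.

## The s_het grid

`defaultSelectionGrid()` uses 101 log-spaced points on $[10^{-8}, 1]$; the
spacing puts the selection-regime boundaries $10^{-4}, 10^{-3}, 10^{-1}$
exactly on grid points. The neutral point $s = 0$ is carried separately by
every site likelihood because the misannotation mixture needs it.

# Composite gene likelihood and misannotation

Sites are combined assuming independence (composite likelihood). Each
annotated LOF is truly loss-of-function with probability $1 - p_{miss}$
and misannotated — evolving neutrally regardless of the gene's constraint
— with probability $p_{miss}$:

$$L_g(s) = \sum_{i \in g} \log\left[(1-p_{miss}) L_i(s) + p_{miss} L_i(0)\right].$$

Invariant sites (AC = 0) contribute exactly like variant sites; their
likelihood is non-decreasing in $s$, which is where the constraint signal
for fully invariant genes comes from. Likelihoods are floored at
$10^{-300}$ before the log; floor hits are counted and reported.

`estimatePMiss()` estimates $p_{miss}$ **before** any feature-based
training (two-stage): it profiles the total marginal log-likelihood under
the re-optimized featureless shared prior over a fixed grid (0 to 0.5 in
steps of 0.01) and returns the maximizer. Profiling before feature
training decouples nuisance estimation from prior fitting and keeps the
estimate deterministic. If the profile is flat to within `flatTol`
(default 1 total log-likelihood unit — fully neutral data cannot identify
$p_{miss}$), the configured default (0.05) is returned with an explicit
flag. A single global $p_{miss}$ is used; per-dataset overrides are a
function argument.

# The empirical Bayes prior

## Family and discretization

The prior on $\log_{10} s_{het}$ is a normal density with parameters
$\theta = (m, \log \sigma)$, truncated to the grid by renormalization:
`discretizePrior()` multiplies the density at the grid points by
trapezoidal log-spacing quadrature weights and renormalizes. The family is
deliberately simple (two interpretable parameters) and sits behind a
narrow interface; the marginal likelihood, gradient and discretization are
the only family-specific pieces.

Two numerical safeguards apply to the featureless fit and are kept during
boosting:

* $\theta$ is **box-constrained**: $m$ within the grid support and
  $\sigma \in [0.05, 3]$. Outside the box the renormalized-truncation
  family is unidentified — every prior far below the grid is the same
  grid-edge point mass — and the optimizer otherwise drifts along that
  flat ridge to a degenerate corner.
* The featureless optimization adds a small **maximum-entropy tie-break**
  (1 nat of pooled log-likelihood per nat of prior entropy). Priors
  concentrated anywhere below the demography's resolvable range of $s$
  have numerically identical pooled likelihoods; among these the most
  diffuse member is the scientifically conservative representative, and
  the tie-break selects it deterministically. The reported featureless
  log-likelihood is evaluated without the entropy term.

## Boosted fitting

`fitPrior()` is an NGBoost-style loop: the featureless baseline $\theta_0$
is optimized on the training genes, then each iteration fits
`treesPerIteration` regression trees per $\theta$ dimension (xgboost, one
CPU thread, native missing-value routing, no imputation) to the per-gene
gradients of the negative marginal log-likelihood, and adds the
learning-rate-scaled tree output to every gene's $\theta$. Gradients are
analytic (`lossGradient()`) and are checked against central finite
differences in the test suite.

Gradient targets are normalized to unit RMS per iteration and dimension,
with the scale multiplied back into the update. This makes the tree-level
regularization hyperparameters (`alpha`, `min_child_weight`) act relative
to the signal scale rather than to the absolute gradient magnitude, which
varies by orders of magnitude with the informativeness of the LOF data.
Optionally (`naturalGradient = TRUE`) gradients are pre-scaled by the
inverse Fisher information of the location/log-scale family,
$\mathrm{diag}(\sigma^2, 1/2)$.

Genes are split by chromosome — train 7–22 and X, validation 2/4/6, test
1/3/5 — so that genomically proximal genes do not leak across sets.
Training stops after 10 validation iterations without improvement, or at
1000 iterations; the iteration with the best validation loss is kept. The
default hyperparameters are the selected values of the full tuning grid
(`fullTuningGrid()`: learning rate 0.04, depth 3, subsample 0.8,
min_child_weight 4, alpha 2, lambda 0, one tree per iteration);
`hyperparameterSearch()` ranks configurations by validation loss with
deterministic tie-breaking (fewer iterations, then config order).
Per-category interpretation models (`categoryModels()`) tune over the
reduced `categoryTuningGrid()`.

The fit is deterministic given `config@seed`; `saveTrainedPrior()` /
`loadTrainedPrior()` persist the ensemble as text and reload predictions
bit-identically.

# Posteriors and summaries

Posterior weights are prior times exponentiated composite likelihood,
normalized per gene with max-subtraction. The point estimate is the
posterior mean on the **natural** scale of $s$. Credible intervals are
equal-tailed 2.5%/97.5% quantiles of the discrete cumulative weights, with
jumps treated as vertical: a point-mass posterior yields a zero-width
interval, and quantiles otherwise land on grid points (grid resolution is
0.08 log10 units). Regime labels partition $(0, 1]$: nearly neutral below
$10^{-4}$, weak from $10^{-4}$, strong from $10^{-3}$, extreme from
$10^{-1}$ (boundaries belong to the higher regime, except $10^{-4}$ which
opens the weak regime).

# Curation defaults

`filterConfig()` defaults: consequence in {splice acceptor, splice donor,
stop gained}; LOF-confidence label "HC"; mean pext $\ge 0.05$; median read
depth cutoff 0x (effectively disabled but exposed); drop
segmental-duplication/low-mappability variants; drop flagged variants.
Rows with missing pext or depth are not dropped by those filters. Filters
are pure predicates — the surviving set is order-independent — and the
audit table counts drops in the documented order. Missing allele numbers
are imputed with the median of observed ANs, separately on autosomes and
X. Coordinates are 1-based fully-closed; the possible-LOF universe is
single-nucleotide changes only.

# The synthetic-data generator

`simulationConfig()` defines the package's standard synthetic study: 800
genes, 20 features (3 informative), 20 sites per gene, AN = 1000,
$p_{miss} = 0.1$, the desk demography, and true
$\log_{10} s_{het} = a_0 + \sum_j a_j\,\mathrm{softsign}(x_j) + \epsilon$
with $a_0 = -1.5$, $a = (1.0, 0.8, 0.6)$, $\epsilon \sim N(0, 0.3^2)$,
clipped to the grid range. Informative features are equicorrelated
(pairwise 0.3), 2% of feature entries are set missing, and chromosomes are
assigned round-robin so every split is populated.

## Desk-scale rescaling

Computing the DTWF exactly caps the usable population size orders of
magnitude below the human ancestral size. The generator therefore applies
the standard population-rescaling logic: as $N$ shrinks, per-site mutation
rates and selection coefficients scale up so the population-scaled
quantities ($\theta = 4N\mu$, $2Ns$) stay in the informative regime. The
mutation-rate table (12 context-style classes log-spaced over
$[10^{-6}, 10^{-4}]$) is calibrated so that a neutral site in the top rate
classes has an appreciable probability of being polymorphic — exactly the
regime in which an invariant high-rate site indicates strong selection —
and the truth distribution is centered two log-units above the human-scale
center for the same reason. Consequently, passing recovery tests
demonstrate the estimator's internal consistency and its statistical
machinery at desk scale; they do not certify point accuracy on real
human-scale data, where the demography, rates and sample sizes differ by
orders of magnitude.

## Simulation mechanics

Sites are simulated in one vectorized forward pass: misannotation
indicators are drawn per site, each site evolves from the LOF-free state
for `burninFactor` $\times\ 2N$ generations of the oldest epoch, and
trajectories that fixed during burn-in are rejection-resimulated — the
conditioned long-run law is the same non-fixation-conditioned equilibrium
the matrix likelihood initializes from. The scalar
`monteCarloForward()` oracle instead samples its start directly from the
quasi-stationary distribution; agreement between the simulator and the
matrix likelihood is itself asserted by the test suite (chi-square at
200,000 replicates on a 3x3 grid of $(s, \mu)$).

## Problem sizes

The test suite runs module tests at diploid sizes 30–100 and the
end-to-end checks at the standard 800-gene study (about two minutes of
computation); `scripts/acceptance.R` re-runs the worked o/e examples, the
gradient check, the simulation-vs-matrix comparison, and the full recovery
experiment from scratch.

# Known limitations

* The likelihood evolves full distributions, so present-day $2N$ beyond a
  few thousand is impractical; large-sample human demographies require the
  fast DTWF machinery this package intentionally does not reproduce.
* The X chromosome is handled only as a feature indicator and a separate
  AN-imputation class; a hemizygous selection model is out of scope.
* Composite independence across sites ignores linkage.
* The prior family is a two-parameter truncated normal; heavier-tailed or
  multimodal per-gene priors are not representable, though the family sits
  behind a narrow interface.
* Desk-scale results are rescaled-regime results (see above).
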