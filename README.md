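# shetboost

Bayesian estimation of gene constraint — the heterozygous selection
coefficient `s_het` — from the frequencies of individual loss-of-function
(LOF) variants, with an empirical Bayes prior learned from gene features by
gradient-boosted trees.

## The problem and the model

Constraint metrics built on counts of unique LOFs (pLI, LOEUF) are
underpowered for the ~25% of genes with few expected LOFs and are not
interpretable as fitness effects. `shetboost` instead:

* models each candidate LOF site's allele count `AC` out of `AN` sampled
  alleles with a **discrete-time Wright–Fisher likelihood**: genic
  selection (offspring weights `1, 1−s, 1−2s`, floored at 0), one-way
  mutation at a per-site rate `μ`, binomial drift through a
  piecewise-constant demography, and a binomial sampling layer — giving
  `P(AC | s)` on a log-spaced grid of `s_het` values (invariant sites,
  `AC = 0`, are first-class data and carry the signal for strongly
  constrained genes);
* combines sites per gene by **composite likelihood with a misannotation
  mixture**: each annotated LOF evolves neutrally with probability
  `p_miss` (estimated from the data by profile likelihood), so single
  misannotated variants cannot destroy a gene's constraint estimate;
* learns a per-gene **prior over `log10 s_het`** (normal, parameters
  `m, log σ`) whose parameters are predicted from gene features by
  NGBoost-style gradient-boosted trees trained to maximize the marginal
  likelihood, with chromosome-based train/validation/test splits and early
  stopping;
* reports per-gene **posterior means, equal-tailed 95% credible
  intervals**, and selection-regime labels (nearly neutral `< 1e-4`, weak,
  strong, extreme `> 1e-1`).

Reference baselines (the observed/expected Poisson 90% upper bound used by
LOEUF, threshold classifiers, matched-background enrichment ratios), the
LOF curation filters, feature-interpretation utilities (percentile-sweep
feature scores, correlation pruning, per-category models) and a synthetic
data generator with a full parameter-recovery harness are included.

## Worked example

Four invariant sites with moderate-to-high mutation rates, under the
desk-scale default demography and a broad prior centered at `s = 1e-2`:

```r
library(shetboost)
dem  <- defaultDemography()          # burn-in N=100, then 20 gen at N=1000
grid <- defaultSelectionGrid()       # 101 log-spaced points, 1e-8..1

sites <- data.frame(
  gene = "GENE1", site_id = paste0("s", 1:4), chrom_class = "autosome",
  mu = c(8e-5, 5e-5, 2e-5, 1e-5), AC = 0L, AN = 1000L)

gl   <- geneCompositeLoglik(sites, grid, pMiss = 0.05, dem)
post <- computePosterior(c(-2, log(0.8)), gl)
summarizePosterior(post)
#>    gene posterior_mean  lower95 upper95 regime
#> 1 GENE1         0.0691 0.000363   0.479 strong
```

Absence of variants at mutable sites pulls the posterior mean to
`s_het ≈ 0.07` — strong selection — but four sites cannot exclude weak
selection, hence the wide interval. The LOEUF-style counting baseline for
a gene set with 3 observed and 139 expected unique LOFs:

```r
oeUpperBound(3, 139)
#> [1] 0.0558   # rounds to 0.06: extreme constraint
```

The full synthetic pipeline — simulate features and LOF data, estimate
`p_miss`, fit featureless and boosted priors, compute posteriors — runs
end to end with:

```r
r <- recoveryExperiment(simulationConfig(seed = 1))
r$spearmanFeatured   # rank agreement of posterior means with the truth
r$coverageFeatured   # empirical 95% credible-interval coverage
r$pMissEstimate      # recovered misannotation probability
```

A thin command-line wrapper over these functions is installed at
`system.file("scripts", "shet_cli.R", package = "shetboost")` with
`curate`, `simulate`, `likelihood`, `fit`, `posterior` and `oe-bound`
subcommands.

## Documentation

The methods vignette (`vignettes/shet-estimation-methods.Rmd`) describes
the model and its assumptions, the numerical choices (quasi-stationary
initialization conditioned on non-fixation, likelihood caching, gradient
normalization, identifiability safeguards), the desk-scale rescaling the
synthetic generator applies, and known limitations.
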