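---
title: "Methods: diachronic weed-survey analysis with weedshift"
author: "weedshift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diachronic weed-survey analysis with weedshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weedshift)
```

## The problem

National weed surveys of arable fields are repeated decades apart, with
different sampling effort, and score species on a six-class
cover-abundance scale rather than counting plants. weedshift implements
the analysis chain that turns such data into ecological conclusions:
which species became more or less common between two survey periods,
whether regional frequency and local abundance move together, and which
biological traits predict a species' success in a focal crop (maize in
the motivating application), while controlling for the phylogenetic
non-independence of species.

## Commonness metrics

Three facets of commonness are computed per species on the **control
plots** (unweeded subplots expressing the field's potential flora):

* **Regional frequency** `F`: the fraction of distinct surveyed fields
  where the species occurs. Fields visited in several years count once;
  the maximum class over visits is kept. (The paper trail for most
  historical surveys aggregates at field level; a `aggregate = "sample"`
  switch treats every visit as a unit instead.)
* **Local mean abundance** `A`: the six-class scale maps to density
  midpoints — classes `+`, 1 and 2 all carry 1.5 individuals/m2 (the
  only reading consistent with the weighted-mean formula the scale was
  designed for), class 3 carries 11.5, class 4 35.5 and class 5 75.5 —
  and `A` is the midpoint mean over the fields of presence:
  `A = [11.5 n3 + 35.5 n4 + 75.5 n5 + 1.5 (N - n3 - n4 - n5)] / N`.
  `A` is therefore always in [1.5, 75.5] and is undefined (an error,
  never silently 0) when a species has no occurrence.
* **Fidelity** to the focal crop: the percentage of a species'
  midpoint-estimated individuals found in the focal crop relative to all
  crops. Midpoints are used because "individuals" cannot be recovered
  from class data any other way; fidelities across crops sum to 100 per
  species.

Changes between periods use the normalized index
`Ch = (S_new - S_old) / (S_new + S_old)`, antisymmetric and bounded in
[-1, 1].

```{r commonness}
mean_local_abundance(2, 1, 1, 10)
change_index(26.5, 39.1)
```

## Status classification by stratified bootstrap

Period designs differ in effort (e.g. 175 vs 484 fields). To compare
like with like, the second period is resampled with replacement
**within regional strata** to the first period's per-region field
counts, and each species' frequency and abundance are summarized over
`B` such resamples (default `B = 1000`; percentile intervals stabilise
well below that). The interval is the plain percentile interval of the
replicate distribution — the simplest reading of a bootstrap CI "around
the mean"; a species absent from a replicate contributes zero frequency
and is excluded from that replicate's abundance mean.

The categorical status of a species compares its first-period point
value to the interval: `+` below the interval, `-` above, `=` inside.
Historical surveys often recorded only their commonest species; species
below that recording floor have no first-period value and are called
`N` (new) when the second-period interval lies entirely at or above the
floor (default 2.3% frequency; 0.5 individuals/m2 for abundance, a
convention inferred from published status calls), and `?` otherwise.

Within-period trends are Spearman rank correlations of the yearly
metric against the year. With typically 7 survey years, p-values come
from the **exact permutation null** (used for n <= 9, with midranks
under ties); the t approximation takes over for longer series. Calls:
`+`/`-` at p < 0.05, `(+)`/`(-)` at 0.05 <= p < 0.10, else `=`.

## Phylogenetic generalized least squares

Species are not independent data points: close relatives have similar
traits and similar fates. The package's central model is GLS with error
covariance proportional to the phylogeny's shared branch lengths
`V[i, j]` (depth of the most recent common ancestor), with two Pagel
transforms:

* **lambda** in [0, 1] multiplies off-diagonal covariances: 0 is a star
  phylogeny (ordinary regression), 1 full Brownian covariance. The
  common phrasing "branch lengths multiplied by lambda" is ambiguous;
  the standard off-diagonal convention is implemented.
* **delta** > 0 raises node depths to a power, after normalizing tree
  depth to 1 so delta is dimensionless. On non-ultrametric trees the
  elementwise form is approximate and a warning is issued.

Estimation maximizes the profile likelihood on a fixed 21-point grid
refined by golden-section search (lambda on [0, 1], delta on
(0.1, 3]); the fixed grid makes results reproducible and the bounded
search robust. The residual variance uses the ML divisor `n` inside the
likelihood, while standard errors carry the `n/(n - p)` correction so
t-tests match the standard GLS convention; with `V = I` the fit
reduces *exactly* to `lm()`. The adjusted R-squared baseline is the
intercept-only GLS under the same covariance, the null a reader of a
GLS F-statistic expects. `lambda_lrt()` compares the fitted model to
`lambda = 0` with a chi-square(1) reference; since 0 is on the boundary
of the parameter space this is conservative, and the documentation says
so rather than halving the p-value silently.

```{r pgls}
tr <- sim_tree(60, seed = 2)
d <- sim_brownian_traits(tr, lambda = 0.7, beta = c(0, 0.5), seed = 3)
fit <- pgls(y ~ x1, d, tr, lambda = "ML")
summary(fit)
lambda_lrt(fit)
```

## Hill-Smith ordination

Trait tables mix quantitative traits (SLA, height, seed weight,
phenology, fecundity, seed longevity, Ellenberg L/N/T, herbicide
sensitivity) with qualitative ones (life form, emergence period,
dispersal mode, photosynthetic pathway). The Hill-Smith design centres
and unit-scales quantitative columns and codes each qualitative level k
as `(indicator - p_k) / sqrt(p_k)`; under this weighting a qualitative
trait with m observed levels contributes inertia m - 1, and an
all-quantitative table reduces exactly to correlation-matrix PCA (a
property the tests verify to 1e-8). Row weights are uniform, as no
species weighting is implied by the design. Axis signs are arbitrary;
each axis is oriented so its largest-magnitude loading is positive, and
published sign patterns are reproducible only up to per-axis
reflection. Contributions are reported both per design column (signed,
absolute values summing to 100 per axis) and aggregated per source
trait, since published contribution tables are ambiguous between the
two. Axis scores join back to species via `axis_scores()` and enter
PGLS jointly (all requested axes in one model per response; axes are
orthogonal in the ordination but not under a phylogenetic metric, so
the joint fit is the honest choice).

## Residual group contrasts

When frequency-abundance residuals retain phylogenetic signal, specific
lineages deviate from the global relationship. Response-scale residuals
are contrasted across taxonomic groups, origin classes
(native/archaeophyte/neophyte) and resistance flags with Kruskal-Wallis
tests, Dunn pairwise z tests on pooled midranks (no multiplicity
adjustment by default, matching common reporting; Bonferroni and Holm
are flags) and a compact letter display built from maximal cliques of
the non-significance graph with deterministic ordering.

## The synthetic-survey generator

The original monitoring data are not redistributable, so every stage is
exercised against a generator that emulates the study design rather
than any particular dataset:

* two periods over five regional strata, defaulting to the historical
  per-region sizes (26, 64, 41, 26, 17; their sum, 174, is what those
  published sizes add to) and a 484-field second period allocated
  proportionally (72, 178, 114, 72, 48);
* right-skewed occupancies from a lognormal truncated to (0, 1)
  (meanlog `log(0.08)`, sdlog 1.1), the few-common/many-rare shape of
  real weed surveys, without asserting any survey-specific law;
* abundance-occupancy coupling `log(mu) = 3.2 + 1.1 log(p)` plus
  lognormal noise, calibrated once so a species occupying ~60% of
  fields averages ~14 plants/m2 and a 3%-occupancy species ~0.5 — the
  magnitudes a maize-field survey reports;
* within-field densities lognormal around the species mean, discretized
  with exhaustive boundaries `<1 -> 1`, `[1, 3) -> 2`, `[3, 20] -> 3`,
  `(20, 50] -> 4`, `> 50 -> 5`, with a literal singleton per plot
  scored `+`. (A rounding-based reading of the printed scale would make
  densities just above 20 fall in class 3; the interval convention
  keeps the bins exhaustive and monotone.)
* every control plot is conditioned on expressing at least one weed, so
  per-region field counts match the design exactly;
* pure-birth trees normalized to unit depth, Brownian responses with a
  tunable lambda (default 0.7, a moderate signal typical of ecological
  performance data), and trait tables drawn inside published min-max
  ranges.

What the generator does **not** emulate: spatial autocorrelation among
fields, herbicide-driven temporal dynamics, trait-trait correlation
structure, or seed-bank memory. Passing tests therefore demonstrate the
statistical machinery (coverage, parameter recovery, reductions to
known special cases), not that any particular field dataset would give
particular answers.

## Numerical choices and degenerate inputs

* Scores accept `"0.5"` as a spelling of the presence class `+`.
* Validation reports offending rows by number and never silently drops
  data; cross-file species keys are case-sensitive and checked before
  any analysis.
* `mean_local_abundance` with `N = 0`, `change_index(0, 0)`, fidelity
  of an absent species, a constant quantitative trait, a singular
  covariance and a rank-deficient design are all errors with
  diagnostics, not silent zeros.
* All-constant values in the group tests return H = 0 / z = 0 (no
  variation, no evidence of difference) instead of the NaN a raw tie
  correction would produce.
* Problem sizes in the test suite and acceptance script (200 x 500
  bootstrap coverage runs on 174-field surveys; 100 lambda-recovery
  replicates at 100 tips; 400 LRT size replicates at 50 tips) were
  chosen to bound Monte-Carlo error at the few-percent level while
  keeping a complete run in well under an hour on one core.

## Known limitations

* The percentile bootstrap undercovers slightly at extreme occupancies
  (coverage ~93-95% at nominal 95% on 174 fields); BCa intervals are
  not implemented.
* The chi-square(1) reference for the lambda LRT is conservative at the
  boundary.
* Fidelity relies on class midpoints, which compress true abundance in
  the open-ended top class; relative fidelities among species are more
  trustworthy than absolute percentages.
* The trait generator draws independent traits; ordinations of real
  trait tables concentrate inertia on fewer axes than its output.
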