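---
title: "Multi-facet diversity partitioning with RaoFacets: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-facet diversity partitioning with RaoFacets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RaoFacets)
```

## The problem

Community ecologists increasingly ask not only how many species co-occur
(taxonomic diversity, TD) but how different those species are in their
traits (functional diversity, FD) and in their evolutionary history
(phylogenetic diversity, PD), and whether each facet is structured by the
contemporary environment (niche processes) or by space (dispersal, drift).
RaoFacets implements that whole chain for presence/absence survey data:
Rao quadratic-entropy partitioning of each facet into within-site (alpha)
and among-site (beta) components, phylogenetic-signal tests for the
traits, spatial eigenvector predictors, and attribution of diversity
variation to environment versus space through forward-selected redundancy
analysis (RDA) and variation partitioning.

## Diversity model

All three facets share one statistic. For a site holding $S$ species with
uniform presence weights $p_i = 1/S$, Rao quadratic entropy is

$$Q = \sum_{i}\sum_{j} p_i\, p_j\, d_{ij},$$

the expected pairwise distance between two randomly drawn occurrences.
The facet lives entirely in the distance matrix $d_{ij}$: species
identity (0/1) for TD, Euclidean distance on retained trait PCA axes for
FD, cophenetic (patristic) tree distance for PD. With the 0/1 distances,
$Q = 1 - 1/S$ — Simpson diversity for presence/absence.

Raw $Q$ is concave in the weights and saturates near 1, so alpha and
gamma are converted to *equivalent numbers* with the Jost transform
$Q^{eq} = 1/(1-Q)$ before any comparison. For TD this maps a site's alpha
exactly onto its richness $S$, a useful end-to-end check that the package
asserts in its tests. Pairwise beta between sites $k$ and $l$ uses the
mean of the two sites' weight vectors for the pair's gamma and is the
proportional excess

$$\beta_{kl} = \frac{\gamma^{eq}_{kl} - \tfrac12\,(\alpha^{eq}_k +
\alpha^{eq}_l)}{\gamma^{eq}_{kl}} \in [0, 1).$$

Three conventions deserve explicit statement:

* **Distance rescaling.** FD and PD distances are divided by their
  maximum over the species pool before Rao computation (the
  `rescale` argument of `diversityProfile()`), keeping raw values inside
  $[0,1)$, the domain of the Jost transform. Beta is therefore invariant
  to any positive rescaling of the input distances; raw alpha is reported
  on the rescaled distance scale.
* **Truncation of negative beta.** The Jost transform is convex, so a
  pair of sites with very uneven alpha can produce corrected gamma
  slightly below the mean corrected alpha. Such negative excess carries
  no turnover information and is truncated at zero. With richness as
  balanced as survey plots usually are, the truncation almost never
  triggers; it is the price of combining pairwise gamma with equivalent
  numbers.
* **Gamma weighting.** The pair's gamma uses the *mean of the two
  within-site weight vectors*, not uniform weights over the union. The
  toy pair {A,B} vs {B,C} fixes the convention unambiguously: gamma
  weights (1/4, 1/2, 1/4), raw gamma 5/8, beta exactly 1/4.

## Phylogenetic signal

Traits are screened for phylogenetic signal with two standard statistics,
computed from the shared-path covariance matrix $C$ of the (ultrametric)
tree:

* **Blomberg's K** compares the observed ratio of the ordinary to the
  phylogenetically corrected mean squared error around the GLS
  phylogenetic mean with its Brownian-motion expectation on the same
  tree; $K = 1$ under Brownian evolution, exactly 1 on an equal-branch
  star tree for any trait. Significance comes from shuffling trait values
  across tips, $p = (1 + \#\{K^\ast \ge K\})/(n_{perm}+1)$, one-tailed.
* **Pagel's lambda** scales the off-diagonal of $C$; its MLE on $[0,1]$
  is found by `optimize()` on the profile likelihood (mean and rate
  profiled out analytically), with the box edges checked explicitly
  because the optimum frequently sits at 0 or 1. Significance is a
  likelihood-ratio test against $\lambda = 0$ on a plain
  $\chi^2_1$ reference. No boundary halving is applied; when
  $\hat\lambda$ is interior this is the usual test, and at the boundary
  it is mildly conservative.

Categorical traits are tested on their numeric codings — the same values
that enter the functional distance — because that is the only scale on
which the community-level analysis sees them. Both statistics are
invariant to affine transformation of the trait, so the particular code
values matter only through their ordering and spacing.

Zero-length branches produced by random polytomy resolution can make $C$
singular; a $10^{-10}$ diagonal jitter is added only when the Cholesky
factorization fails, leaving well-formed trees untouched.

## Environment, space and attribution

Soil and climate tables are reduced separately by correlation-matrix PCA,
keeping the smallest number of leading axes whose cumulative variance
reaches 90% (configurable). The same rule reduces the coded, standardized
trait table before the functional distance, since trait sets are as
redundant as environmental ones.

Spatial predictors are principal coordinates of neighbour matrices
(PCNM): great-circle distances are truncated at the longest
minimum-spanning-tree edge (connectivity-preserving), distances beyond
the threshold replaced by four times it, and the doubly centered
$-\tfrac12 D^{\ast 2}$ matrix eigen-decomposed. All positive-eigenvalue
vectors are returned, each annotated with its Moran's I on the
truncation-neighbour graph; the analysis pipeline uses the subset with
Moran's I above the expectation $-1/(n-1)$, the vectors that model
positive (broad-scale) autocorrelation. On 68 scattered sites the full
basis has roughly 43 vectors while the positive-autocorrelation subset
has about 22; pooling all 43 with the environmental axes would leave a
global permutation test with almost no power at that sample size, which
is why the subset is the default candidate set.

Alpha-scale responses are the per-site equivalent-number alphas
(univariate RDA); beta-scale responses are the principal-coordinate axes
of the beta matrix retained by broken-stick exceedance (leading axes
whose variance share beats the broken-stick expectation; at least one
axis is always kept, since an empty response is useless). RDA is plain
multivariate least squares on standardized predictors; explained variance
is Ezekiel-adjusted, $R^2_{adj} = 1 - (1-R^2)(n-1)/(n-m-1)$, and global
significance comes from permuting response rows.

Forward selection uses the double stopping rule: a global all-candidate
test gates the whole procedure, each entering variable needs a
residual-permutation p-value below alpha (0.05), and selection halts once
the cumulative adjusted $R^2$ reaches the global model's. One detail is
deliberate: the variable that *crosses* the global adjusted $R^2$ is
kept, and selection stops after it. The strict alternative (reject the
crossing variable) empties the selection whenever a single strong
predictor beats the global model's noise-penalized adjusted $R^2$ — a
common situation, not an edge case — and would leave obviously structured
responses with no model at all.

Two-set variation partitioning then decomposes each response into pure
environment $a$, joint $b$, pure space $c$ and unexplained $d$ on
adjusted $R^2$; $a+b+c+d = 1$ algebraically, negative fractions are
reported as-is (except in the headline tests, where only the $a$ vs $c$
ordering is used). When environment and space share columns or structure,
the union's effective predictor count is its matrix rank.

Spatial diagnostics use Moran's I correlograms for per-site values and
Mantel correlograms for beta matrices, on equal-width distance classes
(Sturges' rule by default), with two-tailed permutation tests. The Mantel
statistic is sign-flipped so that positive values mean positive spatial
autocorrelation, the convention correlograms are read with. Residual
correlograms — after regressing values on environmental predictors, or
beta on environmental distance (Mantel residuals) — show how much spatial
structure the environment accounts for.

## What the synthetic generator emulates

`simulateDataset()` builds a complete study under one master seed. Its
defaults are the package's reference conditions, chosen to resemble a
dryland vegetation survey: a 230-species pool on a unit-depth Yule tree;
9 Brownian traits of which 4 are re-expressed as 3-level categories
(quantile bins); 68 sites scattered over a ~330 km rectangle; 8 soil and
6 climate variables; environment-structured assembly.

The landscape generator works through latent Gaussian-process fields
(exponential covariance, 100 km range) rather than independent variables:
soil variables load on 4 latent fields and climate variables on 2, plus
10% measurement noise, so each group's PCA collapses to a handful of
axes — the redundancy that makes the 90% rule meaningful on real
soil/climate tables. Two further parameters express things field data
force on any analysis:

* `nugget` (default 0.3) is site-level microhabitat variance that no
  spatial predictor can capture. Without it, every environmental gradient
  is itself a pure spatial field, environment and space are confounded by
  construction, and the pure-environment fraction of an environment-driven
  community is structurally near zero — no analysis could recover the
  regime.
* `suitFloor` (default 0.05) is a weak background-colonization rate that
  keeps extreme-environment or remote sites occupiable, so the generator
  can honour the "every site holds at least 2 species" requirement of
  presence/absence Rao alpha without silent padding. Sites that still end
  up underfilled are redrawn up to 100 times and then fail loudly.

Assembly is Bernoulli with occurrence probability
`baseProb * max(niche * dispersal, suitFloor)`, a Gaussian niche match
(width `nicheBreadth`, default 0.5 z-score units) between each species'
first quantitative trait and the first environmental variable, times an
exponential dispersal kernel from a random origin site when
`dispersalRange` is finite. Two reference regimes are used throughout the
tests: *environment-driven* (`nicheBreadth = 0.5, dispersalRange = Inf`)
and *dispersal-limited neutral* (`nicheBreadth = Inf, dispersalRange =
100` km), both at `baseProb = 0.25`. The first yields pure-environment >
pure-space for taxonomic beta, the second reverses the ordering, and the
test suite requires each recovery in at least 80% of 25 seeds.

What the generator does *not* emulate: abundance (everything is
presence/absence by design), interspecific interactions, topography as a
separate predictor block, trait–trait correlation beyond what shared
phylogeny induces, non-Gaussian environmental fields, and observational
error in the incidence data. Passing tests therefore demonstrate that the
statistical machinery recovers known structure of this generative family,
not that any particular field system obeys it.

## Numerical choices

* Correlation-matrix PCA eigenvalues from `eigen(symmetric = TRUE)`;
  retained count is the smallest $k$ reaching the variance threshold
  (with a $10^{-12}$ slack against representation error at threshold 1).
* PCNM eigenvector retention at eigenvalue $> 10^{-8} \times$ the
  largest; PCoA likewise, with negative eigenvalues reported untouched.
* Permutation p-values always use the $(r+1)/(n_{perm}+1)$ estimator,
  ties counted as extreme; permutation counts default to 999 in the
  statistical functions and 199 inside the full pipeline.
* `optimize()` tolerance $10^{-8}$ for lambda, box edges re-checked.
* Matrix symmetry is restored explicitly (`(M + t(M))/2`) after chains of
  floating-point operations; beta diagonals are forced to zero.
* Ties in forward selection resolve to the first maximum (`which.max`),
  making selection deterministic under a fixed seed.

The test suite runs its simulations at deliberately moderate sizes —
50-tip trees for signal recovery (200 Brownian replicates for the mean-K
band, 100 each for the lambda medians), 500 null replicates for the K
test calibration, 200 for forward-selection calibration, and 25 seeds per
assembly regime at the full 68-site, 230-species reference conditions —
sizes at which every check is stable under seed changes.

## Known limitations

* Pairwise beta is truncated at zero rather than modelled when alphas are
  extremely uneven (see above).
* The lambda LRT's plain $\chi^2_1$ reference is conservative at the
  $\hat\lambda = 0$ boundary; the qualitative conclusion (signal vs no
  signal) is unaffected in the regimes the tests cover, but boundary
  p-values should not be over-read.
* PCNM counts depend on site geometry; analyses of different surveys
  should compare fractions and orderings, not raw vector counts.
* The "individual contribution" of a forward-selected variable is its
  sequential added unadjusted $R^2$; it depends on selection order and is
  not a variance decomposition.
* `runAnalysis()` trims fine-scale PCNM candidates when the pooled
  candidate count approaches the number of sites; with very small site
  sets the spatial side of the attribution is correspondingly coarse.

## A worked run

```{r, eval = FALSE}
ds <- simulateDataset(seed = 1)
res <- runAnalysis(ds, nPerm = 199, seed = 8)
res$selection[["taxonomic.beta"]]
res$varpart[["taxonomic.beta"]]
```

On the reference conditions this retains a soil axis and a broad-scale
PCNM vector for taxonomic beta and attributes roughly twice as much pure
variance to environment as to space — the qualitative signature of
niche-structured turnover that the dispersal-limited regime reverses.
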