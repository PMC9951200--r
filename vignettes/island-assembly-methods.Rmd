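---
title: "Separating dispersal limitation from environmental filtering in island assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating dispersal limitation from environmental filtering in island assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islecomm)
```

## The inferential problem

A binary species-by-island matrix confounds two classes of assembly
process. Environmental filtering (niche-based, deterministic) sorts
species along gradients of island area, elevation, habitat diversity and
vegetation cover; dispersal limitation (stochastic, spatial) produces
distance decay of compositional similarity even across environmentally
identical islands. Neither a raw beta-diversity value nor a single
correlation separates them, because geographic and environmental distances
between islands are themselves correlated. islecomm implements a chain of
mutually reinforcing analyses that attack the confound from several
directions at once, plus a synthetic archipelago generator whose assembly
regime is known exactly, so that every stage of the chain can be validated
end to end.

## Beta diversity against six null models

Beta diversity is the pairwise Jaccard distance on presence/absence data,
`JD = 1 - C/(A + B + C)`, averaged over all `n(n-1)/2` island pairs. A
pair of islands that are both empty has no defined Jaccard distance; such
pairs are excluded from the mean rather than imputed, and a randomized
matrix in which *no* pair is defined propagates an `NA`, which is exactly
the behaviour sparse taxa show under equiprobable randomization.

The observed mean is calibrated against six binary null models named by
their row (species) and column (island) constraint — Equiprobable,
Proportional to the observed margin, or Fixed: EE, EF, PE, PF, FE, FF.
They span a gradient of conservatism: EE destroys both margins (most
liberal), FF preserves both exactly (most conservative). FF is sampled
with curveball trades, which converge to the uniform distribution on the
margin-constrained set; we burn in with `10 * n_species` trades and thin
successive ensemble samples with `n_species` trades. The suite verifies
uniformity by exhaustive enumeration on small matrices. The default
ensemble size is 1000 randomizations per model (configurable); observed
and expected values are compared by a one-sample t-test of the null values
against the observed value, alongside the standardized effect size
`SES = (obs - mean_null)/sd_null`.

## Null-calibrated partial Mantel tests

Distance decay is tested as the partial correlation of beta diversity with
geographic distance, controlling environmental divergence (Euclidean
distance over z-scored island attributes: area, maximum elevation,
vegetation coverage, habitat richness by default). Coordinates are
projected to a local planar frame by an equirectangular projection about
the centroid (`R = 6371 km`); at the tens-of-kilometres extents this
package targets the planar error against great-circle distances is on the
order of 0.1%. Significance uses the standard permutation scheme
(999 permutations by default) permuting the island labels of the first
matrix only, with one-tailed (`greater`) default, matching the directional
distance-decay hypothesis; p-values have resolution `1/(n_perm + 1)` and
are never zero. Undefined pairs are masked, and masks travel with the
permuted labels. On top of the observed test, the same partial correlation
is computed for each matrix of a null-model ensemble, giving a
null-expected distribution of partial correlations against which the
observed value is calibrated — the step that distinguishes genuine spatial
structure from artefacts of richness and occupancy margins.

## PCNM spatial eigenvectors and forward selection

Spatial predictors are principal coordinates of neighbour matrices:
pairwise distances above a truncation threshold (the longest
minimum-spanning-tree edge, the smallest value keeping the neighbour graph
connected) are replaced by four times the threshold, the modified matrix
is Gower-centred and eigen-decomposed, and axes with positive eigenvalues
(retention tolerance `1e-10` of the leading eigenvalue) form an
orthogonal, centred basis ordered from broad to fine spatial scales.

Because stepwise selection among many orthogonal axes inflates type-I
error if each candidate is tested naively, `forward_select()` uses the
two-stage scheme advocated by Blanchet, Legendre and Borcard: a global
permutation pseudo-F test of all candidate axes gates the procedure (no
global signal, no selection), and only then are axes admitted greedily —
largest added constrained inertia first, lowest index on ties — each
tested by permutation of the reduced-model residuals at the admission
level `alpha` (default 0.05). The stopping rule is significance-only; no
adjusted-R² ceiling is applied. The suite checks both sides of the
trade-off: on spatially unstructured communities the selection is empty in
at least 90% of replicates, while communities assembled under a dispersal
kernel yield a non-empty, signal-bearing selection.

## CCA variance partitioning

Species composition is partitioned with canonical correspondence analysis
in the chi-square metric, sites weighted by their share of total
occurrences, rare species *not* down-weighted. With covariables, both the
chi-square residual matrix and the constraints are residualized on the
covariable space first (partial CCA). Empty islands are dropped from the
ordination with a warning, since the chi-square transform is undefined for
a zero site margin; constraint columns fully absorbed by the covariables
are removed from the projection basis rather than allowed to contribute
numerical noise. The engine is validated cell-for-cell against an
independently coded brute-force oracle (explicit double centring, normal
equations, dense eigendecomposition) to `1e-10`, and against vegan's
`cca()` on shared cases.

The partition between a spatial set (forward-selected PCNM axes) and an
environmental set reports `a` (spatial, independent), `c` (environmental,
independent), `b = total - a - c` (confounded, possibly negative) and the
total explained fraction, all as percentages of total inertia, with
permutation pseudo-F p-values for the two independent fractions
(residual-permutation under the reduced model). The environmental set
defaults to seven variables — area, maximum elevation, shape irregularity,
vegetation coverage, habitat richness, and the two isolation measures ISW
and ISD — with the isolation-specific partition using ISW + ISD (df = 2)
against the remaining five, reporting the isolation fraction independent
of the other variables, the confounded part (marginal minus independent),
and the total explained by the full seven-variable set.

## Species–area relationships

Richness is regressed as `ln(S + 1)` on `ln(A)` (areas in m²) by ordinary
least squares; the `+1` offset retains zero-richness islands, natural logs
throughout. The slope `z` is unit-invariant; the reported `r` is the
correlation of the transformed variables. `compare_z()` ranks fitted
slopes together with externally published `(C, z, r)` rows, supporting the
cross-biota comparison in which steeper slopes indicate stronger
isolation effects.

## Island-level metrics

Shape irregularity is Patton's index `P / (2 sqrt(A pi))` (1 = circle).
The water-isolation fraction ISW is computed on a rasterized land/water
mask as the water share of cells whose centres fall within a 500
m-diameter circle about an island point (the centroid for synthetic data;
polygon GIS is out of scope and field users may supply precomputed
values). Sampling adequacy of a specimen inventory uses the mean species
accumulation curve over random reorderings of the collection sequence,
fitted with the Clench (Michaelis–Menten) asymptotic model — the standard
choice for specimen-based accumulation; the family is a package choice
since only "asymptotic" behaviour is required. The sampling error is
`(E - O)/E * 100` with `E` the fitted asymptote; fits that undershoot the
observed richness, or curves still in their linear regime (no finite
asymptote; the linearized double-reciprocal fall-back then reports an
infinite asymptote and 100% error), are flagged as undersampled. The
default flag threshold is 10%, the conventional adequacy margin for
island inventories.

## The synthetic archipelago generator

`generate_archipelago()` places islands uniformly in a square extent
(default 168 islands in 30 km, echoing a large lake-island system), draws
areas log-uniform between 0.25 ha and 100 ha, and generates environmental
attributes as spatially autocorrelated Gaussian random fields (exponential
covariance, range one fifth of the extent) so that environment and space
are realistically — not pathologically — confounded. Habitat richness
additionally increases with log area; the extent boundary plays the role
of the mainland shore for the isolation measures.

`generate_community()` assembles each species from a random source island
with occupancy probability

```
p_ij = q * exp(-d(source_i, j)/lambda) * exp(-(e_j - mu_i)^2 / (2 sigma^2)) * (A_j/A_max)^w
```

an exponential dispersal kernel (scale `lambda`), a Gaussian niche
response on one environmental axis (breadth `sigma`), and a power-law area
effect (`w`), with independent Bernoulli draws per cell. `lambda = Inf`
switches dispersal limitation off and `sigma = Inf` switches filtering
off; with both off and `w = 0` the cells are iid Bernoulli(`q`). The
exponential kernel is a deliberate simplification — real spore shadows are
better described as fat-tailed — so the generator emulates the *signal
structure* of distance decay, not the mechanics of spore transport; nor
does it model colonization–extinction dynamics, species interactions or
phylogenetic structure. Passing tests therefore demonstrate that the
statistical chain recovers known regimes under clean conditions, not that
any particular field system is dispersal-assembled.

`scenario_suite()` fixes four regimes on a common footing of 60 islands
and 200 species: `dispersal_only` (`lambda = extent/10 = 3000` m,
`sigma = Inf`), `environment_only` (`lambda = Inf`, `sigma` = half the sd
of the elevation axis), `mixed` (both, plus `w = 0.25`), and `neutral`
(neither, `q = 0.3`). The structured scenarios use a source occupancy
`q = 0.8` so that the signal is carried by occupancy pattern rather than
overall fill. These sizes keep a 200-replicate type-I experiment and a
100-replicate power experiment within a few minutes on one CPU while
leaving the tests well away from small-sample degeneracy.

## Numerical and design choices

* **Randomness.** All stochastic steps draw from R's global RNG;
  `run_pipeline()` expands one master seed into independent per-stage
  seeds so stages can be re-ordered or skipped without changing the
  others' output, and the run manifest records everything needed to
  reproduce each table byte for byte.
* **Ensemble sizes.** The literature this package follows reports both
  1000 randomizations and test degrees of freedom implying 10,000; the
  default is 1000, configurable, and the discrepancy is surfaced rather
  than resolved.
* **Degenerate inputs.** Zero-variance distance matrices raise errors;
  a zero-variance covariable reduces the partial Mantel test to the simple
  one with a message; numerically degenerate partial correlations
  (`|r| >= 1 - 1e-12` with the covariable) are refused; zero-variance
  environmental columns are dropped with a warning before standardization.
* **Tie-breaks.** Forward selection breaks added-inertia ties to the
  lowest candidate index; `compare_z()` preserves input order on tied
  slopes. Both make reruns deterministic under a fixed seed.
* **Welch correction.** Between-taxon comparisons of beta-value
  distributions use Welch's t-test on pair values. Pair values within a
  distance matrix are not independent, so this is a descriptive
  comparison, kept for continuity with standard practice rather than
  corrected.
* **p-values.** All permutation p-values are `(1 + #{perm >= obs})/(n_perm + 1)`;
  no multiple-testing adjustment is applied anywhere in the pipeline.

## Known limitations

Occurrence matrices are binary only (no abundance-based beta diversity,
no Sørensen variant, no turnover/nestedness partition). PCNM uses the
classical truncated-distance construction, not generalized Moran
eigenvector maps, and negative-eigenvalue axes are discarded. The CCA
fractions are raw, not adjusted-R² fractions, so they grow mechanically
with predictor degrees of freedom — the permutation tests, not the raw
percentages, carry the inferential weight when predictor sets differ in
size. ISW on real coastline polygons and any GIS ingestion are out of
scope.
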