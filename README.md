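# islecomm

Dispersal limitation versus environmental filtering in island species
assemblages.

## What problem this solves

Ecologists surveying species on islands or habitat fragments face a
classic confound: compositional differences between islands can arise from
deterministic niche sorting along environmental gradients (area,
elevation, habitat diversity, cover) or from stochastic dispersal
limitation, which produces distance decay of similarity even between
environmentally identical islands. Because geographic and environmental
distances are themselves correlated, no single statistic separates the two.
islecomm implements the multi-perspective inference chain used in island
biogeography to attack the confound from several directions at once:

* **Jaccard beta diversity against six binary null models.** Mean pairwise
  Jaccard distance `JD = 1 - C/(A+B+C)` is calibrated against randomized
  matrices under six margin schemes (EE, EF, PE, PF, FE, FF: Equiprobable /
  Proportional / Fixed on the species and island sides), with FF sampled by
  curveball trades. Observed vs expected is summarized by a one-sample
  t-test and the standardized effect size `SES = (obs - mean)/sd`.
* **Null-calibrated partial Mantel tests.** The partial correlation of
  beta diversity with geographic distance controlling environmental
  divergence, `r_AB.C = (r_AB - r_AC r_BC)/sqrt((1-r_AC^2)(1-r_BC^2))`,
  with island-label permutation for significance, and the same statistic
  computed over null-model ensembles to give expected distributions.
* **PCNM + partial CCA variance partitioning.** Spatial eigenvectors from
  principal coordinates of neighbour matrices, a global-test-gated forward
  selection, and chi-square-metric (partial) canonical correspondence
  analysis partitioning compositional inertia into spatial, environmental,
  confounded and isolation-specific percentages.
* **Species–area relationships.** OLS fits of `ln(S+1) = C + z ln(A)` and
  ranking of `z` across taxa, including externally published slopes.
* **Island metrics.** Patton's shape index `P/(2*sqrt(A*pi))`,
  water-isolation fraction within a 500 m circle on a raster mask, and
  Clench-model species-accumulation checks of sampling adequacy.
* **A synthetic archipelago generator** with known dispersal (`lambda`)
  and niche (`sigma`) parameters, used by the test suite to verify that
  the whole chain recovers known assembly regimes.

See the vignette `vignettes/island-assembly-methods.Rmd` for the models,
assumptions and design decisions.

## Worked example

A 60-island, 200-species archipelago assembled under pure dispersal
limitation (exponential kernel, scale 3 km on a 30 km extent), analysed
exactly as a field dataset would be:

```r
library(islecomm)
suite <- scenario_suite(seed = 42)
sc <- suite$dispersal_only

m    <- sc$matrix                                   # species x islands, 0/1
beta <- pairwise_beta(m)
geo  <- geographic_distance(sc$archipelago$coords)
env  <- environmental_distance(sc$archipelago$islands)

mean_beta(beta)
#> 0.9767

set.seed(1)
partial_mantel(beta, geo, env, n_perm = 999)
#> Mantel statistic r = 0.5283, permutation p = 0.001 (greater, 999 permutations, n = 60 islands)

set.seed(2)
nexp <- null_expected_partial_mantel(m, "EE", n = 200, geo = geo, env = env)
nexp$comparison[c("expected_mean", "ses")]
#> expected_mean 0.0010, SES 22.6

basis <- pcnm_basis(sc$archipelago$coords)
#> PCNM basis: 37 positive axes over 60 sites (truncation 6735 m)
set.seed(3)
sel <- forward_select(m, basis, alpha = 0.05, n_perm = 199)   # 34 axes admitted

envtab <- sc$archipelago$islands[, c("area_m2", "elevation_m", "sha",
  "veg_coverage", "habitat_richness", "isw", "isd_m")]
rownames(envtab) <- sc$archipelago$islands$island_id
set.seed(4)
variance_partition(m, sel$vectors, envtab, n_perm = 199)
#> Variance partitioning (% of total inertia 20.7370):
#>   set1 independent (a):  60.86%  (df = 34, p = 0.005)
#>   set2 independent (c):   9.53%  (df = 7, p = 0.005)
#>   confounded       (b):   5.16%
#>   total explained     :  75.55%
```

Reading the numbers: the community is highly dissimilar between islands
(mean Jaccard distance 0.977); beta diversity correlates strongly with
geographic distance after controlling environment (partial r = 0.53,
p = 0.001), sitting 22.6 null standard deviations above the
equiprobable-null expectation of ~0; and the forward-selected spatial
eigenvectors independently explain six times more compositional inertia
than the seven environmental variables — the signature of
dispersal-limited assembly, which is exactly the regime this scenario was
generated under. (The raw spatial percentage also reflects its larger
predictor count, which is why the permutation tests, not the raw
percentages, carry the inference.)

The full pipeline — all tables plus a JSON manifest — runs from one
configuration:

```r
run_pipeline(list(matrix = "matrix.csv", islands = "islands.csv",
                  taxa = "taxa.csv", out_dir = "results", seed = 1))
```

or from the shell via `inst/scripts/islecomm.R` (`simulate` and `run`
subcommands).

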