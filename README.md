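# pondvarpart

Nonlinear variation partitioning for metacommunities, built for multi-taxon
temporary-pond surveys in which ~30 ponds are sampled repeatedly (early /
mid / late hydroperiod) and the question is how much of the community
structure is driven by environmental selection, spatial processes
(dispersal limitation), and time (succession).

It is aimed at community ecologists who would otherwise chain vegan,
mgcv-style GAMs and a latent-variable ordination by hand: the package wires
those stages into one tested pipeline and adds the pieces that are usually
missing — a double-stopping forward selection for GAM smooths, an exact
inclusion–exclusion partition of GAM adjusted R², and a spatially
constrained null correction for spurious environment–space overlap.

## The method

For each taxon's presence–absence matrix `Y` (samples × species):

1. **Response construction.** Fit a binomial latent variable ordination
   with no predictors, `P(y_ij = 1) = logit⁻¹(β0_j + z_iᵀγ_j)`,
   `z_i ~ N(0, I_d)`, by a variational (Jaakkola–Jordan) approximation;
   pick `d` by AIC. The latent site scores `z` are the multivariate
   response — one Gaussian GAM per axis.
2. **Predictors.** Environmental variables are transformed (log /
   arcsine-square-root by distribution shape) and condensed to their first
   three principal components; space enters as one bivariate thin-plate
   smooth of planar coordinates; time (pooled design only) as a smooth of
   days since first sampling. Nine basis functions per variable, GCV
   smoothness selection (γ = 1.4), forward selection with a
   double-stopping criterion (p < 0.05, global-R² ceiling, ≤ 3 predictors
   per snapshot model).
3. **Partition.** Per axis, fit the component models (E, S, [T] and their
   unions), average adjusted R² across axes, and decompose by
   inclusion–exclusion into `(E|S)`, `(S|E)`, `E∩S` — or the seven
   fractions of the pooled E+S+T model. Corrections against Moran spectral
   randomization nulls (surrogate environments preserving each variable's
   variance and Moran's I exactly) remove the spurious part of the
   environmental fractions. Negative fractions are truncated at zero and
   renormalized for the relative view.
4. **Comparisons.** PERMDISP (spatial-median variant) contrasts
   environmental heterogeneity between groups; exact paired Wilcoxon
   signed-rank tests (full 2ⁿ enumeration via convolution) compare the
   snapshot and pooled designs across taxa.

A synthetic metacommunity generator with known environmental, spatial and
temporal effect sizes makes every stage verifiable end to end.

## Worked example

```r
library(pondvarpart)

ds <- simulate_metacommunity(sim_config(beta_E = 2, beta_S = 0.5, beta_T = 0.5,
                                        env_spatial_weight = 0.4, seed = 42))
ds
#> Pond metacommunity dataset
#>   90 samples (30 ponds x 3 occasions)
#>   10 environmental variables (4 climatic, 6 limnological)
#>   taxa: taxon1 (60 spp)

sf  <- ds$sample_frame
pca <- pca_reduce(transform_env(ds$env, ds$env_meta)$env)
pca
#> Environmental PCA: 90 samples, first 3 components
#>   explained variance: 20.6%, 16.3%, 12.3% (cumulative 49.2%)

axes <- select_latent_dimension(ds$communities[[1]], d_max = 3, seed = 1,
                                n_starts = 2)
axes
#> Latent axes: d = 3 (AIC-selected), 90 samples
#>  d      aic converged
#>  1 7015.870      TRUE
#>  2 6821.777      TRUE
#>  3 6771.745      TRUE

dat <- data.frame(pca$scores, x_km = sf$x_km, y_km = sf$y_km,
                  days_since_first = sf$days_since_first)
vp <- partition_three(axes,
        E_terms = lapply(paste0("PC", 1:3), smooth_spec),
        S_terms = list(smooth_spec(c("x_km", "y_km"))),
        T_terms = list(smooth_spec("days_since_first", k = 3)),
        data = dat, correction = TRUE, n_null = 99, seed = 1,
        coords = cbind(sf$x_km, sf$y_km), occasions = sf$occasion,
        pond_index = as.integer(factor(sf$pond_id)))
relative_fractions(vp)
#> Variation partitioning: environment (E) + space (S) + time (T)
#>   total adjusted R2 (E+S+T): 0.6933 over 3 axes
#>                raw corrected truncated relative
#> pure_E      0.3923    0.3673    0.3673   0.6521
#> pure_S      0.0301    0.0301    0.0301   0.0535
#> pure_T      0.0001    0.0001    0.0001   0.0002
#> ES_given_T  0.1090    0.0648    0.0648   0.1151
#> ET_given_S  0.1717    0.0347    0.0347   0.0616
#> ST_given_E  0.0032    0.0032    0.0032   0.0056
#> EST        -0.0131    0.0630    0.0630   0.1118
```

Reading the output: this community was generated with a strong
environmental effect (`beta_E = 2`) and mild spatial/temporal effects, and
the partition recovers that — pure environment dominates (65% of the
explained variation), pure space and pure time are small. Because the
limnological variables shift between occasions, part of the temporal signal
rides on the environment and shows up as temporally structured environment
(`ET_given_S`), which the MSR correction then trims (0.17 raw → 0.03
corrected): most of that overlap is reproducible under environment
surrogates with the same spatio-temporal autocorrelation, i.e. not evidence
of a genuine species–environment match.

Full surveys are driven by `run_spatial_approach()` (per-period snapshots),
`run_spatiotemporal_approach()` (pooled model), or `run_both_approaches()`
(both, plus Wilcoxon comparisons and PERMDISP heterogeneity contrasts),
each taking a `run_config()` and an optional output directory for CSV/JSON
results.

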