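---
title: "Nonlinear variation partitioning for pond metacommunities: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear variation partitioning for pond metacommunities: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Metacommunity ecology asks how much of the variation in community
composition across sites is driven by environmental selection (species
sorting), how much by spatial processes such as dispersal limitation, and —
when surveys are repeated over time — how much by temporal dynamics such as
succession. The classical tool is variation partitioning: regress a
multivariate community response on environmental (E) and spatial (S)
predictor sets, and decompose the adjusted R² of the joint model into
unique and shared fractions by inclusion–exclusion.

`pondvarpart` implements a nonlinear version of this framework aimed at
temporary-pond surveys of the kind where ~30 ponds per region are sampled
three times across one hydroperiod (early, mid, late) for several taxonomic
groups. Two analysis designs are supported:

* the **spatial approach**: each sampling period is analysed as a separate
  snapshot, partitioning variation into (E | S), (S | E) and E ∩ S;
* the **spatio-temporal approach**: all periods are pooled into a single
  model with a temporal predictor (days since each pond's first sampling),
  giving seven fractions — (E | S+T), (S | E+T), (T | E+S), (E ∩ S) | T,
  (E ∩ T) | S, (S ∩ T) | E and E ∩ S ∩ T.

Both designs share four methodological choices that define the package:

1. **GAM smooths instead of linear regressions.** Every predictor enters as
   a penalized regression spline, so environmental responses and spatial
   patterns are modelled with matched (nonlinear) flexibility.
2. **Latent ordination scores as the response.** Each binary community
   matrix is summarized by a binomial generalized linear latent variable
   model with no predictors; the AIC-selected latent site scores become the
   multivariate response, one GAM per axis, and the canonical adjusted R²
   is the unweighted average across axes.
3. **Forward selection with a double-stopping criterion**, keeping models
   tractable at ~30 sites.
4. **A spatially constrained null correction of the environmental
   fractions**, using Moran spectral randomization (MSR), because a
   spatially structured environment can explain community structure for
   purely spatial reasons.

## The GAM engine

For a single latent axis `y` the model is
`y = α + Σ_t f_t(x_t) + ε` with Gaussian errors. Each 1D smooth is a cubic
regression spline in the values-at-knots parameterization: `k` knots (default
9, i.e. "nine splines per variable") at covariate quantiles, penalty equal to
the integrated squared second derivative. The spatial term is a single
bivariate thin-plate-style smooth of planar coordinates: radial basis
`r² log r` on `k` knots chosen by a deterministic space-filling subset of
the sites, polynomial null space {1, x, y}, bending-energy penalty.
Supplied longitude/latitude are projected to planar km by an equirectangular
projection about the site centroid — at the ~100 km extents this package
targets, projection distortion is negligible. Every term absorbs a
sum-to-zero constraint, leaving `k − 1` free columns and at most `k − 1`
effective degrees of freedom (edf).

Smoothing parameters are chosen by GCV, `n·RSS/(n − γ·edf)²`, coordinate
descent with golden-section search on log λ per term, cycling until the
fitted values stabilize (max change < 1e-8). Two numerical choices matter:

* **γ = 1.4, not 1.** At n ≈ 30 with k = 9 smooths, plain GCV occasionally
  undersmooths, and because λ is tuned to the data this inflates the
  adjusted R² of irrelevant terms (we measured a systematic ≈ 0.07 spurious
  pure-spatial fraction in simulations with no spatial signal). The
  conventional γ = 1.4 inflation removes almost all of this bias (to
  ≈ 0.01) while leaving genuine signal essentially untouched. GCV was
  preferred over REML for determinism and simplicity; the direction of any
  difference from a REML-based run is unknown.
* **Duplicate-term collapse.** If two components supply numerically
  identical term designs (e.g. the same smooth reaching a model through
  both E and S), the duplicate is dropped before fitting. Keeping both
  would silently halve the effective penalty and break the redundancy
  identities of the partition (a component shared by two sets must
  contribute exactly zero unique variation).

Adjusted R² is `1 − [RSS/(n − edf)] / [TSS/(n − 1)]` with edf the trace of
the hat matrix; for an unpenalized fit this is exactly the classical
Ezekiel adjustment, which is what makes the linear limit of the partition
(`linear = TRUE`, every smooth replaced by its penalty null space)
numerically identical to classical linear variation partitioning — the
package asserts this bridge against vegan's `varpart` in its tests. Term
p-values are Wald-type tests on the penalized coefficients with rank equal
to the rounded term edf; they are approximate, and are used only for
forward selection, not for inference reported to the user.

Forward selection fits the global model (all candidates) first, then adds
greedily the candidate giving the largest adjusted R², stopping when the
best candidate's p-value exceeds α = 0.05, when the selected model reaches
the global adjusted R², or at the term cap (3 predictors total in the
snapshot design, a sample-size constraint; the environmental selection is
re-run with a tighter cap if the spatial term already claimed a slot). If
nothing is selected but some candidate is significant alone, that single
candidate is kept. With several latent axes, selection runs per axis and
the union (ordered by how many axes chose each candidate) is used, capped
as above — the partition then uses one term set per component for all axes.

## The latent-variable response

The ordination model is `P(y_ij = 1) = logit⁻¹(β0_j + z_iᵀγ_j)` with
`z_i ~ N(0, I_d)` and loadings constrained upper-triangular with positive
diagonal. It is fit by a variational Gaussian approximation under the
Jaakkola–Jordan quadratic bound to the Bernoulli-logit likelihood, which
makes every update — the bound's tightening parameters, the per-sample
Gaussian, the species parameters — an exact closed-form coordinate-ascent
step, so the evidence lower bound (ELBO) increases monotonically (an
invariant the tests assert). The per-sample variational covariance is kept
as a full d×d matrix: at d ≤ 5 this costs nothing and is strictly more
accurate than a diagonal restriction. Three random starts are run by
default and the best bound kept; tests check that independent seeds land on
bounds within 1e-3.

The number of axes d is chosen by AIC, `−2·ELBO + 2·p` with
`p = m + (m·d − d(d−1)/2)` (species intercepts plus free loadings),
over candidates 1..d_max (default 5; the latent structure of interest at
these problem sizes is low-dimensional). The ELBO is a lower-bound
surrogate for the log-likelihood; simulation tests show it selects the
generating dimension in the majority of replicates and recovers simulated
site scores with Procrustes correlation above 0.8 at n = 90, m = 60.
Species present or absent everywhere are dropped (their likelihood
contribution is degenerate). Downstream results are invariant to the
reflection indeterminacy of the scores, which the tests assert by flipping
axis signs and re-partitioning.

## Partitioning and the MSR correction

With component models fitted per axis and averaged, the two-way fractions
are `pure_E = R²(E+S) − R²(S)`, `pure_S = R²(E+S) − R²(E)`,
`common = R²(E) + R²(S) − R²(E+S)`; the three-way case uses the analogous
Möbius inversion over the seven models E, S, T, E+S, E+T, S+T, E+S+T.
Adjusted-R² fractions can be negative; raw values are always reported, and
the relative view truncates negatives at zero before renormalizing by the
truncated total (the standard convention for plotting non-negative shares).
A constant temporal covariate (single occasion) degrades gracefully: the
temporal block is treated as empty and all temporal fractions are exactly
zero.

The environmental correction works on the predictors: each environmental
variable (in practice the three PC scores) is replaced by Moran spectral
randomization surrogates — its centered decomposition on the Moran
eigenvector basis with randomly sign-flipped coefficients. Sign flipping is
an orthogonal remixing that preserves each variable's variance and Moran's
I *exactly* (the tests require 1e-6), while destroying any genuine link to
the response. The eigenvector basis is built from a Gabriel graph over the
ponds, Sinkhorn-balanced towards double stochasticity, restricted to the
orthogonal complement of the constant vector (this restriction, rather than
dropping one eigenvector after the fact, is what keeps the basis exactly
orthonormal when the zero eigenvalue is degenerate). For the pooled
three-way case the basis is the Kronecker combination of the spatial
eigenvectors with chain-graph temporal eigenvectors over the ordered
occasions, so surrogates preserve spatio-temporal autocorrelation; this
requires a complete pond × occasion panel.

Under each of `n_null` (default 199) nulls, every E-containing model is
refit and the environmentally labelled fractions recomputed; their null
means — the spurious, purely spatially/temporally induced part — are
subtracted from the observed fractions. Two design points:

* **Null refits hold λ fixed** at the observed fits' smoothing parameters
  (per model and axis). Re-tuning λ to every surrogate would add a generic
  overfitting offset to the null mean that has nothing to do with spatial
  structure; with fixed λ the null mean is ≈ 0 when the environment is
  spatially unstructured, which is the behaviour that makes the correction
  interpretable. This is the GAM analog of comparing models of fixed
  complexity under the null.
* Only environmental fractions are corrected; `pure_S` (and `pure_T`) are
  left as estimated. With fewer than 4 ponds the correction is unavailable
  and the raw partition is returned flagged.

The correction design adapts a method formulated for linear models with
spatial eigenfunction predictors; its transfer to coordinate smooths is one
faithful reading, and the output records the method used.

## Auxiliary inference

**PERMDISP** compares multivariate environmental heterogeneity between
groups (regions, or sampling periods): Euclidean distances on standardized
transformed variables, principal-coordinate embedding with a spatial median
per group (vegan's `betadisper`, type `"median"`; a centroid switch is
provided), one-way F on the distances, and a permutation p-value from
seeded reshuffling of group labels, `p = (#{F* ≥ F}+1)/(n_perm+1)`.
Climatic and limnological variable classes are analysed separately as well
as jointly — the classes are disjoint and their union is all variables.

**Exact paired Wilcoxon tests** compare the two approaches across taxa. The
exact two-sided p-value is computed from the full distribution of the
signed-rank statistic V over all 2ⁿ sign assignments of the observed
midranks, by generating-function convolution (identical to complete
enumeration, feasible to n = 25); `p = min(1, 2·min(P(V* ≤ V), P(V* ≥ V)))`.
With 7 taxa and differences all of one sign, V is 0 or 28 and
p = 2/2⁷ ≈ 0.016. For the comparison, the snapshot value per taxon is the
mean over periods of each relative fraction, and the pooled value is the
corresponding fraction renormalized over the E+S mass only (excluding
temporal fractions), making the two designs commensurable.

## The synthetic generator

Because the package must be verifiable without field data, it ships a
generator whose defaults emulate the target study design: 30 ponds placed
uniformly in a 120 km square (≈ 1.4·10⁴ km²), 3 occasions at 0/150/250
days spanning a hydroperiod, 60 species per taxon, 4 climatic + 6
limnological variables, and a 7-taxon wrapper mirroring the major
freshwater groups (bacteria, archaea, phytoplankton, rotifers,
microcrustaceans, macroinvertebrates, amphibians). Environmental variables
are Gaussian random fields over the ponds (exponential covariance, default
range 30 km, Cholesky-realized — exact at these n) blended with independent
noise; climatic variables are constant within ponds across the hydroperiod
while limnological ones receive occasion shifts. Occupancy follows
`logit⁻¹(a_s + β_E f_s + β_S u_s + β_T g_s)` with each component
standardized to unit variance so the β are commensurable effect sizes
(default 1 each — a balanced regime; the recovery scenarios in the tests
set one β to 2 and the others to 0). Species environmental responses are
linear by default (unimodal available); residual-spatial components mix two
shared smooth fields with species loadings; the temporal trend is a
half-sine over the hydroperiod (a simple succession proxy) with
species-specific amplitude.

What the generator does *not* emulate: clustered pond configurations
(placement is uniform; the spatial layouts of real surveys are patchier),
species interactions, dispersal kernels, hydrological drying/filling, and
zero-inflation or detection error. Passing recovery tests therefore shows
the estimator identifies the processes it models, under its own data model
— not that real pond data meet those assumptions.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds; a fixed seed reproduces
datasets, fits and permutation p-values bit for bit. The test-suite and
acceptance-script simulations use the study-scale design (30 ponds × 3
occasions × 60 species) with sizes chosen for a thorough but proportionate
run: recovery scenarios use 10 replicates each with d = 2 latent axes;
latent-dimension recovery uses d_max = 3 with 2 starts; corrections in
simulation studies use 39–99 nulls (the package default stays 199);
PERMDISP calibration uses 200 null datasets at 199 permutations. The
acceptance script analyses the full 7-taxon survey with d_max = 3, 2
starts and 99 nulls.

## Known limitations

* Term p-values are approximate (Wald-type with rounded-edf rank); they
  drive selection only. A small anti-conservative tendency remains at
  small n, which forward selection inherits — spurious terms enter in a
  minority of replicates, as the tests document.
* The ELBO stands in for the log-likelihood in AIC; dimension selection is
  consistent in simulations but the absolute AIC values are bounds, not
  likelihoods.
* The three-way MSR correction requires a complete pond × occasion panel;
  unbalanced surveys fall back to raw fractions (flagged).
* Relative fractions are undefined when the truncated total is zero; such
  rows are flagged rather than imputed.
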