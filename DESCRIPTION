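Package: pondvarpart
Title: Nonlinear Variation Partitioning for Metacommunities with
    Penalized-Spline GAMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes variation in metacommunity structure into
    environmental, spatial and temporal components using generalized
    additive models with penalized regression splines. Community
    presence-absence matrices are summarized by a binomial latent
    variable ordination whose AIC-selected site scores serve as the
    multivariate response; adjusted R-squared fractions are obtained by
    inclusion-exclusion over component models, with a Moran spectral
    randomization null correction for spatially (and temporally)
    structured environments. Includes a synthetic metacommunity
    generator, PERMDISP dispersion comparisons, exact paired Wilcoxon
    tests, and drivers for both a repeated snapshot ("spatial") analysis
    and a pooled spatio-temporal analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
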