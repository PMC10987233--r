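# shared fixture builders; everything is generated in code at test time

quiet_latent <- function(...) suppressWarnings(fit_latent_model(...))
quiet_select <- function(...) suppressWarnings(select_latent_dimension(...))

# binary community drawn straight from the latent model
sim_latent_community <- function(n, m, d, seed, loading_sd = 1,
                                 intercept_sd = 0.4) {
  set.seed(seed)
  Z <- matrix(rnorm(n * d), n, d)
  G <- matrix(rnorm(m * d, 0, loading_sd), m, d)
  eta <- sweep(Z %*% t(G), 2, rnorm(m, -0.3, intercept_sd), "+")
  list(Y = matrix(rbinom(n * m, 1, plogis(eta)), n, m), Z = Z, G = G)
}

# small covariate table for partition plumbing tests
small_predictors <- function(n, seed) {
  set.seed(seed)
  data.frame(PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n),
             x_km = runif(n, 0, 100), y_km = runif(n, 0, 100),
             days_since_first = rep(c(0, 150, 250), length.out = n))
}

default_E_terms <- function(k = 9, n_pcs = 3)
  lapply(paste0("PC", seq_len(n_pcs)), smooth_spec, k = k)

default_S_term <- function(k = 9) list(smooth_spec(c("x_km", "y_km"), k = k))

default_T_term <- function(k = 3)
  list(suppressWarnings(smooth_spec("days_since_first", k = k)))

# 2-way partition harness on one simulated metacommunity; `period` slices a
# single occasion (the snapshot design, one sample per pond), NULL pools all
partition_scenario <- function(cfg, d = 2, latent_seed = 1, period = NULL) {
  ds <- simulate_metacommunity(cfg)
  sf <- ds$sample_frame
  rows <- if (is.null(period)) seq_len(nrow(sf)) else which(sf$occasion == period)
  pca <- pca_reduce(transform_env(ds$env[rows, , drop = FALSE],
                                  ds$env_meta)$env)
  dat <- data.frame(pca$scores, x_km = sf$x_km[rows], y_km = sf$y_km[rows],
                    days_since_first = sf$days_since_first[rows])
  ax <- quiet_latent(ds$communities[[1]][rows, , drop = FALSE], d,
                     seed = latent_seed)
  list(ds = ds, dat = dat, axes = ax$site_scores, rows = rows)
}
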