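test_that("AIC identity and identifiability constraints hold", {
  sim <- sim_latent_community(40, 20, 2, seed = 1)
  f <- quiet_latent(sim$Y, 2, seed = 2)
  expect_equal(f$aic, -2 * f$log_likelihood + 2 * f$n_parameters)
  expect_equal(f$n_parameters, 20 + (20 * 2 - 1))
  # upper triangle of loadings fixed at zero, diagonal positive
  expect_equal(f$loadings[1, 2], 0)
  expect_true(all(diag(f$loadings[1:2, 1:2]) > 0))
  expect_equal(dim(f$site_scores), c(40L, 2L))
  expect_true(all(is.finite(f$site_scores)))
})

test_that("the variational bound ascends monotonically", {
  sim <- sim_latent_community(50, 25, 2, seed = 3)
  f <- quiet_latent(sim$Y, 2, seed = 1, n_starts = 1)
  expect_true(all(diff(f$elbo_trace) > -1e-8))
})

test_that("multi-start selection stabilizes the bound across seeds", {
  sim <- sim_latent_community(60, 30, 1, seed = 4, loading_sd = 1.5)
  f1 <- quiet_latent(sim$Y, 1, seed = 11)
  f2 <- quiet_latent(sim$Y, 1, seed = 99)
  expect_lt(abs(f1$log_likelihood - f2$log_likelihood), 1e-3)
})

test_that("structure in the data inflates loadings relative to noise", {
  set.seed(5)
  n <- 60; m <- 30
  Y_noise <- matrix(rbinom(n * m, 1, 0.5), n, m)
  Y_struct <- sim_latent_community(n, m, 1, seed = 6, loading_sd = 1.5)$Y
  f_noise <- quiet_latent(Y_noise, 1, seed = 1)
  f_struct <- quiet_latent(Y_struct, 1, seed = 1)
  expect_gt(mean(abs(f_struct$loadings)), mean(abs(f_noise$loadings)))
})

test_that("invariant species are dropped with a warning", {
  sim <- sim_latent_community(30, 10, 1, seed = 7)
  Y <- cbind(sim$Y, 0, 1)
  expect_warning(f <- fit_latent_model(Y, 1, seed = 1), "dropping 2")
  expect_equal(f$m, 10)
})

test_that("the optimum matches an independent maximization on a tiny model", {
  # 3 samples x 2 species, d = 1: maximize the same quadratic-bound
  # objective over all free parameters with a generic optimizer
  set.seed(8)
  Y <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2)
  f <- quiet_latent(Y, 1, seed = 1, n_starts = 5, max_iter = 2000, tol = 1e-12)
  bound_fun <- function(par) {
    beta0 <- par[1:2]; gam <- par[3:4]; m <- par[5:7]; ls <- par[8:10]
    s <- exp(ls)
    eta <- outer(m, gam) + matrix(beta0, 3, 2, byrow = TRUE)
    e2 <- eta^2 + outer(s, gam^2)
    xi <- sqrt(e2)
    lam <- ifelse(xi < 1e-8, 1 / 8, tanh(xi / 2) / (4 * xi))
    ll <- sum(log(plogis(xi)) + (Y - 0.5) * eta - xi / 2 + lam * (xi^2 - e2))
    kl <- 0.5 * sum(ls - s - m^2 + 1)
    ll + kl
  }
  best <- -Inf
  for (st in 1:40) {
    p0 <- rnorm(10, 0, 0.7)
    o <- optim(p0, bound_fun, control = list(fnscale = -1, maxit = 3000,
                                             reltol = 1e-14))
    o <- optim(o$par, bound_fun, method = "BFGS",
               control = list(fnscale = -1, maxit = 1000))
    best <- max(best, o$value)
  }
  expect_lt(abs(f$log_likelihood - best), 1e-3)
})

test_that("AIC selects the generating dimension often enough", {
  hits <- 0; d1_hits <- 0
  for (s in 1:5) {
    sim <- sim_latent_community(80, 40, 2, seed = 100 + s, loading_sd = 1.2)
    sel <- quiet_select(sim$Y, d_max = 3, seed = s, n_starts = 2)
    hits <- hits + (sel$d == 2)
    # structureless data prefers the smallest dimension
    set.seed(200 + s)
    Y0 <- matrix(rbinom(80 * 40, 1, 0.5), 80, 40)
    sel0 <- quiet_select(Y0, d_max = 2, seed = s, n_starts = 2)
    d1_hits <- d1_hits + (sel0$d == 1)
    expect_equal(sel$aic_table$aic[sel$d],
                 -2 * sel$fit$log_likelihood + 2 * sel$fit$n_parameters)
  }
  expect_gte(hits, 3)
  expect_gte(d1_hits, 4)
})

test_that("score sign flips do not change the partition downstream", {
  harn <- partition_scenario(sim_config(n_ponds = 15, n_species = 20,
                                        beta_E = 1.5, seed = 10), d = 2)
  E <- default_E_terms(); S <- default_S_term()
  vp1 <- partition_two(harn$axes, E, S, harn$dat)
  flipped <- harn$axes %*% diag(c(-1, 1))
  vp2 <- partition_two(flipped, E, S, harn$dat)
  expect_equal(vp1$fractions, vp2$fractions, tolerance = 1e-10)
})
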