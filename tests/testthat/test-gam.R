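test_that("spline basis honours its penalty null space and constraints", {
  set.seed(1)
  d <- data.frame(x = sort(runif(40)))
  b <- build_basis(d, smooth_spec("x", k = 9))
  # centered: column sums exactly absorbed
  expect_lt(max(abs(colSums(b$X))), 1e-10)
  # a straight line lies in the penalty null space: find constrained coefs
  # reproducing a centered linear function, check its penalty is ~ 0
  target <- d$x - mean(d$x)
  beta <- qr.solve(b$X, target)
  expect_lt(max(abs(b$X %*% beta - target)), 1e-8)
  expect_lt(drop(crossprod(beta, b$S %*% beta)), 1e-10)
  # 2D smooth: same properties with the plane in the null space
  d2 <- data.frame(x = runif(40, 0, 100), y = runif(40, 0, 100))
  b2 <- build_basis(d2, smooth_spec(c("x", "y"), k = 9))
  expect_lt(max(abs(colSums(b2$X))), 1e-8)
  plane <- 0.3 * (d2$x - mean(d2$x)) - 0.1 * (d2$y - mean(d2$y))
  beta2 <- qr.solve(b2$X, plane)
  expect_lt(max(abs(b2$X %*% beta2 - plane)), 1e-6)
  expect_lt(drop(crossprod(beta2, b2$S %*% beta2)), 1e-8)
})

test_that("cubic spline basis interpolates knot values like the textbook system", {
  # 5-point toy: coefficients in the values-at-knots parameterization must
  # reproduce those values exactly at the knots (natural spline cardinality)
  xk <- c(0, 0.3, 0.5, 0.8, 1)
  setup <- pondvarpart:::crs_setup(xk)
  X_at_knots <- pondvarpart:::crs_design(xk, setup)
  expect_equal(X_at_knots, diag(5), tolerance = 1e-10)
  # and between knots it matches the independent natural-spline interpolant
  vals <- c(0.2, -1, 0.5, 0.3, -0.4)
  xs <- seq(0, 1, by = 0.01)
  ours <- drop(pondvarpart:::crs_design(xs, setup) %*% vals)
  oracle <- stats::spline(xk, vals, xout = xs, method = "natural")$y
  expect_equal(ours, oracle, tolerance = 1e-8)
})

test_that("a linear signal collapses to one effective degree of freedom", {
  set.seed(2)
  d <- data.frame(x = runif(50))
  d$y <- 2 * d$x + rnorm(50, 0, 1e-6)
  f <- pgam(y ~ s(x), d)
  expect_gte(f$r2_adj, 0.999)
  expect_lt(f$edf[[1]], 1.5)
  expect_lte(f$r2_adj, f$r2)
})

test_that("adjusted R2 is approximately unbiased at zero for pure noise", {
  r2s <- vapply(1:50, function(s) {
    set.seed(s)
    d <- data.frame(x = runif(100), y = rnorm(100))
    pgam(y ~ s(x), d)$r2_adj
  }, 0)
  expect_lt(abs(mean(r2s)), 0.05)
})

test_that("fixed-lambda coefficients equal the direct penalized solve", {
  set.seed(3)
  d <- data.frame(x = runif(12))
  d$y <- sin(3 * d$x) + rnorm(12, 0, 0.1)
  f <- pgam(y ~ s(x, k = 6), d, lambda = 1)
  b <- build_basis(d, smooth_spec("x", k = 6))
  X <- cbind(1, b$X)
  S <- matrix(0, ncol(X), ncol(X))
  S[-1, -1] <- b$S
  beta_oracle <- solve(crossprod(X) + 1 * S, crossprod(X, d$y))
  expect_equal(unname(f$coefficients), drop(beta_oracle), tolerance = 1e-8)
  # fitted values reproduce from coefficients and basis
  expect_lt(max(abs(X %*% beta_oracle - f$fitted)), 1e-8)
})

test_that("unadjusted R2 never decreases when adding a term", {
  set.seed(4)
  d <- data.frame(a = runif(60), b = runif(60))
  d$y <- sin(2 * pi * d$a) + rnorm(60, 0, 0.3)
  # fix lambda so the comparison is a nested least-squares fact
  f1 <- pgam_fit(d$y, list(smooth_spec("a")), d, lambda = 1)
  f2 <- pgam_fit(d$y, list(smooth_spec("a"), smooth_spec("b")), d, lambda = 1)
  expect_gte(f2$r2 + 1e-12, f1$r2)
})

test_that("huge smoothing reproduces the OLS fit on the null space", {
  set.seed(5)
  d <- data.frame(x = runif(30))
  d$y <- 1 + 2 * d$x + rnorm(30, 0, 0.2)
  f_inf <- pgam(y ~ s(x), d, lambda = 1e6)
  ols <- lm(y ~ x, d)
  expect_lt(max(abs(fitted(f_inf) - fitted(ols))), 1e-6)
  # exact null-space substitution gives the OLS fit to machine precision
  f_lin <- pgam(y ~ s(x), d, linear = TRUE)
  expect_equal(unname(fitted(f_lin)), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("sample order does not affect the fit", {
  set.seed(6)
  d <- data.frame(x = runif(40))
  d$y <- cos(4 * d$x) + rnorm(40, 0, 0.2)
  f1 <- pgam(y ~ s(x), d)
  perm <- sample(40)
  f2 <- pgam(y ~ s(x), d[perm, ])
  expect_equal(f1$r2_adj, f2$r2_adj, tolerance = 1e-10)
})

test_that("the fit agrees closely with an independent GAM implementation", {
  skip_if_not_installed("mgcv")
  set.seed(7)
  d <- data.frame(x = runif(80), z = runif(80))
  d$y <- sin(2 * pi * d$x) + rnorm(80, 0, 0.2)
  ours <- pgam(y ~ s(x) + s(z), d)
  ref <- mgcv::gam(y ~ s(x, bs = "cr", k = 9) + s(z, bs = "cr", k = 9),
                   data = d, method = "GCV.Cp")
  expect_lt(abs(ours$r2_adj - summary(ref)$r.sq), 0.02)
  expect_gt(cor(fitted(ours), fitted(ref)), 0.999)
})

test_that("prediction reproduces training fits and extends to new data", {
  set.seed(8)
  d <- data.frame(x = runif(50, 0, 100), y2 = runif(50, 0, 100))
  d$r <- sin(d$x / 30) + cos(d$y2 / 25) + rnorm(50, 0, 0.2)
  f <- pgam(r ~ s(x, y2), d)
  expect_lt(max(abs(predict(f, d) - fitted(f))), 1e-10)
  tm <- predict(f, d, type = "terms")
  expect_equal(drop(coef(f)[1] + rowSums(tm)), unname(fitted(f)),
               tolerance = 1e-10)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(50L, 3L))
})

test_that("forward selection finds the true predictor and obeys its caps", {
  only_A <- 0
  for (s in 1:10) {
    set.seed(s)
    d <- data.frame(A = runif(60), B = runif(60), C = runif(60))
    d$y <- sin(2 * pi * d$A) + rnorm(60, 0, 0.15)
    cands <- lapply(c("A", "B", "C"), smooth_spec)
    fs <- forward_select(d$y, cands, d)
    sel <- vapply(fs$selected, function(sp) sp$vars, "")
    expect_identical(sel[1], "A")   # the real signal always enters first
    only_A <- only_A + identical(sel, "A")
  }
  # spurious additions stay in the minority across seeds
  expect_gte(only_A, 6)
  set.seed(9)
  d <- data.frame(A = runif(60), B = runif(60), C = runif(60))
  d$y <- sin(2 * pi * d$A) + rnorm(60, 0, 0.15)
  cands <- lapply(c("A", "B", "C"), smooth_spec)
  # alpha = 0 can select nothing (no p-value is below zero)
  fs0 <- forward_select(d$y, cands, d, alpha = 0)
  expect_length(fs0$selected, 0)
  # cap of one term with two real predictors
  d$y2 <- sin(2 * pi * d$A) + cos(2 * pi * d$B) + rnorm(60, 0, 0.15)
  fs1 <- forward_select(d$y2, cands, d, max_terms = 1)
  expect_length(fs1$selected, 1)
})

test_that("degenerate inputs are rejected with clear messages", {
  d <- data.frame(x = rep(1, 10), y = rnorm(10))
  expect_error(pgam(y ~ s(x), d), "constant")
  expect_error(pgam(y ~ s(q), data.frame(y = rnorm(5), x = 1:5)),
               "not found")
  # too few distinct values triggers the k reduction warning
  d2 <- data.frame(x = rep(c(0, 150, 250), 10))
  d2$y <- d2$x / 100 + rnorm(30, 0, 0.1)
  expect_warning(f <- pgam(y ~ s(x, k = 9), d2), "distinct")
  expect_lte(f$edf[[1]], 2 + 1e-8)
})
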