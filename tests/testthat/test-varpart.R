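test_that("identical component sets put everything in the common fraction", {
  set.seed(1)
  dat <- small_predictors(30, seed = 1)
  y <- matrix(rnorm(30), ncol = 1)
  E <- list(smooth_spec("PC1"), smooth_spec("PC2"))
  vp <- partition_two(y, E, E, dat, lambda = 1)
  expect_lt(abs(vp$fractions[["pure_E"]]), 1e-10)
  expect_lt(abs(vp$fractions[["pure_S"]]), 1e-10)
  expect_equal(vp$fractions[["common"]], vp$total, tolerance = 1e-10)
})

test_that("fractions recompute from stored component R2 by inclusion-exclusion", {
  set.seed(2)
  dat <- small_predictors(40, seed = 2)
  y <- matrix(sin(dat$PC1) + 0.01 * dat$x_km + rnorm(40, 0, 0.3), ncol = 1)
  vp <- partition_two(y, default_E_terms(k = 5), default_S_term(k = 5), dat)
  a <- vp$R2[["E"]]; b <- vp$R2[["S"]]; ab <- vp$R2[["ES"]]
  expect_equal(vp$fractions[["pure_E"]], ab - b)
  expect_equal(vp$fractions[["pure_S"]], ab - a)
  expect_equal(vp$fractions[["common"]], a + b - ab)
  expect_equal(sum(vp$fractions), vp$total, tolerance = 1e-10)
})

test_that("a temporal term duplicating a spatial one moves mass to their overlap", {
  set.seed(3)
  dat <- small_predictors(36, seed = 3)
  dat$days_since_first <- dat$x_km      # T identical to a predictor in S
  y <- matrix(0.02 * dat$x_km + sin(dat$PC1) + rnorm(36, 0, 0.2), ncol = 1)
  E <- list(smooth_spec("PC1", k = 5))
  S <- list(smooth_spec("x_km", k = 5))
  Tt <- list(smooth_spec("days_since_first", k = 5))
  vp <- partition_three(y, E, S, Tt, dat, lambda = 1)
  expect_lt(abs(vp$fractions[["pure_T"]]), 1e-10)
  expect_equal(sum(vp$fractions), vp$total, tolerance = 1e-10)
  expect_gt(vp$fractions[["ST_given_E"]], 0.01)
})

test_that("the linear limit reproduces classical variation partitioning", {
  set.seed(8)
  n <- 20
  dat <- small_predictors(n, seed = 8)
  y <- 0.5 * dat$PC1 - 0.3 * dat$PC2 + 0.02 * dat$x_km + rnorm(n, 0, 0.5)
  E <- list(smooth_spec("PC1"), smooth_spec("PC2"))
  S <- list(smooth_spec(c("x_km", "y_km")))
  vp <- partition_two(matrix(y, ncol = 1), E, S, dat, linear = TRUE)
  vv <- vegan::varpart(y, dat[, c("PC1", "PC2")], dat[, c("x_km", "y_km")])
  ind <- vv$part$indfract$Adj.R.square   # rows: [a]=E|S, [b]=S|E, [c]=shared
  expect_equal(vp$fractions[["pure_E"]], ind[1], tolerance = 1e-8)
  expect_equal(vp$fractions[["pure_S"]], ind[2], tolerance = 1e-8)
  expect_equal(vp$fractions[["common"]], ind[3], tolerance = 1e-8)
})

test_that("relative fractions truncate negatives and renormalize", {
  vp <- structure(list(total = 0.4,
                       fractions = c(pure_E = 0.2, pure_S = 0.1,
                                     common = 0.1),
                       corrected = NULL, n_axes = 1, degenerate = FALSE),
                  class = "varpart2")
  out <- relative_fractions(vp)
  expect_equal(unname(out$relative), c(0.5, 0.25, 0.25))
  vp$fractions <- c(pure_E = 0.25, pure_S = -0.03, common = 0.05)
  out2 <- relative_fractions(vp)
  expect_equal(unname(out2$truncated), c(0.25, 0, 0.05))
  expect_equal(unname(out2$relative), c(0.25, 0, 0.05) / 0.3)
  # single nonzero fraction takes the whole relative share
  vp$fractions <- c(pure_E = 0.3, pure_S = 0, common = 0)
  expect_equal(unname(relative_fractions(vp)$relative)[1], 1)
  # nothing explained: relative view flagged undefined
  vp$fractions <- c(pure_E = -0.02, pure_S = -0.01, common = 0)
  out3 <- relative_fractions(vp)
  expect_false(out3$relative_defined)
})

test_that("an environment-driven response leaves no mass in pure space", {
  pure_S <- vapply(1:8, function(s) {
    harn <- partition_scenario(sim_config(
      n_ponds = 30, n_species = 40, beta_E = 2, beta_S = 0, beta_T = 0,
      env_spatial_weight = 0, seed = 400 + s), d = 1, period = 1)
    partition_two(harn$axes, default_E_terms(), default_S_term(),
                  harn$dat)$fractions[["pure_S"]]
  }, 0)
  expect_lt(abs(mean(pure_S)), 0.05)
})

test_that("corrections vanish when the environment has no spatial structure", {
  deltas <- vapply(1:5, function(s) {
    harn <- partition_scenario(sim_config(
      n_ponds = 30, n_species = 40, beta_E = 2, beta_S = 0, beta_T = 0,
      env_spatial_weight = 0, seed = 500 + s), d = 1, period = 1)
    vp <- partition_two(harn$axes, default_E_terms(), default_S_term(),
                        harn$dat, correction = TRUE, n_null = 39, seed = s,
                        coords = cbind(harn$dat$x_km, harn$dat$y_km))
    max(abs(vp$corrected$null_mean))
  }, 0)
  expect_lt(mean(deltas), 0.05)
})

test_that("a purely temporal process puts the dominant mass in pure time", {
  hits <- 0
  for (s in 1:10) {
    harn <- partition_scenario(sim_config(
      n_ponds = 20, n_species = 40, beta_E = 0, beta_S = 0, beta_T = 2,
      occasion_shift_sd = 0, seed = 600 + s), d = 1)
    vp <- suppressWarnings(partition_three(
      harn$axes, default_E_terms(), default_S_term(), default_T_term(),
      harn$dat))
    hits <- hits + (names(which.max(vp$fractions)) == "pure_T")
  }
  expect_gte(hits, 8)
})

test_that("too few ponds leaves the partition uncorrected but flagged", {
  set.seed(9)
  dat <- data.frame(PC1 = rnorm(9),
                    x_km = rep(c(0, 10, 20), each = 3),
                    y_km = rep(c(0, 5, 9), each = 3))
  y <- matrix(rnorm(9), ncol = 1)
  vp <- partition_two(y, list(smooth_spec("PC1", k = 4)), list(), dat,
                      lambda = 1, correction = TRUE,
                      coords = cbind(dat$x_km, dat$y_km))
  expect_null(vp$corrected)
  expect_match(vp$correction_note, "fewer than 4")
})
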