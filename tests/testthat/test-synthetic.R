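test_that("simulation is reproducible and validates its configuration", {
  expect_identical(simulate_metacommunity(sim_config(seed = 7)),
                   simulate_metacommunity(sim_config(seed = 7)))
  expect_error(sim_config(occasion_days = c(10, 150, 250)), "start at 0")
  expect_error(sim_config(occasion_days = c(0, 250, 150)), "increasing")
  expect_error(sim_config(beta_E = -1), "non-negative")
})

test_that("intercept-only occupancy sits near one half", {
  ds <- simulate_metacommunity(sim_config(beta_E = 0, beta_S = 0, beta_T = 0,
                                          intercept_mean = 0,
                                          intercept_sd = 0, seed = 2))
  Y <- ds$communities[[1]]
  expect_true(all(Y %in% 0:1))
  expect_equal(nrow(Y), 90)
  # binomial error at n = 90 x 60 draws
  expect_lt(abs(mean(Y) - 0.5), 0.02)
})

test_that("strong environmental effects are recoverable per species", {
  ds <- simulate_metacommunity(sim_config(beta_E = 3, beta_S = 0, beta_T = 0,
                                          seed = 3))
  Y <- ds$communities[[1]]; f <- ds$truth$f_mat
  slopes <- vapply(seq_len(ncol(Y)), function(s)
    coef(glm(Y[, s] ~ f[, s], family = binomial))[2], 0)
  expect_gte(mean(slopes > 0), 0.95)
})

test_that("climatic variables are constant within ponds, limnological vary", {
  ds <- simulate_metacommunity(sim_config(seed = 11))
  env <- as.matrix(ds$env); sf <- ds$sample_frame
  wv <- vapply(colnames(env), function(v)
    max(tapply(env[, v], sf$pond_id, var)), 0)
  cls <- ds$env_meta$class
  expect_true(all(wv[cls == "climatic"] == 0))
  expect_true(all(wv[cls == "limnological"] > 0))
  # zero occasion shift makes limnological constant too
  ds0 <- simulate_metacommunity(sim_config(occasion_shift_sd = 0, seed = 11))
  env0 <- as.matrix(ds0$env)
  wv0 <- vapply(colnames(env0), function(v)
    max(tapply(env0[, v], ds0$sample_frame$pond_id, var)), 0)
  expect_true(all(wv0 < 1e-20))
})

test_that("stronger environmental forcing raises occupancy-environment coupling", {
  mean_abs_cor <- function(beta_E, seed) {
    ds <- simulate_metacommunity(sim_config(
      n_ponds = 20, n_species = 30, beta_E = beta_E, beta_S = 0, beta_T = 0,
      seed = seed))
    Y <- ds$communities[[1]]; f <- ds$truth$f_mat
    mean(abs(vapply(seq_len(ncol(Y)), function(s)
      suppressWarnings(cor(Y[, s], f[, s])), 0)), na.rm = TRUE)
  }
  lo <- vapply(1:10, function(s) mean_abs_cor(0.2, s), 0)
  hi <- vapply(1:10, function(s) mean_abs_cor(2.0, s), 0)
  expect_gt(mean(hi), mean(lo))
})

test_that("datasets round-trip through the CSV layout", {
  ds <- simulate_taxa(sim_config(n_ponds = 6, n_species = 8, seed = 5),
                      n_taxa = 2)
  td <- withr::local_tempdir()
  files <- write_dataset(ds, td)
  expect_true(any(grepl("community_bacteria.csv", files)))
  back <- read_dataset(td)
  expect_equal(back$communities$bacteria,
               matrix(as.integer(ds$communities$bacteria),
                      nrow(ds$communities$bacteria),
                      dimnames = dimnames(ds$communities$bacteria)))
  expect_equal(as.matrix(back$env), as.matrix(ds$env), tolerance = 1e-12)
  expect_equal(back$env_meta$class, ds$env_meta$class)
  # community CSV format contract: sample_id column plus species headers
  comm <- utils::read.csv(file.path(td, "community_bacteria.csv"))
  expect_identical(names(comm)[1], "sample_id")
  expect_identical(names(comm)[-1], colnames(ds$communities$bacteria))
})

test_that("a 2-pond, 1-occasion dataset has exactly 2 data rows", {
  ds <- simulate_metacommunity(sim_config(n_ponds = 2, n_occasions = 1,
                                          occasion_days = 0, n_species = 2,
                                          seed = 1))
  expect_equal(nrow(ds$sample_frame), 2)
  td <- withr::local_tempdir()
  write_dataset(ds, td)
  comm <- utils::read.csv(file.path(td, "community_taxon1.csv"))
  expect_equal(nrow(comm), 2)
})

test_that("taxa drawn over one network share the pond layout", {
  ds <- simulate_taxa(sim_config(n_ponds = 8, n_species = 10, seed = 3),
                      n_taxa = 3)
  expect_length(ds$communities, 3)
  expect_false(identical(ds$communities[[1]], ds$communities[[2]]))
  expect_equal(nrow(ds$communities[[3]]), nrow(ds$sample_frame))
})
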