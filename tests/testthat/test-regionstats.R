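test_that("one-signed differences reach the extreme V and its exact p", {
  w_neg <- wilcoxon_paired_exact(1:7, (1:7) + 2)
  expect_equal(w_neg$V, 0)
  expect_equal(w_neg$p, 2 / 2^7)
  w_pos <- wilcoxon_paired_exact((1:7) + 2, 1:7)
  expect_equal(w_pos$V, 7 * 8 / 2)
  expect_equal(w_pos$p, 2 / 2^7)
  expect_equal(round(w_pos$p, 3), 0.016)
})

test_that("symmetric two-pair case and degenerate inputs behave", {
  w <- wilcoxon_paired_exact(c(1, 2), c(0, 3))  # +1, -1: tied magnitudes
  expect_equal(w$p, 1)
  expect_error(suppressWarnings(wilcoxon_paired_exact(1:3, 1:3)),
               "no informative pairs")
  expect_warning(w2 <- wilcoxon_paired_exact(c(1, 1, 5), c(1, 0, 1)),
                 "zero difference")
  expect_equal(w2$n, 2)
})

test_that("the convolution agrees with literal sign enumeration", {
  brute_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- signs %*% r
    min(1, 2 * min(mean(Vs <= V), mean(Vs >= V)))
  }
  set.seed(1)
  for (rep in 1:6) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n), 1)             # rounding induces occasional ties
    d <- d[d != 0]
    if (length(d) < 2) next
    ours <- wilcoxon_paired_exact(d, rep(0, length(d)))
    expect_equal(ours$p, brute_p(d), tolerance = 1e-12)
  }
  # near the normal approximation for n = 10 without ties
  set.seed(2)
  d <- rnorm(10)
  ours <- wilcoxon_paired_exact(d, rep(0, 10))
  appr <- wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(ours$p - appr), 0.02)
})

test_that("PERMDISP detects inflated dispersion and not identical groups", {
  set.seed(6)
  A <- matrix(rnorm(150), 30, 5)
  B <- A * 3
  p1 <- permdisp(rbind(A, B), rep(c("a", "b"), each = 30), n_perm = 999,
                 seed = 1)
  expect_lte(p1$p, 0.01)
  p0 <- permdisp(rbind(A, A), rep(c("a", "b"), each = 30), n_perm = 99,
                 seed = 1)
  expect_equal(p0$F, 0)
  # reproducible under the seed, resolution 1/(n_perm + 1)
  p1b <- permdisp(rbind(A, B), rep(c("a", "b"), each = 30), n_perm = 999,
                  seed = 1)
  expect_identical(p1$p, p1b$p)
  expect_equal(p1$p * (p1$n_perm + 1), round(p1$p * (p1$n_perm + 1)))
  expect_error(permdisp(A, rep("a", 30)), "2 groups")
})

test_that("PERMDISP is insensitive to sample ordering", {
  set.seed(7)
  X <- matrix(rnorm(200), 40, 5)
  g <- rep(c("a", "b"), each = 20)
  p1 <- permdisp(X, g, n_perm = 199, seed = 3)
  perm <- sample(40)
  p2 <- permdisp(X[perm, ], g[perm], n_perm = 199, seed = 3)
  expect_equal(p1$F, p2$F, tolerance = 1e-10)
})

test_that("approach comparison renormalizes and runs the paired tests", {
  taxa <- letters[1:7]
  spatial <- do.call(rbind, lapply(1:3, function(per)
    data.frame(taxon = taxa, period = per,
               pure_E = 0.5 + 0.01 * seq_len(7), pure_S = 0.3,
               common = 0.2 - 0.01 * seq_len(7))))
  # spatio-temporal shifts mass from pure_E to pure_S for every taxon
  st <- data.frame(taxon = taxa, pure_E = 0.2, pure_S = 0.55 + 0.01 * 1:7,
                   ES_given_T = 0.25 - 0.01 * 1:7)
  cmp <- compare_approaches(spatial, st)
  tests <- cmp$tests
  expect_equal(tests$n[tests$fraction == "pure_S"], 7)
  expect_equal(tests$V[tests$fraction == "pure_S"], 0)   # spatial < pooled
  expect_equal(tests$p[tests$fraction == "pure_S"], 2 / 2^7)
  expect_equal(tests$V[tests$fraction == "pure_E"], 28)
  # identical inputs: no informative pairs, reported as NA
  st_same <- data.frame(taxon = taxa,
                        pure_E = 0.5 + 0.01 * seq_len(7) ,
                        pure_S = rep(0.3, 7),
                        ES_given_T = 0.2 - 0.01 * seq_len(7))
  # renormalize to make pooled fractions equal the spatial ones exactly
  cmp2 <- compare_approaches(spatial, st_same)
  expect_true(all(is.na(cmp2$tests$p)))
  # mismatched taxa fail loudly
  expect_error(compare_approaches(spatial,
                                  st[st$taxon != "a", , drop = FALSE]),
               "mismatch")
})

test_that("comparison results round-trip through CSV", {
  tests <- data.frame(fraction = c("pure_E", "pure_S"), V = c(28, 0),
                      p = c(0.015625, 0.015625), n = c(7L, 7L))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tests, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$V, tests$V)
  expect_equal(back$p, tests$p)
  expect_equal(back$n, tests$n)
})
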