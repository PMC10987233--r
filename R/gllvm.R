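#' Fit a binomial latent variable ordination (no predictors)
#'
#' Model: \eqn{P(y_{ij} = 1) = \mathrm{logit}^{-1}(\beta_{0j} + z_i^\top
#' \gamma_j)} with latent site scores \eqn{z_i \sim N(0, I_d)}. The model is
#' fit by a variational Gaussian approximation: each \eqn{q(z_i)} is a
#' Gaussian whose mean and covariance are updated in closed form under the
#' quadratic (Jaakkola-Jordan) lower bound to the Bernoulli-logit
#' likelihood. Coordinate ascent alternates (a) the bound's variational
#' tightening parameters, (b) the per-sample Gaussians, and (c) the species
#' intercepts and loadings; every step maximizes the same objective, so the
#' evidence lower bound (ELBO) increases monotonically. Multiple seeded
#' starts are run and the best bound kept.
#'
#' Identifiability: loadings are constrained upper-triangular-zero
#' (\eqn{\gamma_{jk} = 0} for k > j) with a positive diagonal (sign flips
#' applied after convergence).
#'
#' @param Y binary matrix (samples x species). Species present everywhere or
#'   absent everywhere are dropped with a warning.
#' @param d number of latent axes (>= 1).
#' @param seed integer seed controlling the random starts.
#' @param n_starts number of random initializations (default 3).
#' @param max_iter maximum coordinate-ascent iterations per start.
#' @param tol relative ELBO convergence tolerance.
#' @return object of class `gllvm_pa` with `site_scores` (variational means,
#'   n x d), `loadings` (species x d), `intercepts`, `log_likelihood` (the
#'   ELBO surrogate), `aic`, `n_parameters`, `converged`, `elbo_trace` (of
#'   the best start), `d`.
#' @export
fit_latent_model <- function(Y, d, seed = 1, n_starts = 3, max_iter = 400,
                             tol = 1e-6) {
  Y <- as.matrix(Y)
  if (!all(Y %in% c(0, 1))) stop("community matrix must be binary 0/1")
  stopifnot(d >= 1)
  keep <- colSums(Y) > 0 & colSums(Y) < nrow(Y)
  if (!all(keep)) {
    warning(sprintf("dropping %d species with no presence/absence variation",
                    sum(!keep)))
    Y <- Y[, keep, drop = FALSE]
  }
  n <- nrow(Y); m <- ncol(Y)
  if (m < d) stop("need at least d species after dropping invariant ones")

  set.seed(seed)
  start_seeds <- sample.int(2^30, n_starts)
  best <- NULL
  for (st in seq_len(n_starts)) {
    set.seed(start_seeds[st])
    fit <- jj_va_fit(Y, d, max_iter, tol)
    if (is.null(best) || fit$elbo > best$elbo) best <- fit
  }

  ## sign convention: positive loading diagonal
  for (k in seq_len(d)) {
    if (best$Gamma[k, k] < 0) {
      best$Gamma[, k] <- -best$Gamma[, k]
      best$M[, k] <- -best$M[, k]
    }
  }
  n_par <- m + (m * d - d * (d - 1) / 2)
  aic <- -2 * best$elbo + 2 * n_par
  structure(list(d = d, site_scores = best$M, loadings = best$Gamma,
                 intercepts = best$beta0, log_likelihood = best$elbo,
                 aic = aic, n_parameters = n_par,
                 converged = best$converged, elbo_trace = best$trace,
                 n = n, m = m),
            class = "gllvm_pa")
}

## one variational fit from the current RNG state; all per-sample d x d
## quantities are held in symmetric-pair storage (n x d(d+1)/2 matrices) so
## the updates vectorize over samples and species
jj_va_fit <- function(Y, d, max_iter, tol) {
  n <- nrow(Y); m <- ncol(Y)
  pbar <- pmin(pmax(colMeans(Y), 1 / (2 * n)), 1 - 1 / (2 * n))
  beta0 <- stats::qlogis(pbar)
  Gamma <- matrix(stats::rnorm(m * d, 0, 0.3), m, d)
  Gamma[upper.tri(Gamma)] <- 0
  M <- matrix(stats::rnorm(n * d, 0, 0.3), n, d)
  Yc <- Y - 0.5

  pk <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  pk <- pk[order(pk[, 2], pk[, 1]), , drop = FALSE]  # (row k, col l), k <= l
  np <- nrow(pk)
  offdiag <- pk[, 1] != pk[, 2]
  Ivec <- as.numeric(pk[, 1] == pk[, 2])
  diag_cols <- which(!offdiag)

  ## symmetric batched inverse of P (rows of Pvec) -> Svec, with log-dets
  inv_batch <- function(Pvec) {
    if (d == 1) {
      list(S = 1 / Pvec, logdet = -log(Pvec))
    } else if (d == 2) {
      det <- Pvec[, 1] * Pvec[, 3] - Pvec[, 2]^2
      list(S = cbind(Pvec[, 3], -Pvec[, 2], Pvec[, 1]) / det,
           logdet = -log(det))
    } else {
      S <- matrix(0, nrow(Pvec), np); ld <- numeric(nrow(Pvec))
      for (i in seq_len(nrow(Pvec))) {
        P <- matrix(0, d, d)
        P[pk] <- Pvec[i, ]; P[pk[, c(2, 1)]] <- Pvec[i, ]
        R <- chol(P)
        S[i, ] <- chol2inv(R)[pk]
        ld[i] <- -2 * sum(log(diag(R)))
      }
      list(S = S, logdet = ld)
    }
  }
  ## batched y = S x for symmetric S in pair storage
  smul_batch <- function(Svec, X) {
    out <- matrix(0, nrow(X), d)
    for (k in seq_len(d)) {
      acc <- 0
      for (l in seq_len(d)) {
        p <- which((pk[, 1] == min(k, l)) & (pk[, 2] == max(k, l)))
        acc <- acc + Svec[, p] * X[, l]
      }
      out[, k] <- acc
    }
    out
  }
  gpair <- function(G) {  # m x np products G[,k] * G[,l]
    G[, pk[, 1], drop = FALSE] * G[, pk[, 2], drop = FALSE]
  }

  lam_fun <- function(xi) ifelse(xi < 1e-6, 1 / 8, tanh(xi / 2) / (4 * xi))

  Svec <- matrix(rep(Ivec, each = n), n, np)
  quad_fun <- function() {
    Gp <- gpair(Gamma)
    Gp[, offdiag] <- 2 * Gp[, offdiag]
    Svec %*% t(Gp)
  }
  Eeta <- sweep(M %*% t(Gamma), 2, beta0, "+")
  E2 <- Eeta^2 + quad_fun()
  xi <- sqrt(pmax(E2, 1e-12))
  lam <- lam_fun(xi)

  elbo_val <- function(logdet) {
    ll <- sum(log(stats::plogis(xi)) + Yc * Eeta - xi / 2 + lam * (xi^2 - E2))
    trS <- rowSums(Svec[, diag_cols, drop = FALSE])
    ll + 0.5 * sum(logdet - trS - rowSums(M^2) + d)
  }

  trace <- numeric(0)
  elbo_old <- -Inf
  converged <- FALSE
  free_k <- pmin(seq_len(m), d)   # species j loads on axes 1..min(j, d)
  logdet <- rep(0, n)

  for (it in seq_len(max_iter)) {
    ## (b) per-sample Gaussians: precision I + 2 sum_j lam_ij g_j g_j'
    Pvec <- sweep((2 * lam) %*% gpair(Gamma), 2, Ivec, "+")
    ib <- inv_batch(Pvec)
    Svec <- ib$S; logdet <- ib$logdet
    Bmat <- (Yc - 2 * lam * matrix(beta0, n, m, byrow = TRUE)) %*% Gamma
    M <- smul_batch(Svec, Bmat)

    ## (c) species intercepts and loadings (upper-triangle constraint)
    EM <- cbind(1, M)
    EMp_idx <- which(upper.tri(diag(d + 1), diag = TRUE), arr.ind = TRUE)
    EMp <- EM[, EMp_idx[, 1], drop = FALSE] * EM[, EMp_idx[, 2], drop = FALSE]
    crossA <- crossprod(EMp, 2 * lam)           # pairs x m
    Ssum <- crossprod(Svec, 2 * lam)            # latent pairs x m
    bAll <- crossprod(EM, Yc)                   # (d+1) x m
    for (j in seq_len(m)) {
      kj <- free_k[j]
      A <- matrix(0, d + 1, d + 1)
      A[EMp_idx] <- crossA[, j]; A[EMp_idx[, c(2, 1)]] <- crossA[, j]
      Sj <- matrix(0, d, d)
      Sj[pk] <- Ssum[, j]; Sj[pk[, c(2, 1)]] <- Ssum[, j]
      A[-1, -1] <- A[-1, -1] + Sj
      idx <- c(1, 1 + seq_len(kj))
      theta <- solve(A[idx, idx] + diag(1e-10, kj + 1), bAll[idx, j])
      beta0[j] <- theta[1]
      Gamma[j, ] <- 0
      Gamma[j, seq_len(kj)] <- theta[-1]
    }

    ## (a) tightening parameters and bound
    Eeta <- sweep(M %*% t(Gamma), 2, beta0, "+")
    E2 <- Eeta^2 + quad_fun()
    xi <- sqrt(pmax(E2, 1e-12))
    lam <- lam_fun(xi)
    elbo <- elbo_val(logdet)
    trace <- c(trace, elbo)
    if (is.finite(elbo_old) && abs(elbo - elbo_old) < tol * (abs(elbo) + 1)) {
      converged <- TRUE
      break
    }
    elbo_old <- elbo
  }
  if (!converged)
    warning("variational fit did not converge; best iterate returned")
  list(beta0 = beta0, Gamma = Gamma, M = M, Svec = Svec,
       elbo = trace[length(trace)], trace = trace, converged = converged)
}

#' @export
print.gllvm_pa <- function(x, ...) {
  cat(sprintf("Binomial latent variable ordination: %d samples, %d species, d = %d\n",
              x$n, x$m, x$d))
  cat(sprintf("  ELBO = %.3f  AIC = %.2f (%d parameters)  converged: %s\n",
              x$log_likelihood, x$aic, x$n_parameters, x$converged))
  invisible(x)
}

#' @export
logLik.gllvm_pa <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_parameters, class = "logLik")
}

#' Select the number of latent axes by AIC
#'
#' Fits the ordination for d = 1..`d_max` and keeps the dimension with the
#' lowest AIC (`-2 * ELBO + 2 * n_parameters`, with parameters counted as
#' the m intercepts plus the m*d - d(d-1)/2 free loadings).
#'
#' @inheritParams fit_latent_model
#' @param d_max largest candidate dimension (default 5).
#' @param taxon optional label carried into the result.
#' @return object of class `latent_axes`: list with `scores` (n x d matrix of
#'   variational site scores), `d`, `taxon`, `aic_table` (candidate d, aic,
#'   converged), `fit` (the winning `gllvm_pa`).
#' @export
select_latent_dimension <- function(Y, d_max = 5, seed = 1, n_starts = 3,
                                    taxon = NULL, max_iter = 500) {
  stopifnot(d_max >= 1)
  fits <- vector("list", d_max)
  for (d in seq_len(d_max)) {
    fits[[d]] <- withCallingHandlers(
      fit_latent_model(Y, d, seed = seed + d, n_starts = n_starts,
                       max_iter = max_iter),
      warning = function(w) {
        if (grepl("did not converge", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  conv <- vapply(fits, function(f) f$converged, TRUE)
  if (!any(conv)) stop("no latent dimension converged")
  aics <- vapply(fits, function(f) f$aic, 0)
  d_sel <- which.min(aics)
  best <- fits[[d_sel]]
  structure(list(scores = best$site_scores, d = d_sel, taxon = taxon,
                 aic_table = data.frame(d = seq_len(d_max),
                                        aic = vapply(fits, function(f) f$aic, 0),
                                        converged = conv),
                 fit = best),
            class = "latent_axes")
}

#' @export
print.latent_axes <- function(x, ...) {
  cat(sprintf("Latent axes%s: d = %d (AIC-selected), %d samples\n",
              if (!is.null(x$taxon)) paste0(" [", x$taxon, "]") else "",
              x$d, nrow(x$scores)))
  print(x$aic_table, row.names = FALSE)
  invisible(x)
}

## coerce either a latent_axes object or a bare matrix to a score matrix
axes_scores <- function(axes) {
  if (inherits(axes, "latent_axes")) axes$scores
  else as.matrix(axes)
}
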