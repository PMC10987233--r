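#' Specify a smooth term
#'
#' Describes one penalized smooth: a cubic regression spline for a single
#' covariate, or a thin-plate style radial smooth for a covariate pair
#' (typically longitude/latitude in planar km). The basis dimension `k`
#' bounds the term's flexibility: after the sum-to-zero centering constraint
#' a term contributes at most `k - 1` effective degrees of freedom.
#'
#' @param vars character vector of 1 or 2 covariate names.
#' @param k basis dimension (default 9).
#' @param type `"cr"` (cubic regression spline, 1 covariate) or `"tp"`
#'   (thin-plate radial smooth, 2 covariates); chosen from the number of
#'   covariates when `NULL`.
#' @return an object of class `smooth_spec`.
#' @export
smooth_spec <- function(vars, k = 9, type = NULL) {
  stopifnot(is.character(vars), length(vars) %in% 1:2, k >= 3)
  if (is.null(type)) type <- if (length(vars) == 1) "cr" else "tp"
  if (type == "cr" && length(vars) != 1)
    stop("cubic regression splines take exactly one covariate")
  if (type == "tp" && length(vars) != 2)
    stop("thin-plate smooths take exactly two covariates")
  structure(list(vars = vars, k = as.integer(k), type = type),
            class = "smooth_spec")
}

#' Smooth term constructor for pgam formulas
#'
#' Used inside [pgam()] formulas, e.g. `y ~ s(PC1) + s(x_km, y_km, k = 9)`.
#'
#' @param ... one or two bare covariate names.
#' @param k basis dimension.
#' @param type basis type, see [smooth_spec()].
#' @export
s <- function(..., k = 9, type = NULL) {
  vars <- vapply(as.list(substitute(list(...)))[-1], deparse, character(1))
  smooth_spec(vars, k = k, type = type)
}

#' @export
print.smooth_spec <- function(x, ...) {
  cat(sprintf("s(%s, k = %d, type = \"%s\")\n",
              paste(x$vars, collapse = ", "), x$k, x$type))
  invisible(x)
}

## ---- cubic regression spline (values-at-knots parameterization) ----
## With knots xk and coefficients = function values at the knots, the natural
## cubic spline interpolant has second derivatives F %*% beta at the knots
## and integrated squared second derivative beta' S beta with S = D'B^{-1}D.
crs_setup <- function(xk) {
  k <- length(xk)
  h <- diff(xk)
  if (k < 3) stop("need at least 3 knots for a cubic regression spline")
  D <- matrix(0, k - 2, k)
  B <- matrix(0, k - 2, k - 2)
  for (i in seq_len(k - 2)) {
    D[i, i] <- 1 / h[i]
    D[i, i + 1] <- -1 / h[i] - 1 / h[i + 1]
    D[i, i + 2] <- 1 / h[i + 1]
    B[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < k - 2) B[i, i + 1] <- B[i + 1, i] <- h[i + 1] / 6
  }
  BiD <- solve(B, D)
  list(xk = xk, h = h, Fmat = rbind(0, BiD, 0), S = crossprod(D, BiD))
}

crs_design <- function(x, setup) {
  xk <- setup$xk; h <- setup$h; Fm <- setup$Fmat
  k <- length(xk)
  j <- findInterval(x, xk, all.inside = TRUE)  # clamp: cubic extrapolation
  xm <- xk[j]; xp <- xk[j + 1]; hj <- h[j]
  am <- (xp - x) / hj
  ap <- (x - xm) / hj
  cm <- ((xp - x)^3 / hj - hj * (xp - x)) / 6
  cp <- ((x - xm)^3 / hj - hj * (x - xm)) / 6
  X <- matrix(0, length(x), k)
  for (i in seq_along(x)) {
    X[i, j[i]] <- X[i, j[i]] + am[i]
    X[i, j[i] + 1] <- X[i, j[i] + 1] + ap[i]
    X[i, ] <- X[i, ] + cm[i] * Fm[j[i], ] + cp[i] * Fm[j[i] + 1, ]
  }
  X
}

## deterministic space-filling subset: farthest-point traversal seeded at the
## point closest to the centroid
space_fill_knots <- function(pts, k) {
  n <- nrow(pts)
  if (n <= k) return(pts)
  d2c <- rowSums(sweep(pts, 2, colMeans(pts))^2)
  sel <- which.min(d2c)
  dmin <- sqrt(rowSums(sweep(pts, 2, pts[sel, ])^2))
  while (length(sel) < k) {
    cand <- which.max(dmin)
    sel <- c(sel, cand)
    dmin <- pmin(dmin, sqrt(rowSums(sweep(pts, 2, pts[cand, ])^2)))
  }
  pts[sel, , drop = FALSE]
}

tps_eta <- function(r) ifelse(r > 0, r^2 * log(r), 0)

#' Build the (constrained) basis and penalty of one smooth term
#'
#' For one covariate: a cubic regression spline with `k` knots at covariate
#' quantiles and the integrated-squared-second-derivative penalty. For two
#' covariates: a thin-plate style radial basis (`r^2 log r`) on `k` knots
#' chosen by a space-filling subset of the observed sites, with polynomial
#' null space `{1, x, y}` and the bending-energy penalty. Either way the
#' sum-to-zero centering constraint is absorbed, leaving `k - 1` free
#' columns whose column sums are exactly zero.
#'
#' @param data data.frame holding the covariate(s).
#' @param spec a [smooth_spec()].
#' @return list with `X` (constrained design), `S` (penalty for the
#'   constrained coefficients), `null_dim` (penalty null space dimension
#'   after the constraint) and everything needed to evaluate the basis at
#'   new covariate values.
#' @export
build_basis <- function(data, spec) {
  stopifnot(inherits(spec, "smooth_spec"))
  miss <- setdiff(spec$vars, names(data))
  if (length(miss))
    stop(sprintf("covariate(s) not found: %s", paste(miss, collapse = ", ")))
  if (spec$type == "cr") {
    x <- data[[spec$vars]]
    ux <- sort(unique(x))
    if (length(ux) < 2) stop(sprintf("constant covariate '%s'", spec$vars))
    k <- spec$k
    if (length(ux) < k) {
      warning(sprintf("covariate '%s' has %d distinct values; reducing k from %d",
                      spec$vars, length(ux), k))
      k <- length(ux)
    }
    xk <- if (length(ux) == k) ux else
      unique(stats::quantile(x, probs = seq(0, 1, length.out = k),
                             names = FALSE, type = 7))
    k <- length(xk)
    if (k < 3) { xk <- c(ux[1], mean(range(ux)), ux[length(ux)])[1:3]
                 xk <- sort(unique(xk)); k <- length(xk) }
    if (k < 3) stop(sprintf("covariate '%s' has too few distinct values", spec$vars))
    setup <- crs_setup(xk)
    Xraw <- crs_design(x, setup)
    Sraw <- setup$S
    null_dim_raw <- 2  # linear functions
    info <- list(type = "cr", setup = setup)
  } else {
    pts <- as.matrix(data[spec$vars])
    upts <- unique(pts)
    if (nrow(upts) < 4)
      stop("thin-plate smooth needs at least 4 distinct sites")
    k <- min(spec$k, nrow(upts))
    if (k < 4) k <- 4
    knots <- space_fill_knots(upts, k)
    Ek <- tps_eta(as.matrix(stats::dist(knots)))
    Tk <- cbind(1, knots)
    Zk <- qr.Q(qr(Tk), complete = TRUE)[, -(1:3), drop = FALSE]  # T'delta = 0
    Ex <- tps_eta(outer(seq_len(nrow(pts)), seq_len(k), function(i, j)
      sqrt(rowSums((pts[i, , drop = FALSE] - knots[j, , drop = FALSE])^2))))
    Xraw <- cbind(Ex %*% Zk, 1, pts)      # radial part + null space {1, x, y}
    Sraw <- matrix(0, ncol(Xraw), ncol(Xraw))
    Sraw[seq_len(k - 3), seq_len(k - 3)] <- crossprod(Zk, Ek %*% Zk)
    null_dim_raw <- 3
    info <- list(type = "tp", knots = knots, Zk = Zk)
  }
  ## absorb the centering constraint c'beta = 0, c = column means
  cvec <- colMeans(Xraw)
  Z <- qr.Q(qr(matrix(cvec)), complete = TRUE)[, -1, drop = FALSE]
  X <- Xraw %*% Z
  S <- crossprod(Z, Sraw %*% Z)
  S <- (S + t(S)) / 2
  list(X = X, S = S, spec = spec, Z = Z, info = info,
       null_dim = null_dim_raw - 1)
}

## evaluate a term's constrained basis at new covariate values
eval_basis <- function(basis, data) {
  spec <- basis$spec
  if (basis$info$type == "cr") {
    Xraw <- crs_design(data[[spec$vars]], basis$info$setup)
  } else {
    pts <- as.matrix(data[spec$vars])
    knots <- basis$info$knots
    Ex <- tps_eta(outer(seq_len(nrow(pts)), seq_len(nrow(knots)), function(i, j)
      sqrt(rowSums((pts[i, , drop = FALSE] - knots[j, , drop = FALSE])^2))))
    Xraw <- cbind(Ex %*% basis$info$Zk, 1, pts)
  }
  Xraw %*% basis$Z
}

## null-space-only (linear) design for a term: centered covariate columns
linear_design <- function(data, spec) {
  X <- as.matrix(data[spec$vars])
  sweep(X, 2, colMeans(X))
}

## ---- penalized least squares machinery ----
pls_solve <- function(XtX, Xty, S_blocks, blocks, lambda) {
  A <- XtX
  for (t in seq_along(blocks))
    A[blocks[[t]], blocks[[t]]] <- A[blocks[[t]], blocks[[t]]] +
      lambda[t] * S_blocks[[t]]
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    A <- A + diag(1e-10 * max(diag(A)), nrow(A))
    R <- chol(A)
  }
  beta <- backsolve(R, forwardsolve(t(R), Xty))
  Ainv <- chol2inv(R)
  list(beta = beta, Ainv = Ainv)
}

gcv_score <- function(y, X, XtX, Xty, S_blocks, blocks, lambda, gamma, TSS) {
  sol <- pls_solve(XtX, Xty, S_blocks, blocks, lambda)
  fitted <- drop(X %*% sol$beta)
  rss <- sum((y - fitted)^2)
  edf <- sum(diag(sol$Ainv %*% XtX))
  n <- length(y)
  denom <- n - gamma * edf
  gcv <- if (denom <= sqrt(.Machine$double.eps)) Inf else n * rss / denom^2
  list(gcv = gcv, sol = sol, fitted = fitted, rss = rss, edf = edf)
}

golden_lambda <- function(obj_fun, lo = -6, hi = 8, tol = 1e-3) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- obj_fun(c1); fd <- obj_fun(d1)
  while (b - a > tol) {
    if (fc < fd) { b <- d1; d1 <- c1; fd <- fc
                   c1 <- b - gr * (b - a); fc <- obj_fun(c1) }
    else { a <- c1; c1 <- d1; fc <- fd
           d1 <- a + gr * (b - a); fd <- obj_fun(d1) }
  }
  opt <- (a + b) / 2
  ## compare against the bounds so a boundary optimum is honoured
  cand <- c(opt, lo, hi)
  vals <- c(obj_fun(opt), obj_fun(lo), obj_fun(hi))
  cand[which.min(vals)]
}

#' Fit a penalized-regression-spline GAM (Gaussian response)
#'
#' The model is \eqn{y = \alpha + \sum_t f_t(x_t) + \varepsilon} with each
#' `f_t` a penalized regression spline ([build_basis()]). Smoothing
#' parameters are chosen by minimizing the GCV score
#' \eqn{n \cdot RSS / (n - \gamma\,edf)^2} via golden-section search on
#' \eqn{\log \lambda_t}, cycling over terms until the fitted values
#' stabilize (max change < 1e-8). The response here is continuous (latent
#' ordination site scores); binomial handling lives entirely in the latent
#' model.
#'
#' Reported fit quality is the adjusted R-squared
#' \eqn{1 - [RSS/(n - edf)] / [TSS/(n - 1)]} with `edf` the trace of the
#' hat matrix (so for an unpenalized fit it reduces to the classical
#' Ezekiel adjustment). Term p-values are Wald-type tests on the penalized
#' coefficients with rank equal to the rounded term edf.
#'
#' @param formula model formula using [s()] terms, e.g.
#'   `score ~ s(PC1) + s(x_km, y_km)`. Bare variable names enter as linear
#'   (unpenalized) terms.
#' @param data data.frame with the response and covariates.
#' @param lambda optional fixed smoothing parameter(s), recycled over terms;
#'   when supplied no GCV search is run.
#' @param linear if `TRUE`, every smooth is replaced by its penalty null
#'   space (centered linear columns) and the fit is ordinary least squares —
#'   the linear limit used to bridge to classical variation partitioning.
#' @param gamma GCV effective-degrees-of-freedom inflation (default 1.4, the
#'   conventional guard against GCV's tendency to undersmooth, which would
#'   otherwise bias adjusted R-squared upwards for irrelevant smooths at
#'   small n).
#' @param k default basis dimension for terms that do not set their own.
#' @return an object of class `pgam`.
#' @examples
#' d <- data.frame(x = seq(0, 1, length.out = 40))
#' d$y <- sin(2 * pi * d$x) + rnorm(40, 0, 0.2)
#' f <- pgam(y ~ s(x), d)
#' summary(f)
#' @export
pgam <- function(formula, data, lambda = NULL, linear = FALSE, gamma = 1.4,
                 k = 9) {
  if (length(formula) != 3) stop("formula needs a response")
  y <- eval(formula[[2]], data, environment(formula))
  labels <- attr(stats::terms(formula), "term.labels")
  specs <- lapply(labels, function(lab) {
    expr <- str2lang(lab)
    if (is.call(expr) && identical(expr[[1]], as.name("s"))) {
      eval(expr, envir = asNamespace("pondvarpart"))
    } else smooth_spec(lab, k = k)  # placeholder; replaced below for linear names
  })
  ## bare names become linear terms
  for (i in seq_along(labels)) {
    expr <- str2lang(labels[i])
    if (!is.call(expr)) specs[[i]] <- structure(list(vars = labels[i]),
                                                class = "linear_term")
  }
  pgam_fit(y, specs, data, lambda = lambda, linear = linear, gamma = gamma,
           call = match.call())
}

#' Fit a pgam from a response vector and a list of term specs
#'
#' Programmatic interface behind [pgam()]; used by the partitioning and
#' selection code, where term sets are assembled by machine.
#'
#' @param y numeric response vector.
#' @param specs list of [smooth_spec()] objects (possibly empty: intercept
#'   only).
#' @param data data.frame of covariates.
#' @inheritParams pgam
#' @param call stored call for printing.
#' @return an object of class `pgam` with elements `coefficients`, `lambda`,
#'   `edf` (per term), `edf_total`, `fitted`, `residuals`, `sigma2`, `r2`,
#'   `r2_adj`, `term_pvalues`, `gcv`, `n`.
#' @export
pgam_fit <- function(y, specs, data, lambda = NULL, linear = FALSE,
                     gamma = 1.4, call = NULL) {
  n <- length(y)
  if (!is.numeric(y) || any(!is.finite(y))) stop("response must be finite numeric")
  nt <- length(specs)
  TSS <- sum((y - mean(y))^2)

  bases <- vector("list", nt)
  Xt_list <- vector("list", nt); St_list <- vector("list", nt)
  for (t in seq_len(nt)) {
    sp <- specs[[t]]
    if (inherits(sp, "linear_term") || linear) {
      Xt <- if (inherits(sp, "linear_term")) {
        Xl <- as.matrix(data[sp$vars]); sweep(Xl, 2, colMeans(Xl))
      } else linear_design(data, sp)
      bases[[t]] <- list(linear = TRUE, spec = sp,
                         centers = colMeans(as.matrix(data[sp$vars])))
      St <- matrix(0, ncol(Xt), ncol(Xt))
    } else {
      bases[[t]] <- build_basis(data, sp)
      Xt <- bases[[t]]$X
      St <- bases[[t]]$S
    }
    Xt_list[[t]] <- Xt
    St_list[[t]] <- St
  }
  ## collapse terms whose constrained designs are numerically identical
  ## (e.g. the same smooth supplied in two components): keeping both would
  ## silently halve the effective penalty and break redundancy identities
  dup_of <- rep(NA_integer_, nt)
  for (t in seq_len(nt)) {
    for (t1 in seq_len(t - 1)) {
      if (is.na(dup_of[t1]) &&
          identical(dim(Xt_list[[t]]), dim(Xt_list[[t1]])) &&
          max(abs(Xt_list[[t]] - Xt_list[[t1]])) < 1e-10) {
        dup_of[t] <- t1
        break
      }
    }
  }
  kept <- which(is.na(dup_of))
  Xs <- c(list(matrix(1, n, 1)), Xt_list[kept])
  S_blocks <- St_list[kept]
  blocks <- vector("list", length(kept))
  col0 <- 1
  for (i in seq_along(kept)) {
    blocks[[i]] <- col0 + seq_len(ncol(Xt_list[[kept[i]]]))
    col0 <- col0 + ncol(Xt_list[[kept[i]]])
  }
  X <- do.call(cbind, Xs)
  p <- ncol(X)
  if (n <= p && is.null(lambda) && !linear && nt > 0) {
    ## penalization keeps this solvable, but warn when n is very small
    if (n <= sum(vapply(bases, function(b)
      if (isTRUE(b$linear)) 1 else as.numeric(b$null_dim), 1.0)) + 1)
      stop("too few samples for the requested terms")
  }
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)

  nk <- length(kept)
  penalized <- !linear && nk > 0 &&
    any(vapply(S_blocks, function(S) any(S != 0), TRUE))
  if (!penalized) {
    lam <- rep(0, nk)
    ev <- gcv_score(y, X, XtX, Xty, S_blocks, blocks, lam, gamma, TSS)
  } else if (!is.null(lambda)) {
    lam <- rep(lambda, length.out = nt)[kept]
    ev <- gcv_score(y, X, XtX, Xty, S_blocks, blocks, lam, gamma, TSS)
  } else {
    lam <- rep(1, nk)
    fitted_old <- rep(Inf, n)
    for (sweep_i in 1:10) {
      for (t in seq_len(nk)) {
        if (all(S_blocks[[t]] == 0)) { lam[t] <- 0; next }
        obj <- function(loglam) {
          l2 <- lam; l2[t] <- 10^loglam
          gcv_score(y, X, XtX, Xty, S_blocks, blocks, l2, gamma, TSS)$gcv
        }
        lam[t] <- 10^golden_lambda(obj)
      }
      ev <- gcv_score(y, X, XtX, Xty, S_blocks, blocks, lam, gamma, TSS)
      if (max(abs(ev$fitted - fitted_old)) < 1e-8) break
      fitted_old <- ev$fitted
    }
  }

  beta <- drop(ev$sol$beta)
  Ainv <- ev$sol$Ainv
  Bmat <- Ainv %*% XtX
  edf_by_col <- diag(Bmat)
  edf_term_k <- vapply(seq_len(nk), function(t) sum(edf_by_col[blocks[[t]]]), 0)
  edf_total <- sum(edf_by_col)
  rss <- ev$rss
  sigma2 <- rss / max(n - edf_total, 1e-8)
  r2 <- if (TSS > 0) 1 - rss / TSS else 0
  r2_adj <- if (TSS > 0) 1 - (rss / max(n - edf_total, 1e-8)) / (TSS / (n - 1))
            else 0

  ## Wald-type term tests on the penalized coefficients
  Vb <- sigma2 * (Ainv %*% XtX %*% Ainv)
  pvals_k <- rep(NA_real_, nk)
  for (t in seq_len(nk)) {
    idx <- blocks[[t]]
    bt <- beta[idx]
    Vt <- (Vb[idx, idx, drop = FALSE] + t(Vb[idx, idx, drop = FALSE])) / 2
    r <- max(1L, min(length(idx), as.integer(round(edf_term_k[t]))))
    eg <- eigen(Vt, symmetric = TRUE)
    keep_ev <- seq_len(r)
    pos <- eg$values[keep_ev] > max(eg$values[1], 0) * 1e-12
    if (!any(pos)) { pvals_k[t] <- 1; next }
    Vi <- eg$vectors[, keep_ev, drop = FALSE][, pos, drop = FALSE]
    stat <- sum((crossprod(Vi, bt))^2 / eg$values[keep_ev][pos])
    df2 <- max(n - edf_total, 1)
    pvals_k[t] <- stats::pf(stat / r, r, df2, lower.tail = FALSE)
  }

  ## expand per-term results back to the full (possibly duplicated) term list
  edf_term <- rep(0, nt); pvals <- rep(NA_real_, nt); lam_full <- rep(NA_real_, nt)
  blocks_full <- rep(list(integer(0)), nt)
  edf_term[kept] <- edf_term_k
  pvals[kept] <- pvals_k
  lam_full[kept] <- lam
  blocks_full[kept] <- blocks
  tnames <- vapply(specs, function(sp)
    paste0("s(", paste(sp$vars, collapse = ","), ")"), character(1))
  names(edf_term) <- names(pvals) <- names(lam_full) <- tnames

  used_vars <- unique(unlist(lapply(specs, function(sp) sp$vars)))
  structure(list(coefficients = beta, lambda = lam_full, specs = specs,
                 bases = bases, blocks = blocks_full, duplicate_of = dup_of,
                 X = X, data_cov = data[intersect(used_vars, names(data))],
                 edf = edf_term, edf_total = edf_total,
                 fitted = ev$fitted, residuals = y - ev$fitted, y = y,
                 sigma2 = sigma2, rss = rss, tss = TSS,
                 r2 = r2, r2_adj = r2_adj, term_pvalues = pvals,
                 gcv = ev$gcv, n = n, gamma = gamma, linear = linear,
                 call = call),
            class = "pgam")
}

#' @export
print.pgam <- function(x, ...) {
  cat("Penalized-spline GAM (Gaussian)\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("n = %d, terms = %d, total edf = %.2f\n",
              x$n, length(x$specs), x$edf_total))
  cat(sprintf("R2 = %.4f, adjusted R2 = %.4f\n", x$r2, x$r2_adj))
  invisible(x)
}

#' @export
summary.pgam <- function(object, ...) {
  tab <- data.frame(edf = object$edf, lambda = object$lambda,
                    p_value = object$term_pvalues)
  out <- list(terms = tab, r2 = object$r2, r2_adj = object$r2_adj,
              sigma2 = object$sigma2, n = object$n,
              edf_total = object$edf_total, gcv = object$gcv)
  class(out) <- "summary.pgam"
  out
}

#' @export
print.summary.pgam <- function(x, ...) {
  cat("Penalized-spline GAM summary\n")
  if (nrow(x$terms)) {
    printCoefmat(as.matrix(x$terms), digits = 4, has.Pvalue = TRUE,
                 P.values = TRUE, cs.ind = integer(0), tst.ind = integer(0))
  } else cat("  (intercept only)\n")
  cat(sprintf("n = %d  total edf = %.2f  sigma2 = %.4g\n",
              x$n, x$edf_total, x$sigma2))
  cat(sprintf("R2 = %.4f  adjusted R2 = %.4f  GCV = %.4g\n",
              x$r2, x$r2_adj, x$gcv))
  invisible(x)
}

#' @export
coef.pgam <- function(object, ...) object$coefficients

#' @export
fitted.pgam <- function(object, ...) object$fitted

#' @export
residuals.pgam <- function(object, ...) object$residuals

#' Predict from a pgam fit
#'
#' @param object a `pgam`.
#' @param newdata data.frame of covariates; the training data when omitted.
#' @param type `"response"` (sum of all terms plus intercept) or `"terms"`
#'   (matrix of per-term contributions).
#' @param ... unused.
#' @export
predict.pgam <- function(object, newdata = NULL, type = c("response", "terms"),
                         ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "response") return(object$fitted)
    newdata <- NULL
  }
  nt <- length(object$specs)
  n_new <- if (is.null(newdata)) object$n else nrow(newdata)
  terms_mat <- matrix(0, n_new, nt)
  for (t in seq_len(nt)) {
    if (length(object$blocks[[t]]) == 0) next  # collapsed duplicate term
    b <- object$bases[[t]]
    sp <- object$specs[[t]]
    Xt <- if (is.null(newdata)) {
      object$X[, object$blocks[[t]], drop = FALSE]
    } else if (isTRUE(b$linear) || inherits(sp, "linear_term") || object$linear) {
      Xl <- as.matrix(newdata[sp$vars])
      sweep(Xl, 2, b$centers)
    } else eval_basis(b, newdata)
    terms_mat[, t] <- Xt %*% object$coefficients[object$blocks[[t]]]
  }
  if (type == "terms") {
    colnames(terms_mat) <- names(object$edf)
    return(terms_mat)
  }
  drop(object$coefficients[1] + rowSums(terms_mat))
}

#' Simulate responses from a fitted pgam
#'
#' Draws Gaussian responses around the fitted values with the estimated
#' residual variance.
#'
#' @param object a `pgam`.
#' @param nsim number of replicate response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @export
simulate.pgam <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  out <- as.data.frame(matrix(stats::rnorm(n * nsim, object$fitted,
                                           sqrt(object$sigma2)), n, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot the fitted smooths of a pgam
#'
#' One panel per term: 1D smooths are drawn as the fitted partial-effect
#' curve over the covariate range with partial residuals; 2D smooths as an
#' image of the fitted surface with the observed sites overlaid.
#'
#' @param x a `pgam`.
#' @param n_grid grid resolution per axis.
#' @param ... passed to the underlying plot calls.
#' @export
plot.pgam <- function(x, n_grid = 100, ...) {
  nt <- length(x$specs)
  if (nt == 0) return(invisible(x))
  op <- graphics::par(mfrow = c(1, nt)); on.exit(graphics::par(op))
  tm <- predict(x, type = "terms")
  for (t in seq_len(nt)) {
    sp <- x$specs[[t]]
    if (length(x$blocks[[t]]) == 0) next
    if (length(sp$vars) == 1) {
      xv <- x$data_cov[[sp$vars]]
      grid <- data.frame(seq(min(xv), max(xv), length.out = n_grid))
      names(grid) <- sp$vars
      b <- x$bases[[t]]
      Xg <- if (isTRUE(b$linear) || x$linear)
        sweep(as.matrix(grid), 2, b$centers) else eval_basis(b, grid)
      fg <- drop(Xg %*% x$coefficients[x$blocks[[t]]])
      pr <- tm[, t] + x$residuals
      graphics::plot(grid[[1]], fg, type = "l", xlab = sp$vars,
                     ylab = names(x$edf)[t],
                     ylim = range(c(fg, pr)), ...)
      graphics::points(xv, pr, col = "grey60", pch = 16, cex = 0.5)
    } else {
      xv <- x$data_cov[[sp$vars[1]]]; yv <- x$data_cov[[sp$vars[2]]]
      gx <- seq(min(xv), max(xv), length.out = n_grid)
      gy <- seq(min(yv), max(yv), length.out = n_grid)
      grid <- expand.grid(gx, gy)
      names(grid) <- sp$vars
      b <- x$bases[[t]]
      Xg <- if (isTRUE(b$linear) || x$linear)
        sweep(as.matrix(grid), 2, b$centers) else eval_basis(b, grid)
      fg <- matrix(Xg %*% x$coefficients[x$blocks[[t]]], n_grid, n_grid)
      graphics::image(gx, gy, fg, xlab = sp$vars[1], ylab = sp$vars[2],
                      main = names(x$edf)[t], ...)
      graphics::contour(gx, gy, fg, add = TRUE)
      graphics::points(xv, yv, pch = 16, cex = 0.5)
    }
  }
  invisible(x)
}

#' Forward selection of smooth terms with a double-stopping criterion
#'
#' Candidates are added greedily: at each step the candidate whose addition
#' gives the largest adjusted R-squared is considered. Selection stops when
#' (i) that candidate's term p-value is at or above `alpha`, (ii) the
#' selected model's adjusted R-squared has reached the adjusted R-squared of
#' the global model holding all candidates, or (iii) `max_terms` is reached.
#' If nothing is selected but some candidate is significant on its own, the
#' single most significant candidate is kept (so a component is represented
#' whenever it has any defensible signal).
#'
#' @param y response vector (one latent axis).
#' @param candidates list of [smooth_spec()] candidates.
#' @param data covariate data.frame.
#' @param alpha significance threshold (default 0.05).
#' @param max_terms cap on the number of selected terms (default all).
#' @param gamma GCV inflation passed to [pgam_fit()].
#' @return list with `selected` (list of specs), `log` (one row per decision:
#'   step, candidate, r2_adj, p, action), `global_r2_adj`, `fallback`.
#' @export
forward_select <- function(y, candidates, data, alpha = 0.05,
                           max_terms = length(candidates), gamma = 1.4) {
  stopifnot(length(candidates) >= 1)
  global <- pgam_fit(y, candidates, data, gamma = gamma)
  r2_global <- global$r2_adj
  sel <- list(); remaining <- candidates
  log <- list(); step <- 0; r2_sel <- 0
  cand_name <- function(sp) paste0("s(", paste(sp$vars, collapse = ","), ")")
  repeat {
    if (length(sel) >= max_terms || length(remaining) == 0) break
    step <- step + 1
    fits <- lapply(remaining, function(sp)
      pgam_fit(y, c(sel, list(sp)), data, gamma = gamma))
    r2s <- vapply(fits, function(f) f$r2_adj, 0)
    best <- which.max(r2s)   # exact ties: first (candidate order) wins
    p_best <- fits[[best]]$term_pvalues[length(sel) + 1]
    log[[length(log) + 1]] <- data.frame(
      step = step, candidate = cand_name(remaining[[best]]),
      r2_adj = r2s[best], p_value = p_best,
      action = if (is.na(p_best) || p_best >= alpha) "stop: p >= alpha" else "add",
      stringsAsFactors = FALSE)
    if (is.na(p_best) || p_best >= alpha) break
    sel <- c(sel, list(remaining[[best]]))
    r2_sel <- r2s[best]
    remaining <- remaining[-best]
    if (r2_sel >= r2_global) {
      log[[length(log) + 1]] <- data.frame(
        step = step, candidate = cand_name(sel[[length(sel)]]),
        r2_adj = r2_sel, p_value = p_best,
        action = "stop: reached global adjusted R2", stringsAsFactors = FALSE)
      break
    }
  }
  fallback <- FALSE
  if (length(sel) == 0) {
    singles <- lapply(candidates, function(sp) pgam_fit(y, list(sp), data,
                                                        gamma = gamma))
    ps <- vapply(singles, function(f) f$term_pvalues[1], 0)
    if (any(!is.na(ps) & ps < alpha)) {
      best <- which.min(ps)
      sel <- list(candidates[[best]])
      fallback <- TRUE
      log[[length(log) + 1]] <- data.frame(
        step = step + 1, candidate = cand_name(candidates[[best]]),
        r2_adj = singles[[best]]$r2_adj, p_value = ps[best],
        action = "fallback: single significant candidate",
        stringsAsFactors = FALSE)
    }
  }
  list(selected = sel,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(step = integer(), candidate = character(),
                    r2_adj = numeric(), p_value = numeric(),
                    action = character()),
       global_r2_adj = r2_global, fallback = fallback)
}
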