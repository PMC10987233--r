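## average adjusted R2 across latent axes for one set of term specs
avg_r2 <- function(axes_mat, specs, data, gamma = 1.4, linear = FALSE,
                   lambda = NULL) {
  if (length(specs) == 0) return(0)
  mean(apply(axes_mat, 2, function(y)
    pgam_fit(y, specs, data, gamma = gamma, linear = linear,
             lambda = lambda)$r2_adj))
}

#' Two-component variation partitioning (environment, space)
#'
#' Per latent axis, GAMs are fitted for the environmental terms (E), the
#' spatial terms (S) and their union (E + S); each model's adjusted
#' R-squared is averaged over axes (unweighted) to give a canonical value,
#' and the unique and common fractions follow by inclusion-exclusion:
#' `pure_E = R2(E+S) - R2(S)`, `pure_S = R2(E+S) - R2(E)`,
#' `common = R2(E) + R2(S) - R2(E+S)`. Negative fractions (a known artifact
#' of adjusted R-squared) are kept in the raw view and truncated to 0 in the
#' reported view. Optionally the environmental fractions are corrected
#' against spatially constrained nulls (see [correct_env()]).
#'
#' @param axes a `latent_axes` object or a numeric matrix of response axes.
#' @param E_terms,S_terms lists of [smooth_spec()] for each component
#'   (typically pre-screened with [forward_select()]); either may be empty.
#' @param data covariate data.frame (PC scores, coordinates).
#' @param gamma,linear,lambda passed to [pgam_fit()].
#' @param correction if `TRUE`, run the Moran-spectral-randomization
#'   correction of the environmental fractions.
#' @param env_vars character vector naming the environmental predictor
#'   columns to randomize under the null (defaults to the union of
#'   covariates in `E_terms`).
#' @param coords site coordinates per sample (for the correction); taken
#'   from columns `x_km`, `y_km` of `data` when `NULL`.
#' @param n_null,seed null replicates and seed for the correction.
#' @return object of class `varpart2`.
#' @export
partition_two <- function(axes, E_terms, S_terms, data, gamma = 1.4,
                          linear = FALSE, lambda = NULL,
                          correction = FALSE, env_vars = NULL,
                          coords = NULL, n_null = 199, seed = 1) {
  A <- axes_scores(axes)
  a <- avg_r2(A, E_terms, data, gamma, linear, lambda)   # R2(E)
  b <- avg_r2(A, S_terms, data, gamma, linear, lambda)   # R2(S)
  ab <- avg_r2(A, c(E_terms, S_terms), data, gamma, linear, lambda)
  if (length(E_terms) == 0 && length(S_terms) == 0)
    warning("both component selections empty; degenerate partition")
  fr <- c(pure_E = ab - b, pure_S = ab - a, common = a + b - ab)
  res <- structure(list(total = ab, R2 = c(E = a, S = b, ES = ab),
                        fractions = fr, corrected = NULL,
                        n_axes = ncol(A),
                        degenerate = length(E_terms) == 0 && length(S_terms) == 0),
                   class = "varpart2")
  if (correction) {
    res <- correct_env(res, axes = A, E_terms = E_terms, S_terms = S_terms,
                       data = data, env_vars = env_vars, coords = coords,
                       n_null = n_null, seed = seed, gamma = gamma,
                       linear = linear, lambda = lambda)
  }
  res
}

#' Three-component variation partitioning (environment, space, time)
#'
#' Pooled (spatio-temporal) partition: the seven models E, S, T, E+S, E+T,
#' S+T and E+S+T are fitted per axis, adjusted R-squared values averaged
#' over axes, and the seven unique/common fractions recovered by
#' inclusion-exclusion:
#' `pure_E = R2(EST) - R2(ST)` (and cyclically), `ES_given_T = R2(EST) -
#' R2(T) - pure_E - pure_S` (and cyclically), with the triple overlap
#' `EST` as the remainder. A constant temporal covariate degrades gracefully
#' (its models equal the ones without it, so all temporal fractions are 0).
#'
#' @inheritParams partition_two
#' @param T_terms list of specs for the temporal component (typically a
#'   single 1D smooth of days since first sampling).
#' @param occasions integer occasion index per sample (needed for the
#'   spatio-temporal null correction).
#' @param pond_index integer pond index per sample (ditto).
#' @return object of class `varpart3`.
#' @export
partition_three <- function(axes, E_terms, S_terms, T_terms, data,
                            gamma = 1.4, linear = FALSE, lambda = NULL,
                            correction = FALSE, env_vars = NULL,
                            coords = NULL, occasions = NULL,
                            pond_index = NULL, n_null = 199, seed = 1) {
  A <- axes_scores(axes)
  ## constant temporal covariate: treat the temporal block as empty
  T_eff <- Filter(function(sp) {
    v <- data[[sp$vars[1]]]
    length(unique(v)) > 1
  }, T_terms)
  r2_of <- function(specs) avg_r2(A, specs, data, gamma, linear, lambda)
  RA <- r2_of(E_terms); RB <- r2_of(S_terms); RC <- r2_of(T_eff)
  RAB <- r2_of(c(E_terms, S_terms))
  RAC <- r2_of(c(E_terms, T_eff))
  RBC <- r2_of(c(S_terms, T_eff))
  RABC <- r2_of(c(E_terms, S_terms, T_eff))
  a <- RABC - RBC          # pure E
  b <- RABC - RAC          # pure S
  cc <- RABC - RAB         # pure T
  d <- RABC - RC - a - b   # (E & S) | T
  f <- RABC - RB - a - cc  # (E & T) | S
  e <- RABC - RA - b - cc  # (S & T) | E
  g <- RABC - a - b - cc - d - e - f
  fr <- c(pure_E = a, pure_S = b, pure_T = cc,
          ES_given_T = d, ET_given_S = f, ST_given_E = e, EST = g)
  res <- structure(list(total = RABC,
                        R2 = c(E = RA, S = RB, T = RC, ES = RAB, ET = RAC,
                               ST = RBC, EST = RABC),
                        fractions = fr, corrected = NULL, n_axes = ncol(A),
                        degenerate = length(E_terms) == 0 &&
                          length(S_terms) == 0 && length(T_eff) == 0),
                   class = "varpart3")
  if (correction) {
    res <- correct_env(res, axes = A, E_terms = E_terms, S_terms = S_terms,
                       T_terms = T_eff, data = data, env_vars = env_vars,
                       coords = coords, occasions = occasions,
                       pond_index = pond_index, n_null = n_null, seed = seed,
                       gamma = gamma, linear = linear, lambda = lambda)
  }
  res
}

#' Null-model correction of the environmental fractions
#'
#' A spatially structured environment can explain community structure for
#' purely spatial reasons; the naive environmental fractions are then
#' inflated. The correction replaces the environmental predictors by Moran
#' spectral randomization surrogates — null variables with the observed
#' variance and Moran's I but no genuine link to the response — refits every
#' E-containing model under each null, and subtracts the null-mean of each
#' environmentally labelled fraction from its observed value. For the
#' three-component case the surrogates are drawn on the Kronecker
#' combination of spatial and temporal eigenvectors, preserving
#' spatio-temporal autocorrelation.
#'
#' @param partition a `varpart2` or `varpart3` from [partition_two()] /
#'   [partition_three()].
#' @param axes response axes matrix (as used for the partition).
#' @param E_terms,S_terms,T_terms the term lists used for the partition.
#' @param data covariate data.frame.
#' @param env_vars environmental columns to randomize; defaults to the union
#'   of covariates appearing in `E_terms`.
#' @param coords per-sample coordinates (`x_km`, `y_km` columns of `data`
#'   when `NULL`).
#' @param occasions,pond_index per-sample occasion and pond indices (3-way
#'   correction only); both must describe a complete pond x occasion panel.
#' @param n_null number of null replicates (default 199).
#' @param seed integer seed.
#' @param gamma,linear,lambda passed to [pgam_fit()].
#' @return the partition with a `corrected` element: corrected fractions,
#'   null means, and the number of nulls; non-environmental fractions are
#'   untouched. If fewer than 4 sites are available the raw partition is
#'   returned with `corrected = NULL` and a flag.
#' @export
correct_env <- function(partition, axes, E_terms, S_terms, T_terms = NULL,
                        data, env_vars = NULL, coords = NULL,
                        occasions = NULL, pond_index = NULL,
                        n_null = 199, seed = 1, gamma = 1.4, linear = FALSE,
                        lambda = NULL) {
  A <- axes_scores(axes)
  if (length(E_terms) == 0) {
    partition$corrected <- NULL
    partition$correction_note <- "no environmental terms selected; nothing to correct"
    return(partition)
  }
  if (is.null(env_vars))
    env_vars <- unique(unlist(lapply(E_terms, function(sp) sp$vars)))
  if (is.null(coords)) {
    if (!all(c("x_km", "y_km") %in% names(data)))
      stop("coords not given and data lacks x_km/y_km columns")
    coords <- as.matrix(data[, c("x_km", "y_km")])
  }
  three_way <- inherits(partition, "varpart3")

  if (three_way) {
    if (is.null(occasions) || is.null(pond_index))
      stop("occasions and pond_index are required for the 3-way correction")
    P <- length(unique(pond_index)); Tn <- length(unique(occasions))
    if (P < 4) {
      partition$correction_note <- "fewer than 4 ponds; correction unavailable"
      return(partition)
    }
    if (P * Tn != nrow(data) ||
        any(table(pond_index, occasions) != 1))
      stop("3-way correction needs a complete pond x occasion panel")
    cp <- coords[match(seq_len(P), pond_index), , drop = FALSE]
    stb <- st_mem_basis(cp, Tn)
    ## reorder basis rows (pond-major) to the sample order
    row_of <- pond_index + (occasions - 1) * P
    basis <- list(vectors = stb$vectors[row_of, , drop = FALSE])
  } else {
    upond <- unique(coords)
    if (nrow(upond) < 4) {
      partition$correction_note <- "fewer than 4 ponds; correction unavailable"
      return(partition)
    }
    if (nrow(upond) == nrow(coords)) {
      basis <- mem_basis(coords)
    } else {
      ## repeated sites (pooled samples): spatial basis expanded by site
      idx <- match(apply(coords, 1, paste, collapse = "_"),
                   apply(upond, 1, paste, collapse = "_"))
      sb <- mem_basis(upond)
      basis <- list(vectors = sb$vectors[idx, , drop = FALSE] /
                      sqrt(tabulate(idx)[1]))
    }
  }

  set.seed(seed)
  var_seeds <- sample.int(2^30, length(env_vars))
  sur <- lapply(seq_along(env_vars), function(v)
    msr_surrogates(data[[env_vars[v]]], basis, n_null, seed = var_seeds[v]))
  names(sur) <- env_vars

  ## capture the observed fits' smoothing parameters per model and axis; the
  ## nulls are refit at those fixed lambdas so that the null distribution
  ## isolates the spatial(-temporal) contribution and is not inflated by
  ## re-tuning the smoothness to each surrogate
  model_specs <- if (three_way) list(
    E = E_terms, ES = c(E_terms, S_terms), ET = c(E_terms, T_terms),
    EST = c(E_terms, S_terms, T_terms))
  else list(E = E_terms, ES = c(E_terms, S_terms))
  obs_lams <- lapply(model_specs, function(sp)
    lapply(seq_len(ncol(A)), function(j) {
      l <- unname(pgam_fit(A[, j], sp, data, gamma = gamma,
                           linear = linear, lambda = lambda)$lambda)
      l[is.na(l)] <- 1
      l
    }))
  r2_fixed <- function(sp_name, dat_w) {
    sp <- model_specs[[sp_name]]
    if (length(sp) == 0) return(0)
    mean(vapply(seq_len(ncol(A)), function(j)
      pgam_fit(A[, j], sp, dat_w, gamma = gamma, linear = linear,
               lambda = obs_lams[[sp_name]][[j]])$r2_adj, 0))
  }

  env_frac_names <- if (three_way)
    c("pure_E", "ES_given_T", "ET_given_S", "EST") else c("pure_E", "common")
  null_fr <- matrix(NA_real_, n_null, length(env_frac_names),
                    dimnames = list(NULL, env_frac_names))
  dat_w <- data
  for (w in seq_len(n_null)) {
    for (v in env_vars) dat_w[[v]] <- sur[[v]][, w]
    if (three_way) {
      R2n <- c(E = r2_fixed("E", dat_w), ES = r2_fixed("ES", dat_w),
               ET = r2_fixed("ET", dat_w), EST = r2_fixed("EST", dat_w))
      null_fr[w, ] <- recombine3(R2n, partition$R2)[env_frac_names]
    } else {
      aw <- r2_fixed("E", dat_w)
      abw <- r2_fixed("ES", dat_w)
      b <- partition$R2[["S"]]
      null_fr[w, "pure_E"] <- abw - b
      null_fr[w, "common"] <- aw + b - abw
    }
  }
  null_mean <- colMeans(null_fr)
  corrected <- partition$fractions
  corrected[env_frac_names] <- corrected[env_frac_names] - null_mean
  partition$corrected <- list(fractions = corrected,
                              total = sum(corrected),
                              null_mean = null_mean, n_null = n_null,
                              method = "MSR on environmental predictors (sign-flip remixing)")
  partition
}

## recompute 3-way fractions from null E-model R2s combined with the
## observed S/T-only R2s
recombine3 <- function(R2_null, R2_obs) {
  RA <- R2_null[["E"]]; RAB <- R2_null[["ES"]]; RAC <- R2_null[["ET"]]
  RABC <- R2_null[["EST"]]
  RB <- R2_obs[["S"]]; RC <- R2_obs[["T"]]; RBC <- R2_obs[["ST"]]
  a <- RABC - RBC; b <- RABC - RAC; cc <- RABC - RAB
  d <- RABC - RC - a - b
  f <- RABC - RB - a - cc
  e <- RABC - RA - b - cc
  g <- RABC - a - b - cc - d - e - f
  c(pure_E = a, pure_S = b, pure_T = cc, ES_given_T = d, ET_given_S = f,
    ST_given_E = e, EST = g)
}

#' Truncated and relative views of a partition
#'
#' Negative raw fractions are truncated to zero, and each truncated fraction
#' is divided by the sum of truncated fractions, giving the relative shares
#' used to compare taxa and regions. When the correction has been run, the
#' corrected fractions are used; otherwise the raw ones. If no variation is
#' explained the relative view is undefined and flagged.
#'
#' @param partition a `varpart2` or `varpart3`.
#' @param use `"corrected"` (default: corrected when available) or `"raw"`.
#' @return the partition with `truncated`, `relative` and
#'   `relative_defined` elements added.
#' @export
relative_fractions <- function(partition, use = c("corrected", "raw")) {
  use <- match.arg(use)
  fr <- if (use == "corrected" && !is.null(partition$corrected))
    partition$corrected$fractions else partition$fractions
  tr <- pmax(fr, 0)
  tot <- sum(tr)
  partition$truncated <- tr
  if (tot > 0) {
    partition$relative <- tr / tot
    partition$relative_defined <- TRUE
  } else {
    partition$relative <- tr * NA_real_
    partition$relative_defined <- FALSE
  }
  partition
}

print_partition <- function(x, labels) {
  cat(sprintf("  total adjusted R2 (%s): %.4f over %d axes\n",
              labels, x$total, x$n_axes))
  tab <- data.frame(raw = x$fractions)
  if (!is.null(x$corrected)) tab$corrected <- x$corrected$fractions
  if (!is.null(x$truncated)) tab$truncated <- x$truncated
  if (!is.null(x$relative)) tab$relative <- x$relative
  print(round(tab, 4))
  if (!is.null(x$correction_note)) cat("  note:", x$correction_note, "\n")
  invisible(x)
}

#' @export
print.varpart2 <- function(x, ...) {
  cat("Variation partitioning: environment (E) + space (S)\n")
  print_partition(x, "E+S")
}

#' @export
print.varpart3 <- function(x, ...) {
  cat("Variation partitioning: environment (E) + space (S) + time (T)\n")
  print_partition(x, "E+S+T")
}
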