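#' Tag environmental variables with a transform
#'
#' The two transforms in use are the conventional ones for environmental
#' predictors with awkward distributions: arcsine square root for
#' proportions, logarithm for right-skewed positive quantities. The rule
#' applied per variable is:
#' * every value in \[0, 1\] (a proportion-type variable) -> `asin_sqrt`;
#' * strictly positive with moment skewness > 1 -> `log`;
#' * otherwise -> `none`.
#'
#' @param env data.frame or matrix of raw environmental values.
#' @param meta optional metadata data.frame (`variable`, `class`,
#'   `transform`); when given, its `transform` column is overwritten and the
#'   rest preserved.
#' @return a metadata data.frame with columns `variable`, `class`,
#'   `transform`.
#' @export
auto_tag_transforms <- function(env, meta = NULL) {
  env <- as.matrix(env)
  tags <- vapply(seq_len(ncol(env)), function(j) {
    x <- env[, j]
    if (all(x >= 0 & x <= 1)) return("asin_sqrt")
    if (all(x > 0) && moment_skewness(x) > 1) return("log")
    "none"
  }, character(1))
  if (is.null(meta))
    meta <- data.frame(variable = colnames(env),
                       class = "limnological", stringsAsFactors = FALSE)
  meta$transform <- tags
  meta
}

## sample skewness by the moment formula m3 / m2^(3/2)
moment_skewness <- function(x) {
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 < 1e-300) return(0)
  mean(xc^3) / m2^1.5
}

#' Apply tagged transforms to environmental variables
#'
#' Variables tagged `asin_sqrt` get `asin(sqrt(x))` (values must lie in
#' \[0, 1\]); variables tagged `log` get `log(x + c)` where `c` is half the
#' smallest positive value when zeros occur and 0 otherwise (negative values
#' are an error); `none` passes through. The constants actually applied are
#' recorded in the returned metadata.
#'
#' @param env data.frame or matrix of raw values.
#' @param meta metadata with a `transform` column (see
#'   [auto_tag_transforms()]); if missing, tags are derived automatically.
#' @return list with `env` (transformed data.frame) and `meta` (with an
#'   added `log_offset` column).
#' @export
transform_env <- function(env, meta = NULL) {
  env <- as.data.frame(env)
  if (any(!vapply(env, is.numeric, TRUE)))
    stop("all environmental variables must be numeric")
  if (any(!is.finite(as.matrix(env))))
    stop("environmental values must be finite; impute or drop explicitly first")
  if (is.null(meta)) meta <- auto_tag_transforms(env)
  stopifnot(all(meta$variable == colnames(env)))
  meta$log_offset <- 0
  for (j in seq_along(env)) {
    x <- env[[j]]
    tag <- meta$transform[j]
    if (tag == "asin_sqrt") {
      if (any(x < 0 | x > 1))
        stop(sprintf("variable '%s' tagged asin_sqrt has values outside [0, 1]",
                     meta$variable[j]))
      env[[j]] <- asin(sqrt(x))
    } else if (tag == "log") {
      if (any(x < 0))
        stop(sprintf("variable '%s' tagged log has negative values",
                     meta$variable[j]))
      c0 <- if (any(x == 0)) min(x[x > 0]) / 2 else 0
      meta$log_offset[j] <- c0
      env[[j]] <- log(x + c0)
    } else if (tag != "none") {
      stop(sprintf("unknown transform tag '%s'", tag))
    }
  }
  list(env = env, meta = meta)
}

#' Principal component scores of the environment
#'
#' Centers and scales each variable to unit variance and eigen-decomposes the
#' correlation matrix (variables mix units, so the correlation rather than
#' covariance matrix is the defensible choice). Returns the first `n_pcs`
#' score columns; these condensed axes stand in for the full variable set as
#' environmental predictors downstream. Sign convention: the
#' largest-magnitude entry of each loading vector is positive, making scores
#' reproducible across platforms.
#'
#' @param env transformed environmental data (samples x variables).
#' @param n_pcs number of components to keep (default 3).
#' @return object of class `env_pca`: list with `scores` (n x n_pcs),
#'   `loadings` (variables x n_pcs), `explained` (variance fractions for all
#'   components), `center`, `scale`.
#' @export
pca_reduce <- function(env, n_pcs = 3) {
  X <- as.matrix(env)
  if (ncol(X) < n_pcs)
    stop(sprintf("need at least %d variables", n_pcs))
  if (nrow(X) < 4) stop("need at least 4 samples")
  sds <- apply(X, 2, stats::sd)
  if (any(sds < 1e-12))
    stop(sprintf("zero-variance variable(s): %s",
                 paste(colnames(X)[sds < 1e-12], collapse = ", ")))
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pr$sdev^2
  explained <- ev / sum(ev)
  L <- pr$rotation[, seq_len(n_pcs), drop = FALSE]
  S <- pr$x[, seq_len(n_pcs), drop = FALSE]
  for (k in seq_len(n_pcs)) {   # deterministic sign convention
    i <- which.max(abs(L[, k]))
    if (L[i, k] < 0) { L[, k] <- -L[, k]; S[, k] <- -S[, k] }
  }
  colnames(S) <- colnames(L) <- paste0("PC", seq_len(n_pcs))
  structure(list(scores = S, loadings = L, explained = explained,
                 center = pr$center, scale = pr$scale),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("Environmental PCA: %d samples, first %d components\n",
              nrow(x$scores), k))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained[seq_len(k)]), collapse = ", "),
      sprintf("(cumulative %.1f%%)\n", 100 * sum(x$explained[seq_len(k)])))
  invisible(x)
}
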