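#' Moran eigenvector basis from site coordinates
#'
#' Builds spatial eigenfunctions: Gabriel-graph connectivity between sites,
#' symmetric (Sinkhorn) balancing of the binary weights towards double
#' stochasticity, double centering, and eigen-decomposition. Eigenvectors
#' associated with positive eigenvalues describe positively autocorrelated
#' (broad to fine scale) spatial patterns; the full orthonormal set (minus
#' the constant) spans all centered site vectors, which is what the spectral
#' randomization needs.
#'
#' @param coords matrix of site coordinates (2 columns, planar km).
#' @return object of class `mem_basis`: `vectors` (n x (n-1), orthonormal,
#'   all orthogonal to 1), `values` (matching eigenvalues of the centered
#'   weight matrix), `W` (balanced weights), `n_pos` (count of positive
#'   eigenvalues).
#' @export
mem_basis <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 4) stop("need at least 4 sites for a Moran eigenvector basis")
  A <- gabriel_graph(coords)
  ## symmetric Sinkhorn balancing: D A D with row sums driven to 1
  dvec <- rep(1, n)
  for (it in 1:200) {
    rs <- drop(A %*% dvec) * dvec
    if (max(abs(rs - 1)) < 1e-12) break
    dvec <- dvec / sqrt(pmax(rs, 1e-12))
  }
  W <- A * tcrossprod(dvec)
  ce <- centered_eigen(W)
  structure(list(vectors = ce$vectors, values = ce$values, W = W,
                 n_pos = sum(ce$values > 1e-10), coords = coords),
            class = "mem_basis")
}

## eigen-decomposition of a symmetric weight matrix restricted to the
## orthogonal complement of the constant vector; returns an exactly
## orthonormal basis of the centered space (robust to degenerate zero
## eigenvalues, which can otherwise mix the constant into the basis)
centered_eigen <- function(W) {
  n <- nrow(W)
  H0 <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
  B2 <- crossprod(H0, W %*% H0)
  eg <- eigen((B2 + t(B2)) / 2, symmetric = TRUE)
  list(vectors = H0 %*% eg$vectors, values = eg$values)
}

## Gabriel graph: i-j connected iff no third point lies inside the circle
## with segment ij as diameter; O(n^3), fine for a few dozen ponds
gabriel_graph <- function(coords) {
  n <- nrow(coords)
  d2 <- as.matrix(stats::dist(coords))^2
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- TRUE
    for (kk in seq_len(n)) {
      if (kk == i || kk == j) next
      if (d2[i, kk] + d2[j, kk] < d2[i, j] - 1e-12) { ok <- FALSE; break }
    }
    if (ok) A[i, j] <- A[j, i] <- 1
  }
  A
}

#' Moran's I of a variable under a weight matrix
#'
#' @param x numeric vector.
#' @param W symmetric spatial weight matrix (same order as `x`).
#' @return Moran's I.
#' @export
moran_I <- function(x, W) {
  xc <- x - mean(x)
  n <- length(x)
  (n / sum(W)) * drop(crossprod(xc, W %*% xc)) / sum(xc^2)
}

#' Moran spectral randomization surrogates
#'
#' Generates spatially constrained null versions of a variable: the centered
#' variable is decomposed on the full Moran eigenvector basis and the
#' coefficients are remixed by random sign flips (a random orthogonal
#' diagonal map). Because each eigenvector's squared coefficient is
#' untouched, every surrogate preserves the variable's variance and Moran's
#' I exactly, while destroying its alignment with any particular response.
#'
#' @param x numeric vector (a site-level variable).
#' @param basis a [mem_basis()] (or any list with orthonormal `vectors`
#'   orthogonal to the constant).
#' @param n_sim number of surrogates.
#' @param seed integer seed.
#' @return matrix (length(x) x n_sim) of surrogate variables.
#' @export
msr_surrogates <- function(x, basis, n_sim, seed = 1) {
  U <- basis$vectors
  stopifnot(nrow(U) == length(x))
  xc <- x - mean(x)
  cf <- drop(crossprod(U, xc))
  resid <- xc - drop(U %*% cf)   # 0 when the basis spans the centered space
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), length(cf) * n_sim, replace = TRUE),
                  length(cf), n_sim)
  mean(x) + resid + U %*% (signs * cf)
}

## spatio-temporal eigenvector basis: Kronecker combination of the spatial
## basis (plus constant) with a temporal chain-graph basis (plus constant),
## minus the overall constant. Rows are ordered to match sample_frame via
## (pond index, occasion index).
st_mem_basis <- function(coords_pond, n_occasions) {
  sb <- mem_basis(coords_pond)
  P <- nrow(coords_pond)
  Us <- cbind(1 / sqrt(P), sb$vectors)          # orthonormal incl. constant
  Tn <- n_occasions
  if (Tn < 2) stop("spatio-temporal basis needs at least 2 occasions")
  Wt <- matrix(0, Tn, Tn)
  for (i in seq_len(Tn - 1)) Wt[i, i + 1] <- Wt[i + 1, i] <- 1
  Ut <- cbind(1 / sqrt(Tn), centered_eigen(Wt)$vectors)
  ## sample index (pond p, occasion t) -> row p + (t-1) * P
  cols <- list()
  for (a in seq_len(ncol(Us))) for (b in seq_len(ncol(Ut))) {
    if (a == 1 && b == 1) next
    cols[[length(cols) + 1]] <- as.vector(outer(Us[, a], Ut[, b]))
  }
  U <- do.call(cbind, cols)  # (P*Tn) x (P*Tn - 1), orthonormal
  list(vectors = U, spatial = sb)
}
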