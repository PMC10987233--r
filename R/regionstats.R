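#' PERMDISP: homogeneity of multivariate dispersion
#'
#' Compares environmental heterogeneity between groups (e.g. regions or
#' sampling periods): Euclidean distances on standardized variables,
#' principal-coordinate embedding with a spatial median per group
#' (vegan's `betadisper`, type `"median"` by default), one-way ANOVA F on
#' the per-sample distances to the own group's median, and a permutation
#' p-value obtained by reshuffling group labels of the distance vectors
#' under a controllable seed: `p = (#\{F* >= F\} + 1) / (n_perm + 1)`.
#'
#' @param env matrix or data.frame of (transformed) environmental variables.
#' @param groups factor-like group labels, one per row; at least 2 groups
#'   with at least 2 samples each.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param type `"median"` (spatial median, default) or `"centroid"`.
#' @param standardize scale columns to unit variance first (default TRUE).
#' @return object of class `permdisp_res`: `F`, `p`, `n_perm`, `distances`,
#'   `groups`.
#' @export
permdisp <- function(env, groups, n_perm = 999, seed = 1,
                     type = c("median", "centroid"), standardize = TRUE) {
  type <- match.arg(type)
  X <- as.matrix(env)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    X <- scale(X, scale = ifelse(sds > 0, sds, 1))
  }
  bd <- vegan::betadisper(stats::dist(X), groups, type = type)
  z <- as.numeric(bd$distances)

  f_stat <- function(z, g) {
    gm <- tapply(z, g, mean); ng <- tabulate(g)
    ssb <- sum(ng * (gm - mean(z))^2)
    ssw <- sum((z - gm[as.integer(g)])^2)
    k <- nlevels(g); n <- length(z)
    msw <- ssw / (n - k)
    if (msw < 1e-300) return(if (ssb < 1e-300) 0 else Inf)
    (ssb / (k - 1)) / msw
  }
  Fobs <- f_stat(z, groups)
  set.seed(seed)
  Fperm <- vapply(seq_len(n_perm), function(i)
    f_stat(z, groups[sample.int(length(z))]), 0)
  p <- (sum(Fperm >= Fobs) + 1) / (n_perm + 1)
  structure(list(F = Fobs, p = p, n_perm = n_perm, distances = z,
                 groups = groups, type = type),
            class = "permdisp_res")
}

#' @export
print.permdisp_res <- function(x, ...) {
  cat(sprintf("PERMDISP (%s): F = %.4f, permutation p = %.4g (%d permutations)\n",
              x$type, x$F, x$p, x$n_perm))
  gm <- tapply(x$distances, x$groups, mean)
  cat("  mean distance to group", x$type, ":",
      paste(sprintf("%s = %.3f", names(gm), gm), collapse = ", "), "\n")
  invisible(x)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided exact test for paired values: zero differences are dropped
#' (with a warning), absolute differences are midranked, V is the sum of
#' ranks of the positive differences, and the exact p-value comes from the
#' full distribution of V over all 2^n equally likely sign assignments of
#' the observed ranks, computed by generating-function convolution
#' (identical to complete enumeration):
#' `p = min(1, 2 * min(P(V* <= V), P(V* >= V)))`.
#' With 7 pairs whose differences all share one sign, V is 0 or 28 and
#' p = 2 / 2^7 = 0.015625.
#'
#' @param x,y numeric vectors of equal length (paired observations).
#' @return object of class `wilcoxon_exact`: `V`, `p`, `n` (pairs used).
#' @export
wilcoxon_paired_exact <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  if (any(d == 0)) {
    warning(sprintf("dropping %d zero difference(s)", sum(d == 0)))
    d <- d[d != 0]
  }
  n <- length(d)
  if (n == 0) stop("no informative pairs (all differences zero)")
  if (n > 25) stop("exact enumeration supports at most 25 nonzero pairs")
  r <- rank(abs(d))          # midranks under ties
  V <- sum(r[d > 0])
  ## doubled ranks are integers even with .5 midranks
  r2 <- as.integer(round(2 * r))
  maxs <- sum(r2)
  ## distribution of 2V over sign assignments: polynomial product
  dist <- numeric(maxs + 1); dist[1] <- 1   # dist[s + 1] = #assignments with 2V = s
  for (ri in r2) {
    shifted <- c(rep(0, ri), dist[seq_len(maxs + 1 - ri)])
    dist <- dist + shifted
  }
  dist <- dist / 2^n
  V2 <- as.integer(round(2 * V))
  p_le <- sum(dist[seq_len(V2 + 1)])
  p_ge <- sum(dist[(V2 + 1):(maxs + 1)])
  p <- min(1, 2 * min(p_le, p_ge))
  structure(list(V = V, p = p, n = n), class = "wilcoxon_exact")
}

#' @export
print.wilcoxon_exact <- function(x, ...) {
  cat(sprintf("Exact paired Wilcoxon signed-rank test: V = %g, p = %.6g (n = %d)\n",
              x$V, x$p, x$n))
  invisible(x)
}

#' Compare the spatial and spatio-temporal approaches per fraction
#'
#' For each taxon, the snapshot ("spatial") approach contributes the mean
#' over sampling periods of each relative fraction, and the pooled
#' spatio-temporal approach contributes the corresponding fraction
#' recalculated after excluding the temporal effects: the purely
#' environmental, purely spatial and spatially-structured-environment
#' fractions are renormalized over their own sum (the E+S mass), making the
#' two approaches directly comparable. Paired exact Wilcoxon tests are then
#' run across taxa for `pure_E`, `pure_S` and `common`.
#'
#' @param spatial data.frame of spatial-approach results with columns
#'   `taxon`, `period`, `pure_E`, `pure_S`, `common` (relative fractions).
#' @param spatiotemporal data.frame of pooled results with columns `taxon`,
#'   `pure_E`, `pure_S`, `ES_given_T` (fractions on any common scale;
#'   renormalization makes the scale irrelevant).
#' @return object of class `approach_comparison`: `values` (per-taxon paired
#'   values) and `tests` (fraction, V, p, n; NA when no informative pairs).
#' @export
compare_approaches <- function(spatial, spatiotemporal) {
  tax_sp <- sort(unique(spatial$taxon))
  tax_st <- sort(unique(spatiotemporal$taxon))
  if (!identical(tax_sp, tax_st))
    stop(sprintf("taxa mismatch between approaches: only in spatial: %s; only in spatio-temporal: %s",
                 paste(setdiff(tax_sp, tax_st), collapse = ",") ,
                 paste(setdiff(tax_st, tax_sp), collapse = ",")))
  sp_mean <- do.call(rbind, lapply(tax_sp, function(tx) {
    sub <- spatial[spatial$taxon == tx, , drop = FALSE]
    data.frame(taxon = tx, pure_E = mean(sub$pure_E, na.rm = TRUE),
               pure_S = mean(sub$pure_S, na.rm = TRUE),
               common = mean(sub$common, na.rm = TRUE))
  }))
  st_sub <- spatiotemporal[match(tax_sp, spatiotemporal$taxon), , drop = FALSE]
  es_mass <- st_sub$pure_E + st_sub$pure_S + st_sub$ES_given_T
  st_rel <- data.frame(taxon = tax_sp,
                       pure_E = ifelse(es_mass > 0, st_sub$pure_E / es_mass, NA),
                       pure_S = ifelse(es_mass > 0, st_sub$pure_S / es_mass, NA),
                       common = ifelse(es_mass > 0, st_sub$ES_given_T / es_mass, NA))
  tests <- do.call(rbind, lapply(c("pure_E", "pure_S", "common"), function(fr) {
    xs <- sp_mean[[fr]]; ys <- st_rel[[fr]]
    ok <- is.finite(xs) & is.finite(ys)
    res <- tryCatch(suppressWarnings(wilcoxon_paired_exact(xs[ok], ys[ok])),
                    error = function(e) NULL)
    if (is.null(res))
      data.frame(fraction = fr, V = NA_real_, p = NA_real_, n = 0L)
    else data.frame(fraction = fr, V = res$V, p = res$p, n = res$n)
  }))
  structure(list(values = list(spatial = sp_mean, spatiotemporal = st_rel),
                 tests = tests),
            class = "approach_comparison")
}

#' @export
print.approach_comparison <- function(x, ...) {
  cat("Spatial vs spatio-temporal approach (paired Wilcoxon across taxa)\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
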