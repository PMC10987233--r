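#' Analysis configuration
#'
#' Collects the tuning parameters of both analysis approaches. Defaults are
#' the package's canonical settings: nine splines per variable (`k = 9`),
#' the first three environmental principal components (`n_pcs = 3`),
#' forward selection at `alpha = 0.05`, a maximum of three predictors in the
#' snapshot models (`max_terms_spatial = 3`, a sample-size constraint at
#' about 30 ponds per period), latent dimension candidates up to
#' `d_max = 5`, and 199 spatially constrained nulls for the environmental
#' correction.
#'
#' @param alpha forward-selection significance threshold.
#' @param k basis dimension per smooth.
#' @param n_pcs environmental principal components used as predictors.
#' @param max_terms_spatial cap on total selected predictors per snapshot
#'   model (environmental + spatial combined).
#' @param d_max largest latent dimension candidate.
#' @param n_null null replicates for the environmental correction.
#' @param n_perm permutations for PERMDISP.
#' @param seed integer seed for every stochastic step.
#' @param correction run the MSR environmental correction (default TRUE).
#' @param n_starts random starts per latent fit.
#' @param min_samples skip a taxon/period slice with fewer samples.
#' @param gamma GCV inflation for the GAM fits.
#' @return object of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, k = 9, n_pcs = 3, max_terms_spatial = 3,
                       d_max = 5, n_null = 199, n_perm = 999, seed = 1,
                       correction = TRUE, n_starts = 3, min_samples = 10,
                       gamma = 1.4) {
  structure(list(alpha = alpha, k = k, n_pcs = n_pcs,
                 max_terms_spatial = max_terms_spatial, d_max = d_max,
                 n_null = n_null, n_perm = n_perm, seed = as.integer(seed),
                 correction = correction, n_starts = n_starts,
                 min_samples = min_samples, gamma = gamma),
            class = "run_config")
}

## per-axis forward selection, then union over axes (ordered by how many
## axes selected each candidate, ties by candidate order), capped
select_terms_union <- function(A, candidates, data, alpha, max_terms, gamma) {
  if (max_terms < 1) return(list(selected = list(), logs = list()))
  nm <- vapply(candidates, function(sp)
    paste0("s(", paste(sp$vars, collapse = ","), ")"), character(1))
  counts <- setNames(numeric(length(candidates)), nm)
  logs <- list()
  for (j in seq_len(ncol(A))) {
    fs <- forward_select(A[, j], candidates, data, alpha = alpha,
                         max_terms = max_terms, gamma = gamma)
    sel_nm <- vapply(fs$selected, function(sp)
      paste0("s(", paste(sp$vars, collapse = ","), ")"), character(1))
    counts[sel_nm] <- counts[sel_nm] + 1
    logs[[j]] <- fs$log
  }
  ord <- order(-counts, seq_along(counts))
  keep <- ord[counts[ord] > 0]
  keep <- keep[seq_len(min(length(keep), max_terms))]
  list(selected = candidates[sort(keep)], logs = logs, counts = counts)
}

prep_period_data <- function(ds, rows, n_pcs) {
  tr <- transform_env(ds$env[rows, , drop = FALSE], ds$env_meta)
  pca <- pca_reduce(tr$env, n_pcs = n_pcs)
  km <- coords_km(ds$sample_frame[rows, , drop = FALSE])
  dat <- data.frame(pca$scores, x_km = km[, 1], y_km = km[, 2],
                    days_since_first = ds$sample_frame$days_since_first[rows])
  list(data = dat, pca = pca, env_transformed = tr$env)
}

partition_row <- function(vp, taxon, period = NA) {
  fr <- vp$fractions
  out <- data.frame(taxon = taxon, period = period, total = vp$total,
                    t(fr), check.names = FALSE)
  cor <- if (!is.null(vp$corrected)) vp$corrected$fractions else fr
  names(cor) <- paste0(names(vp$fractions), "_corrected")
  out <- cbind(out, t(cor),
               data.frame(correction_applied = !is.null(vp$corrected)))
  rel <- vp$relative
  names(rel) <- paste0(names(vp$fractions), "_rel")
  cbind(out, t(rel))
}

#' Run the repeated snapshot ("spatial") analysis
#'
#' For every taxon and sampling period: environmental transform and
#' per-period PCA, AIC-selected latent axes fitted on that period's
#' community slice, forward selection of environmental (PC smooths) and
#' spatial (coordinate smooth) terms per axis with a union over axes, a cap
#' of `max_terms_spatial` predictors in total (environmental selection is
#' re-run tighter if the cap is exceeded), and the two-component partition
#' with optional environmental correction and relative fractions.
#'
#' @param ds a `pond_dataset` (from [simulate_metacommunity()],
#'   [simulate_taxa()] or [read_dataset()]).
#' @param cfg a [run_config()].
#' @param out_dir optional directory for CSV outputs.
#' @return object of class `spatial_run`: `partitions` (one row per taxon x
#'   period), `details` (the `varpart2` objects), `selection_logs`,
#'   `skipped`.
#' @export
run_spatial_approach <- function(ds, cfg = run_config(), out_dir = NULL) {
  stopifnot(inherits(ds, "pond_dataset"))
  occasions <- sort(unique(ds$sample_frame$occasion))
  rows_out <- list(); details <- list(); sel_logs <- list(); skipped <- list()
  for (tx in names(ds$communities)) {
    Y_all <- ds$communities[[tx]]
    for (per in occasions) {
      rows <- which(ds$sample_frame$occasion == per)
      key <- sprintf("%s_period%s", tx, per)
      if (length(rows) < cfg$min_samples) {
        skipped[[key]] <- sprintf("only %d samples", length(rows))
        next
      }
      prep <- prep_period_data(ds, rows, cfg$n_pcs)
      Y <- Y_all[rows, , drop = FALSE]
      axes <- suppressWarnings(
        select_latent_dimension(Y, d_max = cfg$d_max,
                                seed = cfg$seed + 1000 * per,
                                n_starts = cfg$n_starts, taxon = tx))
      A <- axes$scores
      E_cand <- lapply(paste0("PC", seq_len(cfg$n_pcs)), smooth_spec, k = cfg$k)
      S_cand <- list(smooth_spec(c("x_km", "y_km"), k = cfg$k))
      selE <- select_terms_union(A, E_cand, prep$data, cfg$alpha,
                                 max_terms = cfg$max_terms_spatial,
                                 gamma = cfg$gamma)
      selS <- select_terms_union(A, S_cand, prep$data, cfg$alpha,
                                 max_terms = 1, gamma = cfg$gamma)
      nS <- length(selS$selected)
      if (length(selE$selected) + nS > cfg$max_terms_spatial) {
        selE <- select_terms_union(A, E_cand, prep$data, cfg$alpha,
                                   max_terms = cfg$max_terms_spatial - nS,
                                   gamma = cfg$gamma)
      }
      vp <- partition_two(A, selE$selected, selS$selected, prep$data,
                          gamma = cfg$gamma, correction = cfg$correction,
                          env_vars = paste0("PC", seq_len(cfg$n_pcs)),
                          coords = coords_km(ds$sample_frame[rows, , drop = FALSE]),
                          n_null = cfg$n_null, seed = cfg$seed)
      vp <- relative_fractions(vp)
      details[[key]] <- vp
      sel_logs[[key]] <- list(E = selE$logs, S = selS$logs, d = axes$d)
      rows_out[[key]] <- partition_row(vp, tx, per)
    }
  }
  partitions <- if (length(rows_out)) do.call(rbind, rows_out) else NULL
  if (!is.null(partitions)) rownames(partitions) <- NULL
  res <- structure(list(partitions = partitions, details = details,
                        selection_logs = sel_logs, skipped = skipped,
                        cfg = cfg),
                   class = "spatial_run")
  if (!is.null(out_dir)) write_run(res, out_dir, "spatial")
  res
}

#' Run the pooled spatio-temporal analysis
#'
#' All sampling periods are consolidated: one PCA on the pooled
#' environmental table, one latent ordination on the stacked community
#' matrix, environmental and spatial forward selection as in the snapshot
#' analysis plus a temporal smooth of days since each pond's first
#' sampling, and the three-component partition (seven fractions) with the
#' spatio-temporal environmental correction.
#'
#' @inheritParams run_spatial_approach
#' @return object of class `spatiotemporal_run`: `partitions` (one row per
#'   taxon), `details`, `selection_logs`, `skipped`.
#' @export
run_spatiotemporal_approach <- function(ds, cfg = run_config(),
                                        out_dir = NULL) {
  stopifnot(inherits(ds, "pond_dataset"))
  sf <- ds$sample_frame
  rows <- seq_len(nrow(sf))
  prep <- prep_period_data(ds, rows, cfg$n_pcs)
  km <- coords_km(sf)
  pond_index <- as.integer(factor(sf$pond_id, levels = unique(sf$pond_id)))
  occ_index <- as.integer(factor(sf$occasion))
  k_t <- min(cfg$k, length(unique(sf$days_since_first)))
  rows_out <- list(); details <- list(); sel_logs <- list(); skipped <- list()
  for (tx in names(ds$communities)) {
    Y <- ds$communities[[tx]]
    if (nrow(Y) < cfg$min_samples) {
      skipped[[tx]] <- sprintf("only %d samples", nrow(Y))
      next
    }
    axes <- suppressWarnings(
      select_latent_dimension(Y, d_max = cfg$d_max, seed = cfg$seed,
                              n_starts = cfg$n_starts, taxon = tx))
    A <- axes$scores
    E_cand <- lapply(paste0("PC", seq_len(cfg$n_pcs)), smooth_spec, k = cfg$k)
    S_cand <- list(smooth_spec(c("x_km", "y_km"), k = cfg$k))
    T_terms <- if (length(unique(sf$days_since_first)) > 1)
      list(suppressWarnings(smooth_spec("days_since_first",
                                        k = max(3, k_t)))) else list()
    selE <- select_terms_union(A, E_cand, prep$data, cfg$alpha,
                               max_terms = cfg$n_pcs, gamma = cfg$gamma)
    selS <- select_terms_union(A, S_cand, prep$data, cfg$alpha,
                               max_terms = 1, gamma = cfg$gamma)
    vp <- suppressWarnings(partition_three(
      A, selE$selected, selS$selected, T_terms, prep$data,
      gamma = cfg$gamma, correction = cfg$correction,
      env_vars = paste0("PC", seq_len(cfg$n_pcs)),
      coords = km, occasions = occ_index, pond_index = pond_index,
      n_null = cfg$n_null, seed = cfg$seed))
    vp <- relative_fractions(vp)
    details[[tx]] <- vp
    sel_logs[[tx]] <- list(E = selE$logs, S = selS$logs, d = axes$d)
    rows_out[[tx]] <- partition_row(vp, tx)
  }
  partitions <- if (length(rows_out)) do.call(rbind, rows_out) else NULL
  if (!is.null(partitions)) rownames(partitions) <- NULL
  res <- structure(list(partitions = partitions, details = details,
                        selection_logs = sel_logs, skipped = skipped,
                        cfg = cfg),
                   class = "spatiotemporal_run")
  if (!is.null(out_dir)) write_run(res, out_dir, "spatiotemporal")
  res
}

#' Run both approaches and compare them
#'
#' Convenience driver: runs [run_spatial_approach()] and
#' [run_spatiotemporal_approach()] on the same dataset, compares their
#' relative environmental/spatial fractions with paired exact Wilcoxon
#' tests ([compare_approaches()]), and computes PERMDISP heterogeneity
#' contrasts between sampling periods for all variables and for the
#' climatic and limnological subsets separately.
#'
#' @inheritParams run_spatial_approach
#' @return list with `spatial`, `spatiotemporal`, `comparison`, `permdisp`.
#' @export
run_both_approaches <- function(ds, cfg = run_config(), out_dir = NULL) {
  sp <- run_spatial_approach(ds, cfg, out_dir = out_dir)
  st <- run_spatiotemporal_approach(ds, cfg, out_dir = out_dir)
  comparison <- NULL
  if (!is.null(sp$partitions) && !is.null(st$partitions)) {
    sp_rel <- data.frame(taxon = sp$partitions$taxon,
                         period = sp$partitions$period,
                         pure_E = sp$partitions$pure_E_rel,
                         pure_S = sp$partitions$pure_S_rel,
                         common = sp$partitions$common_rel)
    st_rel <- data.frame(taxon = st$partitions$taxon,
                         pure_E = st$partitions$pure_E_rel,
                         pure_S = st$partitions$pure_S_rel,
                         ES_given_T = st$partitions$ES_given_T_rel)
    comparison <- tryCatch(compare_approaches(sp_rel, st_rel),
                           error = function(e) e$message)
  }
  pd <- permdisp_by_class(ds, cfg)
  out <- list(spatial = sp, spatiotemporal = st, comparison = comparison,
              permdisp = pd)
  if (!is.null(out_dir)) {
    if (!is.null(comparison) && inherits(comparison, "approach_comparison"))
      utils::write.csv(comparison$tests,
                       file.path(out_dir, "wilcoxon_results.csv"),
                       row.names = FALSE)
    utils::write.csv(pd, file.path(out_dir, "permdisp_results.csv"),
                     row.names = FALSE)
    prov <- list(config = unclass(cfg), package_version =
                   as.character(utils::packageVersion("pondvarpart")))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

## PERMDISP between sampling periods for all / climatic / limnological
## variable subsets (disjoint classes whose union is all variables)
permdisp_by_class <- function(ds, cfg) {
  tr <- transform_env(ds$env, ds$env_meta)
  cls <- ds$env_meta$class
  stopifnot(all(cls %in% c("climatic", "limnological")))
  groups <- factor(ds$sample_frame$occasion)
  sets <- list(all = seq_along(cls),
               climatic = which(cls == "climatic"),
               limnological = which(cls == "limnological"))
  out <- list()
  for (nm in names(sets)) {
    idx <- sets[[nm]]
    if (length(idx) < 2 || nlevels(groups) < 2) next
    pd <- permdisp(tr$env[, idx, drop = FALSE], groups,
                   n_perm = cfg$n_perm, seed = cfg$seed)
    out[[nm]] <- data.frame(variable_class = nm, contrast = "between periods",
                            F = pd$F, p = pd$p, n_perm = pd$n_perm)
  }
  do.call(rbind, out)
}

write_run <- function(res, out_dir, prefix) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(res$partitions))
    utils::write.csv(res$partitions,
                     file.path(out_dir, sprintf("partition_%s.csv", prefix)),
                     row.names = FALSE)
  invisible(NULL)
}

#' @export
print.spatial_run <- function(x, ...) {
  cat("Snapshot (spatial) variation partitioning run\n")
  if (!is.null(x$partitions))
    print(x$partitions[, c("taxon", "period", "total", "pure_E", "pure_S",
                           "common")], row.names = FALSE, digits = 3)
  if (length(x$skipped)) cat(sprintf("  skipped: %d slice(s)\n",
                                     length(x$skipped)))
  invisible(x)
}

#' @export
print.spatiotemporal_run <- function(x, ...) {
  cat("Pooled spatio-temporal variation partitioning run\n")
  if (!is.null(x$partitions))
    print(x$partitions[, c("taxon", "total", "pure_E", "pure_S", "pure_T")],
          row.names = FALSE, digits = 3)
  invisible(x)
}
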