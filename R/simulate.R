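#' Configuration for a synthetic metacommunity
#'
#' Bundles every knob of the simulator into a validated list. Defaults emulate
#' the sampling design the package targets: roughly 30 temporary ponds
#' surveyed three times over one hydroperiod (early / mid / late), with a
#' mixed set of climatic variables (constant within a pond over the
#' hydroperiod) and limnological variables (varying between occasions), and
#' species occupancy driven by environmental, residual-spatial and temporal
#' components of configurable strength.
#'
#' @param n_ponds number of ponds (default 30).
#' @param n_occasions number of sampling occasions per pond (default 3).
#' @param n_species number of species in the community matrix (default 60).
#' @param occasion_days days since the first sampling for each occasion;
#'   strictly increasing, first entry 0. Default `c(0, 150, 250)`, matching a
#'   hydroperiod sampled at its early, mid and late stages.
#' @param region_extent_km side of the planar square over which ponds are
#'   scattered, in km (default 120, i.e. about a 1.4e4 km2 region).
#' @param n_climatic,n_limnological number of climatic / limnological
#'   environmental variables.
#' @param beta_E,beta_S,beta_T non-negative effect sizes scaling the
#'   environmental, residual-spatial and temporal components of the occupancy
#'   linear predictor. Each component is standardized to unit variance across
#'   samples before scaling, so the betas are directly comparable.
#' @param env_spatial_range_km range (in km) of the exponential spatial
#'   correlation of the spatially structured share of the environment.
#' @param env_spatial_weight proportion (in sd units) of each environmental
#'   variable that follows the spatial field rather than independent noise.
#' @param occasion_shift_sd sd of the occasion-specific shifts added to
#'   limnological variables (0 makes them constant within ponds).
#' @param response_type `"linear"` (random linear combination of variables)
#'   or `"unimodal"` (Gaussian response curve along the first variable) for
#'   the species-environment response `f_s`.
#' @param n_spatial_fields number of shared latent spatial fields from which
#'   species residual-spatial components are built.
#' @param intercept_mean,intercept_sd distribution of species intercepts
#'   `a_s` on the logit scale.
#' @param seed integer seed; the same config and seed reproduce the dataset
#'   bit for bit.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_metacommunity()]
#' @export
sim_config <- function(n_ponds = 30, n_occasions = 3, n_species = 60,
                       occasion_days = c(0, 150, 250),
                       region_extent_km = 120,
                       n_climatic = 4, n_limnological = 6,
                       beta_E = 1, beta_S = 1, beta_T = 1,
                       env_spatial_range_km = 30,
                       env_spatial_weight = 0.7,
                       occasion_shift_sd = 0.5,
                       response_type = c("linear", "unimodal"),
                       n_spatial_fields = 2,
                       intercept_mean = -0.5, intercept_sd = 0.5,
                       seed = 1L) {
  response_type <- match.arg(response_type)
  stopifnot(n_ponds >= 1, n_occasions >= 1, n_species >= 1,
            n_climatic >= 1, n_limnological >= 0,
            region_extent_km > 0, env_spatial_range_km > 0,
            env_spatial_weight >= 0, env_spatial_weight <= 1,
            n_spatial_fields >= 1)
  if (length(occasion_days) != n_occasions)
    stop("occasion_days must have one entry per occasion")
  if (occasion_days[1] != 0)
    stop("occasion_days must start at 0 (days since first sampling)")
  if (n_occasions > 1 && any(diff(occasion_days) <= 0))
    stop("occasion_days must be strictly increasing")
  if (beta_E < 0 || beta_S < 0 || beta_T < 0)
    stop("effect sizes beta_E, beta_S, beta_T must be non-negative")
  cfg <- list(n_ponds = as.integer(n_ponds),
              n_occasions = as.integer(n_occasions),
              n_species = as.integer(n_species),
              occasion_days = as.numeric(occasion_days),
              region_extent_km = region_extent_km,
              n_climatic = as.integer(n_climatic),
              n_limnological = as.integer(n_limnological),
              beta_E = beta_E, beta_S = beta_S, beta_T = beta_T,
              env_spatial_range_km = env_spatial_range_km,
              env_spatial_weight = env_spatial_weight,
              occasion_shift_sd = occasion_shift_sd,
              response_type = response_type,
              n_spatial_fields = as.integer(n_spatial_fields),
              intercept_mean = intercept_mean,
              intercept_sd = intercept_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

## exact Gaussian random field over <= a few dozen points: Cholesky of the
## exponential covariance exp(-h / range), with a small jitter for rank safety
grf_exp <- function(coords, range_km, n_draws = 1) {
  h <- as.matrix(stats::dist(coords))
  C <- exp(-h / range_km)
  diag(C) <- diag(C) + 1e-8
  L <- chol(C)
  t(L) %*% matrix(stats::rnorm(nrow(coords) * n_draws), nrow(coords), n_draws)
}

unit_scale <- function(x) {
  s <- stats::sd(x)
  if (s < 1e-12) x - mean(x) else (x - mean(x)) / s
}

#' Simulate a metacommunity with known structure
#'
#' Ponds are placed uniformly at random in a planar square. Environmental
#' variables are Gaussian random fields over the pond coordinates (exponential
#' covariance, range `env_spatial_range_km`) blended with independent noise;
#' limnological variables additionally receive occasion-specific shifts.
#' Species occupancy at sample i follows
#' \deqn{P(y_{is} = 1) = \mathrm{logit}^{-1}(a_s + \beta_E f_s(env_i) +
#'   \beta_S u_s(x_i, y_i) + \beta_T g_s(t_i))}
#' where `f_s` is a linear or unimodal environmental response, `u_s` a
#' species-specific mixture of shared smooth spatial fields, and `g_s` a
#' species-scaled half-sine trend over the hydroperiod (mimicking
#' succession). All generating components are stored in `$truth` so recovery
#' can be tested.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `pond_dataset`: a list with `sample_frame`
#'   (one row per pond x occasion: sample_id, pond_id, occasion, longitude,
#'   latitude, x_km, y_km, days_since_first), `env` (data.frame of raw
#'   environmental variables), `env_meta` (variable, class, transform),
#'   `communities` (named list with one binary matrix), and `truth`.
#' @examples
#' ds <- simulate_metacommunity(sim_config(n_ponds = 10, n_species = 12))
#' dim(ds$communities[[1]])
#' @export
simulate_metacommunity <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  P <- cfg$n_ponds; Tn <- cfg$n_occasions; m <- cfg$n_species
  n <- P * Tn

  coords <- cbind(x_km = stats::runif(P, 0, cfg$region_extent_km),
                  y_km = stats::runif(P, 0, cfg$region_extent_km))

  ## geographic coordinates consistent with the planar km under an
  ## equirectangular projection about a fixed Mediterranean-like origin
  lat0 <- 39.5; lon0 <- -0.6
  lat <- lat0 + coords[, "y_km"] / 110.574
  lon <- lon0 + coords[, "x_km"] / (111.320 * cos(lat0 * pi / 180))

  pond_id <- sprintf("pond%02d", seq_len(P))
  sample_frame <- data.frame(
    sample_id = sprintf("%s_t%d", rep(pond_id, Tn), rep(seq_len(Tn), each = P)),
    pond_id = rep(pond_id, Tn),
    occasion = rep(seq_len(Tn), each = P),
    longitude = rep(lon, Tn),
    latitude = rep(lat, Tn),
    x_km = rep(coords[, "x_km"], Tn),
    y_km = rep(coords[, "y_km"], Tn),
    days_since_first = rep(cfg$occasion_days, each = P),
    stringsAsFactors = FALSE)

  ## --- environment: spatially structured share + independent pond noise ---
  nv <- cfg$n_climatic + cfg$n_limnological
  vclass <- c(rep("climatic", cfg$n_climatic), rep("limnological", cfg$n_limnological))
  vname <- c(sprintf("clim%02d", seq_len(cfg$n_climatic)),
             if (cfg$n_limnological > 0) sprintf("limn%02d", seq_len(cfg$n_limnological)))
  w <- cfg$env_spatial_weight
  spat <- grf_exp(coords, cfg$env_spatial_range_km, nv)
  pond_env <- sqrt(w) * spat + sqrt(1 - w) *
    matrix(stats::rnorm(P * nv), P, nv)
  env <- pond_env[rep(seq_len(P), Tn), , drop = FALSE]
  if (cfg$n_limnological > 0 && Tn > 1) {
    lim <- which(vclass == "limnological")
    shift <- matrix(stats::rnorm(Tn * length(lim), 0, cfg$occasion_shift_sd),
                    Tn, length(lim))
    shift[1, ] <- 0  # first occasion is the baseline
    eps <- matrix(stats::rnorm(n * length(lim), 0, 0.5 * cfg$occasion_shift_sd),
                  n, length(lim))
    env[, lim] <- env[, lim] + shift[sample_frame$occasion, , drop = FALSE] + eps
  }
  colnames(env) <- vname

  drawn <- draw_community(cfg, sample_frame, coords, env)

  env <- as.data.frame(env)
  rownames(env) <- sample_frame$sample_id
  env_meta <- data.frame(variable = vname, class = vclass,
                         transform = "none", stringsAsFactors = FALSE)

  structure(list(
    sample_frame = sample_frame,
    env = env,
    env_meta = env_meta,
    communities = list(taxon1 = drawn$Y),
    truth = c(list(config = cfg, coords = coords), drawn$truth)),
    class = "pond_dataset")
}

## draw one taxon's community on a fixed pond layout and environment;
## consumes the current RNG stream
draw_community <- function(cfg, sample_frame, coords, env) {
  P <- cfg$n_ponds; Tn <- cfg$n_occasions; m <- cfg$n_species
  n <- P * Tn
  nv <- ncol(env)
  env_std <- scale(as.matrix(env))
  env_std[, apply(as.matrix(env), 2, stats::sd) < 1e-12] <- 0
  if (cfg$response_type == "linear") {
    env_coef <- matrix(stats::rnorm(nv * m), nv, m)
    f_mat <- env_std %*% env_coef
  } else {
    opt <- stats::rnorm(m, 0, 1); wid <- stats::runif(m, 0.5, 1.5)
    f_mat <- sapply(seq_len(m), function(s)
      exp(-(env_std[, 1] - opt[s])^2 / (2 * wid[s]^2)))
    env_coef <- rbind(opt, wid)
  }
  f_mat <- apply(f_mat, 2, unit_scale)

  U <- grf_exp(coords, cfg$region_extent_km / 4, cfg$n_spatial_fields)
  load_S <- matrix(stats::rnorm(cfg$n_spatial_fields * m), cfg$n_spatial_fields, m)
  u_mat <- apply(U[rep(seq_len(P), Tn), , drop = FALSE] %*% load_S, 2, unit_scale)

  tmax <- max(cfg$occasion_days)
  Gt <- if (tmax > 0) sin(pi * sample_frame$days_since_first / tmax) else
    rep(0, n)
  load_T <- stats::rnorm(m)
  g_mat <- apply(outer(Gt, load_T), 2, unit_scale)

  a_s <- stats::rnorm(m, cfg$intercept_mean, cfg$intercept_sd)
  eta <- matrix(a_s, n, m, byrow = TRUE) +
    cfg$beta_E * f_mat + cfg$beta_S * u_mat + cfg$beta_T * g_mat
  if (!all(is.finite(eta)))
    stop("non-finite occupancy linear predictor; check effect sizes and config")
  prob <- stats::plogis(eta)
  Y <- matrix(stats::rbinom(n * m, 1, prob), n, m)
  dimnames(Y) <- list(sample_frame$sample_id, sprintf("sp%03d", seq_len(m)))
  list(Y = Y,
       truth = list(intercepts = a_s, env_coef = env_coef, f_mat = f_mat,
                    u_mat = u_mat, g_mat = g_mat, spatial_fields = U,
                    temporal_basis = Gt, prob = prob))
}

#' Simulate several taxa over one pond network
#'
#' Draws `n_taxa` independent community matrices (default 7, mirroring the
#' major freshwater groups a multi-taxon pond survey follows: bacteria,
#' archaea, phytoplankton, rotifers, microcrustaceans, macroinvertebrates,
#' amphibians) over a single shared pond network and environment. Taxon
#' communities use seeds derived from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param n_taxa number of taxa (default 7).
#' @param taxa optional character vector of taxon names.
#' @return a `pond_dataset` whose `communities` holds one matrix per taxon
#'   and whose `truth$taxa` holds per-taxon truth records.
#' @export
simulate_taxa <- function(config = sim_config(), n_taxa = 7, taxa = NULL) {
  if (is.null(taxa))
    taxa <- c("bacteria", "archaea", "phytoplankton", "rotifers",
              "microcrustaceans", "macroinvertebrates", "amphibians")[seq_len(n_taxa)]
  stopifnot(length(taxa) == n_taxa)
  base <- simulate_metacommunity(config)
  ## redraw each taxon's community on the shared pond network and environment
  set.seed(config$seed)
  sub_seeds <- sample.int(2^30, n_taxa)
  communities <- list(); truths <- list()
  for (i in seq_len(n_taxa)) {
    set.seed(sub_seeds[i])
    drawn <- draw_community(config, base$sample_frame, base$truth$coords,
                            base$env)
    communities[[taxa[i]]] <- drawn$Y
    truths[[taxa[i]]] <- drawn$truth
  }
  base$communities <- communities
  base$truth$taxa <- truths
  base
}

#' Write a dataset to the CSV layout the pipeline reads
#'
#' Emits `samples.csv`, `env.csv`, `env_meta.csv` and one
#' `community_<taxon>.csv` per taxon (binary matrix; first column
#' `sample_id`, header row of species IDs). UTF-8, comma separated, '.'
#' decimal. Round-trips losslessly through [read_dataset()].
#'
#' @param ds a `pond_dataset`.
#' @param directory output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(ds, directory) {
  stopifnot(inherits(ds, "pond_dataset"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(directory, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(ds$sample_frame, "samples.csv")
  wr(cbind(sample_id = rownames(ds$env), ds$env), "env.csv")
  wr(ds$env_meta, "env_meta.csv")
  for (tx in names(ds$communities)) {
    Y <- ds$communities[[tx]]
    wr(cbind(sample_id = rownames(Y), as.data.frame(Y)),
       sprintf("community_%s.csv", tx))
  }
  invisible(files)
}

#' Read a dataset from the CSV layout
#'
#' Inverse of [write_dataset()]; `truth` is not stored on disk and comes back
#' `NULL`.
#'
#' @param directory directory holding `samples.csv`, `env.csv`,
#'   `env_meta.csv` and `community_*.csv`.
#' @return a `pond_dataset`.
#' @export
read_dataset <- function(directory) {
  rd <- function(name) utils::read.csv(file.path(directory, name),
                                       stringsAsFactors = FALSE)
  sample_frame <- rd("samples.csv")
  env <- rd("env.csv")
  rownames(env) <- env$sample_id
  env$sample_id <- NULL
  env_meta <- rd("env_meta.csv")
  comm_files <- list.files(directory, "^community_.*\\.csv$")
  communities <- list()
  for (f in comm_files) {
    tx <- sub("^community_(.*)\\.csv$", "\\1", f)
    df <- rd(f)
    Y <- as.matrix(df[, -1, drop = FALSE])
    rownames(Y) <- df[[1]]
    storage.mode(Y) <- "integer"
    communities[[tx]] <- Y
  }
  structure(list(sample_frame = sample_frame, env = env, env_meta = env_meta,
                 communities = communities, truth = NULL),
            class = "pond_dataset")
}

#' @export
print.pond_dataset <- function(x, ...) {
  sf <- x$sample_frame
  cat("Pond metacommunity dataset\n")
  cat(sprintf("  %d samples (%d ponds x %d occasions)\n",
              nrow(sf), length(unique(sf$pond_id)),
              length(unique(sf$occasion))))
  cat(sprintf("  %d environmental variables (%d climatic, %d limnological)\n",
              ncol(x$env), sum(x$env_meta$class == "climatic"),
              sum(x$env_meta$class == "limnological")))
  cat(sprintf("  taxa: %s\n", paste(sprintf("%s (%d spp)",
              names(x$communities), vapply(x$communities, ncol, 0L)),
              collapse = ", ")))
  invisible(x)
}

## planar coordinates in km for any sample frame: trust x_km/y_km when the
## simulator provided them, otherwise equirectangular projection about the
## centroid (fine at ~100 km extents)
coords_km <- function(sample_frame) {
  if (all(c("x_km", "y_km") %in% names(sample_frame)))
    return(cbind(x_km = sample_frame$x_km, y_km = sample_frame$y_km))
  lat0 <- mean(sample_frame$latitude)
  cbind(x_km = (sample_frame$longitude - mean(sample_frame$longitude)) *
          111.320 * cos(lat0 * pi / 180),
        y_km = (sample_frame$latitude - lat0) * 110.574)
}
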