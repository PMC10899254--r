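#' Configuration for the synthetic world generator
#'
#' Describes an abstract global lattice of grid cells with ten predictor
#' covariates and a known MBC-generating model in which the spatial
#' MBC-temperature gradient (`spatial_slope_true`) and the true temporal
#' temperature sensitivity (`temporal_sensitivity_true`) are independent,
#' separately controllable parameters. The grid carries 22 annual
#' temperature layers for 1992-2013 with a linear warming trend totalling
#' `warming_1992_2013` degrees; all other predictors are static. The true
#' MBC trajectory of every cell responds to time only through
#' `temporal_sensitivity_true`, so a world with
#' `temporal_sensitivity_true = 0` has, by construction, no temporal MBC
#' change at all - any predicted change is a space-for-time artifact.
#'
#' The nine continuous predictors are driven by correlated standard-normal
#' latents. By default temperature is correlated with precipitation, NDVI
#' and elevation (which carry no direct MBC effect), while the predictors
#' with direct MBC effects (SOC, nitrogen, clay, pH) are uncorrelated with
#' temperature, so `spatial_slope_true` is both the direct and the marginal
#' MBC-temperature gradient and the two sensitivities are separately
#' identifiable. Land cover is an independent categorical predictor entering
#' as a class offset.
#'
#' @param n_cells number of grid cells.
#' @param n_obs number of spatial MBC observations sampled from the grid
#'   (default 762, the scale of the global compilation being emulated).
#' @param spatial_slope_true spatial MBC-temperature gradient,
#'   mmol kg-1 per deg C (sign-controllable; negative emulates the observed
#'   global decline of MBC with temperature).
#' @param temporal_sensitivity_true true temporal response of cell MBC to
#'   its own temperature anomaly, mmol kg-1 per deg C (may be 0).
#' @param warming_1992_2013 total linear warming over 1992-2013, deg C.
#' @param noise_sd residual SD of cell MBC, mmol kg-1.
#' @param mbc_intercept MBC at the temperature origin before covariate and
#'   land-cover contributions, mmol kg-1.
#' @param predictor_cor optional 9 x 9 correlation matrix for the continuous
#'   predictor latents (order: temperature, soc, ph, precipitation, clay,
#'   sand, nitrogen, ndvi, elevation); `NULL` uses the default described
#'   above.
#' @param temp_anomaly_sd SD of cell-level interannual temperature
#'   anomalies around the warming trend, deg C (default 0: pure trend).
#' @param seed integer seed.
#' @return object of class `world_sim_config`.
#' @export
world_sim_config <- function(n_cells = 2000L, n_obs = 762L,
                             spatial_slope_true = -8,
                             temporal_sensitivity_true = 0,
                             warming_1992_2013 = 0.28,
                             noise_sd = 40,
                             mbc_intercept = 250,
                             predictor_cor = NULL,
                             temp_anomaly_sd = 0,
                             seed = 1L) {
  if (n_obs > n_cells) stop("n_obs must not exceed n_cells")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (temp_anomaly_sd < 0) stop("temp_anomaly_sd must be >= 0")
  if (!is.null(predictor_cor)) {
    stopifnot(is.matrix(predictor_cor), all(dim(predictor_cor) == 9L))
    if (any(eigen(predictor_cor, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("predictor_cor must be positive definite")
  }
  structure(list(n_cells = as.integer(n_cells), n_obs = as.integer(n_obs),
                 spatial_slope_true = spatial_slope_true,
                 temporal_sensitivity_true = temporal_sensitivity_true,
                 warming_1992_2013 = warming_1992_2013,
                 noise_sd = noise_sd, mbc_intercept = mbc_intercept,
                 predictor_cor = predictor_cor,
                 temp_anomaly_sd = temp_anomaly_sd,
                 seed = as.integer(seed)),
            class = "world_sim_config")
}

# predictor latent order and default correlation structure
.latent_names <- c("temperature", "soc", "ph", "precipitation", "clay",
                   "sand", "nitrogen", "ndvi", "elevation")

.default_predictor_cor <- function() {
  R <- diag(9)
  dimnames(R) <- list(.latent_names, .latent_names)
  set2 <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set2("temperature", "precipitation", 0.5)
  set2("temperature", "ndvi", 0.4)
  set2("temperature", "elevation", -0.4)
  set2("precipitation", "ndvi", 0.5)
  set2("soc", "nitrogen", 0.6)
  set2("clay", "sand", -0.5)
  R
}

.land_cover_levels <- c("forest", "grassland", "shrubland", "cropland", "bare")
.land_cover_probs <- c(0.30, 0.25, 0.15, 0.20, 0.10)
.land_cover_offsets <- c(forest = 20, grassland = 10, shrubland = 0,
                         cropland = -5, bare = -25)
# direct MBC contributions per unit latent (orthogonal to temperature by
# default, so the marginal MBC-temperature slope equals spatial_slope_true)
.latent_betas <- c(soc = 12, nitrogen = 8, clay = 5, ph = -6)

# draw n cells: latents -> transformed predictors -> true baseline MBC,
# with the temperature coefficient overridable (for flatter extra data)
.draw_cells <- function(cfg, n, slope) {
  R <- if (is.null(cfg$predictor_cor)) .default_predictor_cor() else cfg$predictor_cor
  L <- chol(R)
  z <- matrix(rnorm(n * 9L), n, 9L) %*% L
  colnames(z) <- .latent_names

  u_clay <- exp(0.8 * z[, "clay"])
  u_sand <- exp(0.8 * z[, "sand"])
  lc <- factor(sample(.land_cover_levels, n, replace = TRUE,
                      prob = .land_cover_probs), levels = .land_cover_levels)
  cells <- data.frame(
    temperature   = 9 + 7 * z[, "temperature"],
    soc           = exp(2.8 + 0.5 * z[, "soc"]),
    ph            = 3.5 + 5.5 * pnorm(z[, "ph"]),
    precipitation = exp(6.6 + 0.6 * z[, "precipitation"]),
    clay          = 100 * u_clay / (u_clay + u_sand + 1),
    sand          = 100 * u_sand / (u_clay + u_sand + 1),
    land_cover    = lc,
    nitrogen      = exp(0.4 + 0.5 * z[, "nitrogen"]),
    ndvi          = pnorm(z[, "ndvi"]),
    elevation     = pmax(0, 800 + 600 * z[, "elevation"]))

  mbc <- cfg$mbc_intercept + slope * cells$temperature +
    z[, names(.latent_betas)] %*% .latent_betas +
    unname(.land_cover_offsets[as.character(lc)]) +
    rnorm(n, 0, cfg$noise_sd)
  cells$mbc_true <- pmax(as.numeric(mbc), 1)
  cells
}

#' Generate a synthetic world: spatial MBC observations plus a warming grid
#'
#' Builds the grid cells, samples `n_obs` cells (without replacement) as the
#' spatial observation set at the 1992 baseline, and constructs 22 annual
#' temperature layers with a linear warming trend. The generating truth
#' (per-cell baseline MBC, baseline temperature, the two sensitivities) is
#' stored in the grid for parameter-recovery checks.
#'
#' @param cfg a [world_sim_config()].
#' @return list with elements `observations` (data frame: `cell_id`, `mbc`,
#'   ten predictor columns) and `grid` (class `world_grid`: `cells` with
#'   static predictors and area weights, `temperature` matrix
#'   n_cells x 22 years, `years`, and `truth`).
#' @export
generate_world <- function(cfg) {
  stopifnot(inherits(cfg, "world_sim_config"))
  set.seed(cfg$seed)
  cells <- .draw_cells(cfg, cfg$n_cells, cfg$spatial_slope_true)
  years <- 1992:2013
  trend <- cfg$warming_1992_2013 * (years - years[1L]) / (years[length(years)] - years[1L])
  temp <- outer(cells$temperature, rep(1, length(years))) +
    outer(rep(1, cfg$n_cells), trend)
  if (cfg$temp_anomaly_sd > 0)
    temp <- temp + matrix(rnorm(length(temp), 0, cfg$temp_anomaly_sd),
                          nrow = cfg$n_cells)
  colnames(temp) <- years

  static <- cells[, setdiff(names(cells), c("temperature", "mbc_true"))]
  grid <- structure(list(
    cells = cbind(data.frame(cell_id = seq_len(cfg$n_cells), area = 1), static),
    temperature = temp,
    years = years,
    truth = list(mbc0 = cells$mbc_true,
                 temp_base = cells$temperature,
                 spatial_slope = cfg$spatial_slope_true,
                 temporal_sensitivity = cfg$temporal_sensitivity_true,
                 config = cfg)),
    class = "world_grid")

  idx <- sample(cfg$n_cells, cfg$n_obs)
  obs <- cbind(data.frame(cell_id = idx, mbc = cells$mbc_true[idx]),
               cells[idx, c("temperature", "soc", "ph", "precipitation",
                            "clay", "sand", "land_cover", "nitrogen",
                            "ndvi", "elevation")])
  rownames(obs) <- NULL
  list(observations = obs, grid = grid)
}

#' True global MBC series of a synthetic world
#'
#' Area-weighted annual totals of the generating truth: cell MBC responds to
#' time only through the configured temporal sensitivity applied to the
#' cell's temperature anomaly. With `temporal_sensitivity_true = 0` the
#' series is exactly constant.
#'
#' @param grid a `world_grid` from [generate_world()].
#' @return named numeric vector of 22 annual true global MBC totals.
#' @export
true_global_series <- function(grid) {
  stopifnot(inherits(grid, "world_grid"))
  tr <- grid$truth
  anomaly <- grid$temperature - tr$temp_base
  totals <- colSums(grid$cells$area * (tr$mbc0 + tr$temporal_sensitivity * anomaly))
  setNames(totals, colnames(grid$temperature))
}

#' Extra spatial observations from a flatter MBC-temperature relationship
#'
#' Draws `n` additional observations whose predictors follow the same
#' distribution as the world's cells but whose MBC is generated with a
#' different (typically flatter) temperature slope. Used to emulate
#' augmenting a spatial compilation with independent field-control
#' measurements that do not share its steep spatial temperature gradient.
#'
#' @param cfg the [world_sim_config()] of the world being augmented.
#' @param n number of extra observations (e.g. 106).
#' @param spatial_slope temperature slope of the extra data,
#'   mmol kg-1 per deg C (default 0: no spatial temperature gradient).
#' @param seed integer seed (independent of the world's seed).
#' @return data frame in the same format as `generate_world()$observations`
#'   (with `cell_id = NA`: these points are not grid cells).
#' @export
generate_extra_observations <- function(cfg, n = 106L, spatial_slope = 0,
                                        seed = 1L) {
  stopifnot(inherits(cfg, "world_sim_config"), n >= 1L)
  set.seed(seed)
  cells <- .draw_cells(cfg, n, spatial_slope)
  out <- cbind(data.frame(cell_id = NA_integer_, mbc = cells$mbc_true),
               cells[, c("temperature", "soc", "ph", "precipitation", "clay",
                         "sand", "land_cover", "nitrogen", "ndvi", "elevation")])
  rownames(out) <- NULL
  out
}
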