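#' Read and write paired warming-experiment records
#'
#' Plain-CSV adapters for the paired warming/control record table. The
#' header must contain `mbc_warmed` and `mbc_control`; dispersion columns
#' (`sd_warmed`, `sd_control`, `n_warmed`, `n_control`) and metadata
#' (`warming_magnitude`, `duration`, identifiers, coordinates) are optional
#' and carried through.
#'
#' @param path CSV file path.
#' @param records data frame of records.
#' @return `read_effect_records()` returns the validated data frame.
#' @export
read_effect_records <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("mbc_warmed", "mbc_control")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0L)
    stop("effect-record CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!(rec$mbc_warmed > 0 & rec$mbc_control > 0)))
    stop("effect-record CSV contains nonpositive MBC means")
  rec
}

#' @rdname read_effect_records
#' @export
write_effect_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read and write long-term site series
#'
#' @param path CSV file path; the header must contain `site_id`, `year`,
#'   `mbc`, `temp`.
#' @param data stacked site-series data frame.
#' @export
read_site_series <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "year", "mbc", "temp")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L)
    stop("site-series CSV is missing column(s): ", paste(miss, collapse = ", "))
  d
}

#' @rdname read_site_series
#' @export
write_site_series <- function(data, path) {
  stopifnot(is.data.frame(data))
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Write and read a synthetic world as plain CSV plus a manifest
#'
#' `write_world()` emits `observations.csv`, `grid_cells.csv` (static
#' predictors, area weights, and the generating truth columns `mbc0_true`
#' and `temp_base`), `grid_temperature.csv` (long format: `cell_id`, `year`,
#' `temperature`), and `manifest.yml` recording the generator configuration
#' and seed. `read_world()` reconstructs the `world_grid` and observation
#' table from such a directory.
#'
#' @param world list from [generate_world()].
#' @param dir output directory (created if absent).
#' @export
write_world <- function(world, dir) {
  stopifnot(is.list(world), inherits(world$grid, "world_grid"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- world$grid
  write.csv(world$observations, file.path(dir, "observations.csv"),
            row.names = FALSE)
  cells <- grid$cells
  cells$mbc0_true <- grid$truth$mbc0
  cells$temp_base <- grid$truth$temp_base
  write.csv(cells, file.path(dir, "grid_cells.csv"), row.names = FALSE)
  longt <- data.frame(cell_id = rep(grid$cells$cell_id, length(grid$years)),
                      year = rep(grid$years, each = nrow(grid$cells)),
                      temperature = as.vector(grid$temperature))
  write.csv(longt, file.path(dir, "grid_temperature.csv"), row.names = FALSE)
  cfg <- grid$truth$config
  manifest <- list(
    config = lapply(unclass(cfg)[setdiff(names(unclass(cfg)), "predictor_cor")],
                    function(x) if (is.numeric(x)) as.vector(x) else x),
    spatial_slope = grid$truth$spatial_slope,
    temporal_sensitivity = grid$truth$temporal_sensitivity)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' @rdname write_world
#' @export
read_world <- function(dir) {
  obs <- read.csv(file.path(dir, "observations.csv"), stringsAsFactors = FALSE)
  cells <- read.csv(file.path(dir, "grid_cells.csv"), stringsAsFactors = FALSE)
  longt <- read.csv(file.path(dir, "grid_temperature.csv"))
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yml"))
  obs$land_cover <- factor(obs$land_cover, levels = .land_cover_levels)
  cells$land_cover <- factor(cells$land_cover, levels = .land_cover_levels)
  years <- sort(unique(longt$year))
  temp <- matrix(NA_real_, nrow(cells), length(years),
                 dimnames = list(NULL, years))
  temp[cbind(match(longt$cell_id, cells$cell_id),
             match(longt$year, years))] <- longt$temperature
  truth <- list(mbc0 = cells$mbc0_true, temp_base = cells$temp_base,
                spatial_slope = manifest$spatial_slope,
                temporal_sensitivity = manifest$temporal_sensitivity,
                config = manifest$config)
  cells$mbc0_true <- NULL
  cells$temp_base <- NULL
  grid <- structure(list(cells = cells, temperature = temp, years = years,
                         truth = truth), class = "world_grid")
  list(observations = obs, grid = grid)
}

#' Forest-plot data for effects and their subgroup pools
#'
#' Stacks the per-study effects (yi, si, label) with one pooled row per
#' poolable bin, ready for plotting or CSV export.
#'
#' @param effects data frame with `yi`, `vi` and the moderator column.
#' @param bins a [bin_spec()].
#' @param by moderator column name.
#' @return data frame with columns `label`, `bin`, `yi`, `si`, `pooled`.
#' @export
forest_plot_data <- function(effects, bins = warming_bins(),
                             by = "warming_magnitude") {
  sub <- subgroup_analysis(effects, bins, by = by)
  grp <- assign_bins(effects[[by]], bins)
  studies <- data.frame(
    label = if ("study_id" %in% names(effects)) effects$study_id
            else sprintf("study %d", seq_len(nrow(effects))),
    bin = as.character(grp), yi = effects$yi, si = sqrt(effects$vi),
    pooled = FALSE)
  pooled <- sub[sub$poolable, , drop = FALSE]
  if (nrow(pooled) > 0L) {
    studies <- rbind(studies, data.frame(
      label = paste0("pooled ", pooled$bin), bin = pooled$bin,
      yi = pooled$mu, si = pooled$se_mu, pooled = TRUE))
  }
  rownames(studies) <- NULL
  studies
}

#' Write the per-replicate table and summary of an SFT bootstrap
#'
#' @param summary an `sft_summary` from [bootstrap_sft()].
#' @param dir output directory (created if absent).
#' @export
write_sft_outcomes <- function(summary, dir) {
  stopifnot(inherits(summary, "sft_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(summary$replicates, file.path(dir, "bootstrap_replicates.csv"),
            row.names = FALSE)
  yaml::write_yaml(list(
    mean_change_rate = summary$mean_change_rate,
    ci_low = summary$ci_low, ci_high = summary$ci_high,
    pearson_r = summary$pearson_r, r_p_value = summary$r_p_value,
    n_failed = summary$n_failed,
    settings = summary$settings), file.path(dir, "sft_summary.yml"))
  invisible(dir)
}
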