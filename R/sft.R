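#' The ten MBC predictor covariates
#'
#' Column names of the predictor set used throughout the space-for-time
#' diagnostic: annual temperature, soil organic carbon, soil pH,
#' precipitation, clay, sand, land cover (categorical), soil nitrogen,
#' NDVI, and elevation.
#' @format character vector of length 10.
#' @export
mbc_predictors <- c("temperature", "soc", "ph", "precipitation", "clay",
                    "sand", "land_cover", "nitrogen", "ndvi", "elevation")

.continuous_predictors <- setdiff(mbc_predictors, "land_cover")

#' Spatial MBC-temperature slope of an observation set
#'
#' Univariate OLS slope of MBC on annual temperature across sites - the
#' spatial gradient that a space-for-time extrapolation implicitly converts
#' into a temporal trend.
#'
#' @param data data frame with columns `mbc` and `temperature`.
#' @return numeric slope, mmol kg-1 per deg C.
#' @export
spatial_slope <- function(data) {
  stopifnot(is.data.frame(data), all(c("mbc", "temperature") %in% names(data)))
  if (nrow(data) < 3L) stop("need at least 3 observations")
  if (diff(range(data$temperature)) < .Machine$double.eps^0.5)
    stop("temperature is constant across observations")
  unname(coef(lm(mbc ~ temperature, data = data))[2L])
}

#' Random-Forest model of MBC from the ten predictor covariates
#'
#' Thin wrapper around [ranger::ranger()] with fixed, reproducible settings
#' (single thread, explicit seed). `mbc_predictors` lists the ten predictor
#' columns; land cover must be a factor with fixed global levels so that
#' subsamples missing a class remain alignable.
#'
#' @param train data frame with column `mbc` and the ten predictors.
#' @param seed integer seed (predictions are bit-reproducible given it).
#' @param num_trees number of trees (default 500).
#' @param mtry predictors tried per split; default one third of the
#'   predictors.
#' @param min_node_size minimal terminal node size (default 5, the
#'   regression default).
#' @return a fitted `ranger` object.
#' @export
fit_mbc_model <- function(train, seed = 1L, num_trees = 500L, mtry = NULL,
                          min_node_size = 5L) {
  stopifnot(is.data.frame(train),
            all(c("mbc", mbc_predictors) %in% names(train)))
  if (nrow(train) < 2L) stop("training set is degenerate")
  if (is.null(mtry)) mtry <- max(1L, floor(length(mbc_predictors) / 3))
  ranger::ranger(
    dependent.variable.name = "mbc",
    data = train[, c("mbc", mbc_predictors)],
    num.trees = num_trees, mtry = mtry, min.node.size = min_node_size,
    respect.unordered.factors = "order",
    seed = seed, num.threads = 1L)
}

#' Predict annual global MBC totals over a world grid
#'
#' For each of the 22 years, predicts MBC for every valid grid cell from
#' the static predictors plus that year's temperature layer, and sums the
#' predictions with the cell area weights. Cells outside the mask are
#' excluded from every year equally, so the series is comparable across
#' years.
#'
#' @param model fitted model from [fit_mbc_model()].
#' @param grid a `world_grid` from [generate_world()].
#' @param mask logical vector over grid cells (`NULL`: all valid).
#' @return named numeric vector of annual global MBC totals.
#' @export
predict_global_series <- function(model, grid, mask = NULL) {
  stopifnot(inherits(grid, "world_grid"))
  n_cells <- nrow(grid$cells)
  if (is.null(mask)) mask <- rep(TRUE, n_cells)
  stopifnot(is.logical(mask), length(mask) == n_cells)
  if (!any(mask)) stop("coverage mask is empty: no valid cells to predict")

  cells <- grid$cells[mask, , drop = FALSE]
  temp <- grid$temperature[mask, , drop = FALSE]
  n_valid <- nrow(cells)
  n_years <- length(grid$years)

  static_cols <- setdiff(mbc_predictors, "temperature")
  newdata <- cells[rep(seq_len(n_valid), times = n_years), static_cols,
                   drop = FALSE]
  newdata$temperature <- as.vector(temp)
  pred <- predict(model, data = newdata, num.threads = 1L)$predictions
  totals <- colSums(matrix(cells$area * pred, nrow = n_valid, ncol = n_years))
  setNames(totals, colnames(grid$temperature))
}

#' Annual change rate of a predicted global MBC series
#'
#' OLS trend of the annual totals against year, normalized by the
#' period-mean total (or the initial-year total) and expressed in % per
#' year. The confidence interval comes from the t distribution of the
#' year-trend slope.
#'
#' @param series numeric vector of annual totals; years are taken from its
#'   names unless given.
#' @param years optional numeric vector of years.
#' @param denominator `"period_mean"` (default) or `"initial"`.
#' @param level confidence level.
#' @return list of class `change_rate`: `rate` (% per year), `se`,
#'   `ci_low`, `ci_high`, `n_years`.
#' @export
change_rate <- function(series, years = NULL,
                        denominator = c("period_mean", "initial"),
                        level = 0.95) {
  denominator <- match.arg(denominator)
  if (is.null(years)) years <- as.numeric(names(series))
  stopifnot(length(series) == length(years), length(series) >= 3L,
            all(is.finite(series)), all(is.finite(years)))
  denom <- switch(denominator, period_mean = mean(series),
                  initial = unname(series[1L]))
  if (abs(denom) < .Machine$double.eps) stop("zero denominator MBC total")
  fit <- lm(y ~ x, data = data.frame(y = series, x = years))
  # exactly linear series (zero residual) are valid input
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["x", "Estimate"]
  se <- sm["x", "Std. Error"]
  tcrit <- qt(1 - (1 - level) / 2, df = length(series) - 2L)
  structure(list(rate = 100 * slope / denom, se = 100 * se / abs(denom),
                 ci_low = 100 * (slope - tcrit * se) / denom,
                 ci_high = 100 * (slope + tcrit * se) / denom,
                 n_years = length(series), denominator = denominator),
            class = "change_rate")
}

#' @export
print.change_rate <- function(x, ...) {
  cat(sprintf("Annual change rate: %.4f%% yr-1 [%.4f, %.4f] over %d years (%s)\n",
              x$rate, min(x$ci_low, x$ci_high), max(x$ci_low, x$ci_high),
              x$n_years, x$denominator))
  invisible(x)
}

#' Mahalanobis-distance coverage mask
#'
#' A grid cell is considered inside the model's applicable domain iff the
#' squared Mahalanobis distance of its continuous predictor vector from the
#' training centroid does not exceed the chi-square quantile at as many
#' degrees of freedom as there are continuous predictors. The training
#' covariance is ridge-regularized when near-singular.
#'
#' @param train data frame of training observations (predictor columns).
#' @param grid a `world_grid`.
#' @param quantile chi-square quantile (default 0.975).
#' @param year which year's temperature layer to evaluate (default the
#'   baseline, 1992).
#' @return logical vector over grid cells, with the squared distances in
#'   attribute `"d2"`.
#' @export
coverage_mask_mahalanobis <- function(train, grid, quantile = 0.975,
                                      year = NULL) {
  stopifnot(inherits(grid, "world_grid"), quantile > 0, quantile < 1)
  X <- .grid_predictor_matrix(grid, year)
  Tm <- as.matrix(train[, .continuous_predictors])
  mu <- colMeans(Tm)
  S <- cov(Tm)
  # ridge-regularize a near-singular training covariance
  if (rcond(S) < 1e-10) S <- S + diag(1e-8 * mean(diag(S)), ncol(S))
  if (rcond(S) < 1e-12) stop("singular training covariance after regularization")
  d2 <- mahalanobis(X, mu, S)
  mask <- d2 <= qchisq(quantile, df = length(.continuous_predictors))
  attr(mask, "d2") <- d2
  mask
}

#' Dissimilarity-index coverage mask
#'
#' Per-cell dissimilarity index: Euclidean distance, in predictor space
#' standardized by the training means and SDs, to the nearest training
#' point, divided by the mean pairwise training distance. A cell is valid
#' iff its index does not exceed the threshold; by default the threshold is
#' the upper boxplot whisker (Q3 + 1.5 IQR, capped at the maximum) of the
#' leave-one-out training indices.
#'
#' @param train data frame of training observations.
#' @param grid a `world_grid`.
#' @param threshold optional fixed threshold; `NULL` applies the
#'   upper-whisker rule.
#' @param year temperature layer to evaluate (default baseline).
#' @return logical vector over grid cells with attributes `"di"` and
#'   `"threshold"`.
#' @export
coverage_mask_dissimilarity <- function(train, grid, threshold = NULL,
                                        year = NULL) {
  stopifnot(inherits(grid, "world_grid"))
  Tm <- as.matrix(train[, .continuous_predictors])
  if (nrow(Tm) < 2L) stop("dissimilarity index needs at least 2 training points")
  mu <- colMeans(Tm)
  sdev <- apply(Tm, 2L, sd)
  sdev[sdev < .Machine$double.eps] <- 1
  Ts <- sweep(sweep(Tm, 2L, mu), 2L, sdev, "/")
  X <- .grid_predictor_matrix(grid, year)
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdev, "/")

  cross2 <- .cross_dist2(Xs, Ts)
  nnd <- sqrt(pmax(0, apply(cross2, 1L, min)))
  self2 <- .cross_dist2(Ts, Ts)
  mean_pair <- mean(sqrt(pmax(0, self2[upper.tri(self2)])))
  if (mean_pair < .Machine$double.eps)
    stop("degenerate training set: all points coincide")
  di <- nnd / mean_pair

  if (is.null(threshold)) {
    diag(self2) <- Inf
    train_di <- sqrt(pmax(0, apply(self2, 1L, min))) / mean_pair
    qs <- quantile(train_di, c(0.25, 0.75), names = FALSE)
    threshold <- min(max(train_di), qs[2L] + 1.5 * (qs[2L] - qs[1L]))
  }
  mask <- di <= threshold
  attr(mask, "di") <- di
  attr(mask, "threshold") <- threshold
  mask
}

# squared Euclidean cross-distances, row-wise A vs B
.cross_dist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

# continuous predictor matrix of the grid at a given year's temperature
.grid_predictor_matrix <- function(grid, year = NULL) {
  if (is.null(year)) year <- grid$years[1L]
  ycol <- match(as.character(year), colnames(grid$temperature))
  if (is.na(ycol)) stop("year ", year, " not in the grid")
  X <- grid$cells[, setdiff(.continuous_predictors, "temperature")]
  X$temperature <- grid$temperature[, ycol]
  as.matrix(X[, .continuous_predictors])
}

#' Bootstrap diagnostic for the space-for-time substitution artifact
#'
#' The m-out-of-n bootstrap at the heart of the package: `reps` times, draw
#' `m` observations with replacement from the spatial observation set,
#' record the subsample's spatial MBC-temperature slope, train a Random
#' Forest on it, restrict the grid to the subsample's coverage mask, predict
#' annual global MBC for 1992-2013, and convert the predicted series to an
#' annual change rate. If the predicted temporal decline is an artifact of
#' the spatial MBC-temperature gradient, subsamples with steeper negative
#' spatial slopes predict steeper declines, and the across-rep correlation
#' between change rate and spatial slope is positive.
#'
#' @param observations spatial observation data frame (`mbc` + the ten
#'   predictors), e.g. `generate_world()$observations`, optionally augmented
#'   with [generate_extra_observations()].
#' @param grid a `world_grid`.
#' @param m subsample size per replicate (default 500).
#' @param reps number of bootstrap replicates (default 200).
#' @param seed master seed; per-replicate Random-Forest seeds are derived
#'   from it and the whole summary is bit-reproducible given it.
#' @param mask_method `"mahalanobis"` (default), `"dissimilarity"`, or
#'   `"none"`.
#' @param shared_mask if `TRUE`, predictions for every replicate use the
#'   single shared layer of cells valid in all replicates' masks, instead of
#'   each replicate's own mask.
#' @param quantile chi-square quantile for the Mahalanobis mask.
#' @param num_trees,mtry,min_node_size forwarded to [fit_mbc_model()].
#' @param denominator forwarded to [change_rate()].
#' @return object of class `sft_summary`: `mean_change_rate`, `ci_low`,
#'   `ci_high` (normal approximation across replicates), `pearson_r` and
#'   `r_p_value` for the change-rate vs spatial-slope relationship,
#'   `replicates` (per-rep data frame with `rep_id`, `spatial_slope`,
#'   `change_rate`, `rate_ci_low`, `rate_ci_high`, `coverage_fraction`),
#'   `n_failed`, and `settings`.
#' @export
bootstrap_sft <- function(observations, grid, m = 500L, reps = 200L,
                          seed = 1L,
                          mask_method = c("mahalanobis", "dissimilarity", "none"),
                          shared_mask = FALSE, quantile = 0.975,
                          num_trees = 500L, mtry = NULL, min_node_size = 5L,
                          denominator = c("period_mean", "initial")) {
  mask_method <- match.arg(mask_method)
  denominator <- match.arg(denominator)
  stopifnot(is.data.frame(observations), inherits(grid, "world_grid"),
            reps >= 2L, m >= 3L)
  n <- nrow(observations)
  if (m > 10L * n) stop("m is implausibly large relative to n")

  set.seed(seed)
  idx <- matrix(sample.int(n, m * reps, replace = TRUE), nrow = m, ncol = reps)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)

  masks <- lapply(seq_len(reps), function(r) {
    tr <- observations[idx[, r], , drop = FALSE]
    switch(mask_method,
           mahalanobis = as.logical(coverage_mask_mahalanobis(tr, grid, quantile)),
           dissimilarity = as.logical(coverage_mask_dissimilarity(tr, grid)),
           none = rep(TRUE, nrow(grid$cells)))
  })
  if (shared_mask) {
    shared <- Reduce(`&`, masks)
    if (!any(shared)) stop("shared coverage mask is empty")
    masks <- rep(list(shared), reps)
  }

  rows <- vector("list", reps)
  errors <- character(0)
  for (r in seq_len(reps)) {
    res <- tryCatch({
      tr <- observations[idx[, r], , drop = FALSE]
      slope <- spatial_slope(tr)
      model <- fit_mbc_model(tr, seed = rep_seeds[r], num_trees = num_trees,
                             mtry = mtry, min_node_size = min_node_size)
      series <- predict_global_series(model, grid, masks[[r]])
      cr <- change_rate(series, denominator = denominator)
      data.frame(rep_id = r, spatial_slope = slope, change_rate = cr$rate,
                 rate_ci_low = cr$ci_low, rate_ci_high = cr$ci_high,
                 coverage_fraction = mean(masks[[r]]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("rep %d: %s", r, conditionMessage(res)))
    } else {
      rows[[r]] <- res
    }
  }
  reps_df <- do.call(rbind, rows)
  if (is.null(reps_df) || nrow(reps_df) < 2L)
    stop("fewer than 2 bootstrap replicates succeeded; first error: ",
         if (length(errors)) errors[1L] else "none recorded")

  rate <- reps_df$change_rate
  mu <- mean(rate)
  half <- qnorm(0.975) * sd(rate) / sqrt(length(rate))
  ct <- suppressWarnings(cor.test(reps_df$change_rate, reps_df$spatial_slope,
                                  method = "pearson"))

  structure(list(mean_change_rate = mu, ci_low = mu - half, ci_high = mu + half,
                 pearson_r = unname(ct$estimate), r_p_value = ct$p.value,
                 replicates = reps_df, n_failed = length(errors),
                 failures = errors,
                 settings = list(m = m, reps = reps, seed = seed,
                                 mask_method = mask_method,
                                 shared_mask = shared_mask,
                                 quantile = quantile, num_trees = num_trees,
                                 mtry = mtry, min_node_size = min_node_size,
                                 denominator = denominator, n = n)),
            class = "sft_summary")
}

#' @export
print.sft_summary <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Space-for-time bootstrap: %d reps of m = %d from n = %d (%s mask%s)\n",
              s$reps, s$m, s$n, s$mask_method,
              if (s$shared_mask) ", shared" else ""))
  cat(sprintf("  mean change rate: %.4f%% yr-1 [%.4f, %.4f]\n",
              x$mean_change_rate, x$ci_low, x$ci_high))
  cat(sprintf("  change rate vs spatial slope: Pearson r = %.3f, p = %.3g\n",
              x$pearson_r, x$r_p_value))
  if (x$n_failed > 0)
    cat(sprintf("  %d replicate(s) failed and were excluded\n", x$n_failed))
  invisible(x)
}
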