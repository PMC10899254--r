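#' Per-site regression of long-term MBC on annual temperature
#'
#' Fits, for one multi-year in-situ site series, the simple linear
#' regression MBC ~ annual temperature, with a t-based 95% confidence
#' interval for the slope (n - 2 degrees of freedom). "No significant
#' correlation" corresponds to a CI spanning zero.
#'
#' @param series data frame with columns `year`, `mbc`, `temp` for one site
#'   (at least 3 years, strictly increasing years, temperature not constant).
#' @param level confidence level (default 0.95).
#' @return one-row data frame: `slope`, `se`, `ci_low`, `ci_high`,
#'   `p_value`, `n`, `significant` (CI excludes zero).
#' @export
site_slope <- function(series, level = 0.95) {
  stopifnot(is.data.frame(series),
            all(c("year", "mbc", "temp") %in% names(series)))
  n <- nrow(series)
  if (n < 3L) stop("site series needs at least 3 years, got ", n)
  if (any(diff(order(series$year)) <= 0) || anyDuplicated(series$year))
    stop("years must be strictly increasing")
  if (diff(range(series$temp)) < .Machine$double.eps^0.5)
    stop("annual temperature is constant; slope is undefined")
  if (diff(range(series$mbc)) < .Machine$double.eps^0.5) {
    # constant MBC: zero slope, no evidence of any temperature association
    return(data.frame(slope = 0, se = 0, ci_low = 0, ci_high = 0,
                      p_value = 1, n = n, significant = FALSE))
  }
  fit <- lm(mbc ~ temp, data = series)
  # noiseless series are valid input: silence the perfect-fit warning
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["temp", "Estimate"]
  se <- sm["temp", "Std. Error"]
  tcrit <- qt(1 - (1 - level) / 2, df = n - 2L)
  ci <- slope + c(-1, 1) * tcrit * se
  data.frame(slope = slope, se = se, ci_low = ci[1L], ci_high = ci[2L],
             p_value = sm["temp", "Pr(>|t|)"], n = n,
             significant = ci[1L] > 0 | ci[2L] < 0)
}

#' Slopes for all long-term sites
#'
#' Applies [site_slope()] to each site in a stacked site-series table.
#'
#' @param data data frame with columns `site_id`, `year`, `mbc`, `temp`.
#' @param level confidence level.
#' @return data frame with one row per site (`site_id` plus the
#'   [site_slope()] columns).
#' @export
longterm_slopes <- function(data, level = 0.95) {
  stopifnot(is.data.frame(data),
            all(c("site_id", "year", "mbc", "temp") %in% names(data)))
  sites <- unique(data$site_id)
  rows <- lapply(sites, function(s) {
    res <- site_slope(data[data$site_id == s, , drop = FALSE], level = level)
    cbind(data.frame(site_id = s), res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
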