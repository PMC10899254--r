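#' Generate long-term in-situ site series of MBC and annual temperature
#'
#' Emulates multi-year in-situ MBC monitoring: each site gets 3-10 annual
#' observations, a site-specific mean temperature and baseline MBC, and
#' MBC = baseline + `temp_sensitivity` x (T - site mean T) + noise. With
#' `noise_sd = 0`, per-site OLS recovers `temp_sensitivity` exactly.
#'
#' @param n_sites number of sites.
#' @param years_per_site integer pair; observation-period lengths are drawn
#'   uniformly from this range (must lie within 3-10 years).
#' @param temp_sensitivity true temporal slope, mmol kg-1 per deg C
#'   (0 gives the null world of temperature-insensitive MBC).
#' @param noise_sd residual SD of annual MBC, mmol kg-1.
#' @param temp_anomaly_sd SD of interannual temperature anomalies, deg C.
#' @param baseline_mbc site baseline MBC is drawn uniformly in
#'   `baseline_mbc * c(0.5, 1.5)` (mmol kg-1).
#' @param seed integer seed.
#' @return data frame with columns `site_id`, `year`, `mbc`, `temp`.
#' @export
generate_longterm_series <- function(n_sites = 6L,
                                     years_per_site = c(3L, 10L),
                                     temp_sensitivity = 0,
                                     noise_sd = 2,
                                     temp_anomaly_sd = 0.8,
                                     baseline_mbc = 30,
                                     seed = 1L) {
  stopifnot(n_sites >= 1L, length(years_per_site) == 2L,
            noise_sd >= 0, temp_anomaly_sd > 0)
  if (years_per_site[1L] < 3L || years_per_site[2L] > 10L ||
      years_per_site[2L] < years_per_site[1L])
    stop("years_per_site must be an increasing pair within [3, 10]")
  set.seed(seed)
  rows <- lapply(seq_len(n_sites), function(s) {
    len <- sample(years_per_site[1L]:years_per_site[2L], 1L)
    years <- seq(2000L, length.out = len)
    site_mean_t <- runif(1, 2, 15)
    temp <- site_mean_t + rnorm(len, 0, temp_anomaly_sd)
    base <- baseline_mbc * runif(1, 0.5, 1.5)
    mbc <- base + temp_sensitivity * (temp - site_mean_t) + rnorm(len, 0, noise_sd)
    data.frame(site_id = sprintf("LT%02d", s), year = years,
               mbc = mbc, temp = temp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
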