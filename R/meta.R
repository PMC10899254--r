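#' Random-effects pooling by the DerSimonian-Laird moment estimator
#'
#' Pools effect sizes under the additive random-effects model
#' \eqn{y_i \sim N(\mu, v_i + \tau^2)}. The between-study variance is the
#' DerSimonian-Laird moment estimate
#' \deqn{\tau^2 = \max\left(0, \frac{Q - (k-1)}{\sum w_i - \sum w_i^2/\sum w_i}\right),}
#' with fixed-effect weights \eqn{w_i = 1/v_i} and Cochran's
#' \eqn{Q = \sum w_i (y_i - \hat\mu_F)^2}. The pooled mean uses
#' random-effects weights \eqn{w_i^* = 1/(v_i + \tau^2)}, the 95% CI the
#' normal quantile, and \eqn{I^2 = \max(0, (Q - (k-1))/Q) \cdot 100}.
#'
#' When no sampling variances are available at all (`vi = NULL` or all `NA`),
#' an unweighted method-of-moments fit is used instead: `mu` is the
#' arithmetic mean, all observed spread is attributed to `tau2`
#' (`tau2 = var(yi)`), `se_mu = sd(yi)/sqrt(k)`, and `Q`/`I2` are `NA`.
#'
#' @param yi numeric vector of effect sizes (or a data frame with columns
#'   `yi` and `vi`, e.g. the output of [log_response_ratio()]).
#' @param vi sampling variances, same length as `yi`; all must be positive,
#'   or all `NA`/`NULL` for the unweighted fallback.
#' @param level confidence level (default 0.95).
#' @return object of class `meta_result`: list with `k`, `mu`, `se_mu`,
#'   `ci_low`, `ci_high`, `tau2`, `Q`, `I2`, `p_value`, `method`.
#' @examples
#' pool_random_effects(c(0.1, 0.3), c(0.01, 0.02))
#' @export
pool_random_effects <- function(yi, vi = NULL, level = 0.95) {
  if (is.data.frame(yi)) {
    if (is.null(vi) && "vi" %in% names(yi)) vi <- yi$vi
    yi <- yi$yi
  }
  k <- length(yi)
  if (k < 2L) stop("random-effects pooling needs k >= 2 studies, got ", k)
  if (any(!is.finite(yi))) stop("non-finite effect sizes")

  crit <- qnorm(1 - (1 - level) / 2)

  if (is.null(vi) || all(is.na(vi))) {
    # unweighted method-of-moments: all spread is between-study
    mu <- mean(yi)
    tau2 <- var(yi)
    se_mu <- sd(yi) / sqrt(k)
    res <- list(k = k, mu = mu, se_mu = se_mu,
                ci_low = mu - crit * se_mu, ci_high = mu + crit * se_mu,
                tau2 = tau2, Q = NA_real_, I2 = NA_real_,
                p_value = 2 * pnorm(-abs(mu / se_mu)),
                method = "unweighted-MoM")
    class(res) <- "meta_result"
    return(res)
  }

  if (length(vi) != k) stop("yi and vi must have equal length")
  if (any(is.na(vi)))
    stop("some sampling variances are missing; impute them first ",
         "(see log_response_ratio(impute_missing = TRUE)) or pass vi = NULL")
  if (any(vi <= 0)) stop("all sampling variances must be > 0")

  w <- 1 / vi
  mu_f <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - mu_f)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (Q - (k - 1)) / denom) else 0
  ws <- 1 / (vi + tau2)
  mu <- sum(ws * yi) / sum(ws)
  se_mu <- sqrt(1 / sum(ws))
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0

  res <- list(k = k, mu = mu, se_mu = se_mu,
              ci_low = mu - crit * se_mu, ci_high = mu + crit * se_mu,
              tau2 = tau2, Q = Q, I2 = I2,
              p_value = 2 * pnorm(-abs(mu / se_mu)),
              method = "DL")
  class(res) <- "meta_result"
  res
}

#' @export
print.meta_result <- function(x, digits = 4, ...) {
  cat(sprintf("Random-effects meta-analysis (%s), k = %d\n", x$method, x$k))
  cat(sprintf("  mu = %.*f  [%.*f, %.*f]  (p = %.3g)\n",
              digits, x$mu, digits, x$ci_low, digits, x$ci_high, x$p_value))
  cat(sprintf("  tau2 = %.*f  Q = %s  I2 = %s%%\n", digits, x$tau2,
              ifelse(is.na(x$Q), "NA", sprintf("%.*f", digits, x$Q)),
              ifelse(is.na(x$I2), "NA", sprintf("%.1f", x$I2))))
  invisible(x)
}

#' Bin specifications for warming-magnitude and duration subgroups
#'
#' Bins are left-closed, right-open (`[e_i, e_{i+1})`) except the last,
#' which is closed on both sides so the upper edge belongs to a bin.
#'
#' @param edges strictly increasing numeric boundaries.
#' @param labels optional bin labels; defaults are built from the edges.
#' @return object of class `bin_spec`.
#' @examples
#' warming_bins()
#' duration_bins()
#' @export
bin_spec <- function(edges, labels = NULL) {
  stopifnot(is.numeric(edges), length(edges) >= 2L)
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  nb <- length(edges) - 1L
  if (is.null(labels)) {
    labels <- paste0(edges[-length(edges)], "-", edges[-1L])
    labels[1L] <- paste0("<", edges[2L])
  }
  if (length(labels) != nb) stop("need one label per bin")
  if (anyDuplicated(labels)) stop("bin labels must be unique")
  structure(list(edges = edges, labels = labels), class = "bin_spec")
}

#' @rdname bin_spec
#' @export
warming_bins <- function() {
  bin_spec(c(0, 1, 2, 3, 4, 5), c("<1", "1-2", "2-3", "3-4", "4-5"))
}

#' @rdname bin_spec
#' @export
duration_bins <- function() {
  bin_spec(c(0, 3, 6, 30), c("<3", "3-6", "6-30"))
}

#' Assign values to bins
#'
#' @param x numeric vector (e.g. warming magnitudes in deg C).
#' @param bins a [bin_spec()].
#' @return factor with the bin labels as levels; values outside the edges
#'   raise an error (bins must be exhaustive over the observed range).
#' @export
assign_bins <- function(x, bins) {
  stopifnot(inherits(bins, "bin_spec"))
  out_of_range <- !is.na(x) & (x < bins$edges[1L] | x > bins$edges[length(bins$edges)])
  if (any(out_of_range))
    stop("value(s) outside the bin range: ",
         paste(utils::head(x[out_of_range], 5L), collapse = ", "))
  idx <- findInterval(x, bins$edges, rightmost.closed = TRUE)
  factor(bins$labels[idx], levels = bins$labels)
}

#' Subgroup random-effects analysis over bins of a moderator
#'
#' Pools effect sizes separately within each bin of `by` (default: warming
#' magnitude). Bins with fewer than two studies are reported as unpoolable
#' rather than dropped; empty bins are reported with `k = 0`.
#'
#' @param effects data frame with columns `yi`, `vi` and the moderator
#'   column named by `by` (e.g. output of [log_response_ratio()]).
#' @param bins a [bin_spec()].
#' @param by name of the moderator column, default `"warming_magnitude"`.
#' @param level confidence level.
#' @return data frame with one row per bin: `bin`, `k`, `poolable`, `mu`,
#'   `se_mu`, `ci_low`, `ci_high`, `tau2`, `Q`, `I2`, `p_value`. The list of
#'   underlying `meta_result` objects is attached as attribute `"fits"`.
#' @export
subgroup_analysis <- function(effects, bins = warming_bins(),
                              by = "warming_magnitude", level = 0.95) {
  stopifnot(is.data.frame(effects), by %in% names(effects),
            all(c("yi", "vi") %in% names(effects)))
  grp <- assign_bins(effects[[by]], bins)
  fits <- vector("list", length(bins$labels))
  names(fits) <- bins$labels
  rows <- lapply(bins$labels, function(lab) {
    sel <- which(grp == lab)
    k <- length(sel)
    if (k < 2L) {
      return(data.frame(bin = lab, k = k, poolable = FALSE,
                        mu = NA_real_, se_mu = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, tau2 = NA_real_, Q = NA_real_,
                        I2 = NA_real_, p_value = NA_real_))
    }
    fit <- pool_random_effects(effects$yi[sel], effects$vi[sel], level = level)
    fits[[lab]] <<- fit
    data.frame(bin = lab, k = k, poolable = TRUE, mu = fit$mu,
               se_mu = fit$se_mu, ci_low = fit$ci_low, ci_high = fit$ci_high,
               tau2 = fit$tau2, Q = fit$Q, I2 = fit$I2, p_value = fit$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Quadratic fit of effect size on warming magnitude
#'
#' Fits `yi ~ dT + dT^2` by OLS, mirroring the check for a hump-shaped
#' response of the log response ratio to warming magnitude.
#'
#' @param effects data frame with columns `yi` and `warming_magnitude`.
#' @return list of class `quadratic_fit`: `coefficients` (intercept, linear,
#'   quadratic), `r2_adj`, `p_value` (overall F test), `n`, and the `lm` fit.
#' @export
fit_quadratic_response <- function(effects) {
  stopifnot(is.data.frame(effects),
            all(c("yi", "warming_magnitude") %in% names(effects)))
  n <- nrow(effects)
  if (n < 4L) stop("quadratic fit needs at least 4 observations")
  dT <- effects$warming_magnitude
  if (length(unique(dT)) < 3L)
    stop("warming magnitudes are (nearly) constant; quadratic design is collinear")
  fit <- lm(yi ~ dT + I(dT^2), data = data.frame(yi = effects$yi, dT = dT))
  sm <- suppressWarnings(summary(fit))
  fstat <- sm$fstatistic
  p <- unname(pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  structure(list(coefficients = setNames(coef(fit),
                                         c("intercept", "linear", "quadratic")),
                 r2_adj = sm$adj.r.squared, p_value = p, n = n, fit = fit),
            class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat("Quadratic response fit: yi ~ dT + dT^2, n =", x$n, "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  adj. R2 = %.3f, overall F p = %.3g\n", x$r2_adj, x$p_value))
  invisible(x)
}
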