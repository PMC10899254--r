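#' Configuration for the synthetic field-warming experiment generator
#'
#' Describes a population of paired warming/control MBC studies with known
#' ground truth: a true mean log response ratio per warming-magnitude bin,
#' between-study heterogeneity, within-study replicate noise, and an
#' optional one-sided suppression mechanism that emulates publication bias.
#'
#' @param n_pairs number of paired studies to generate (before suppression).
#' @param bin_effects named numeric vector: true mean LN(RR) per
#'   warming-magnitude bin; names must be labels of `bins`. Only named bins
#'   are populated.
#' @param bins a [bin_spec()] giving the warming-magnitude bins
#'   (default [warming_bins()]).
#' @param between_study_sd SD of the study-level true effects around the
#'   bin mean (dimensionless, on the LN(RR) scale).
#' @param within_sd_frac median relative SD of replicate MBC measurements
#'   within an arm (per-arm reported SD = study CV x arm mean); must be > 0.
#' @param within_sd_sdlog log-scale SD of the study-level CV around
#'   `within_sd_frac`. Studies compiled from many independent papers differ
#'   widely in measurement precision; 0 gives every study the same CV.
#' @param replicates_range integer pair: per-arm replicate counts are drawn
#'   uniformly from this range.
#' @param duration_range numeric pair of warming durations in years.
#' @param control_meanlog,control_sdlog log-normal parameters of the control
#'   arm mean MBC (mmol kg-1); defaults centre around ~30 mmol kg-1.
#' @param suppress_prob probability that an eligible study is dropped
#'   (publication-bias injection; 0 disables).
#' @param suppress_side `"high"` drops studies with observed LN(RR) above
#'   `suppress_cutoff`; `"low"` drops those below it.
#' @param suppress_cutoff LN(RR) cutoff for suppression eligibility.
#' @param suppress_max_n only studies whose mean per-arm replicate count is
#'   at most this value are eligible for suppression (`Inf`: all studies).
#'   Selective non-publication of small studies is what produces the
#'   funnel asymmetry an Egger test is designed to detect.
#' @param seed integer seed; generation is deterministic given the config.
#' @return object of class `warming_sim_config`.
#' @export
warming_sim_config <- function(n_pairs = 130L,
                               bin_effects = c("<1" = 0, "1-2" = 0, "2-3" = 0,
                                               "3-4" = 0, "4-5" = 0),
                               bins = warming_bins(),
                               between_study_sd = 0.1,
                               within_sd_frac = 0.25,
                               within_sd_sdlog = 0.5,
                               replicates_range = c(3L, 10L),
                               duration_range = c(1, 10),
                               control_meanlog = log(30),
                               control_sdlog = 0.4,
                               suppress_prob = 0,
                               suppress_side = c("high", "low"),
                               suppress_cutoff = 0,
                               suppress_max_n = Inf,
                               seed = 1L) {
  suppress_side <- match.arg(suppress_side)
  if (length(bin_effects) == 0L || is.null(names(bin_effects)))
    stop("bin_effects must be a non-empty named vector of true mean LN(RR)")
  if (!all(names(bin_effects) %in% bins$labels))
    stop("bin_effects names must be bin labels: ",
         paste(bins$labels, collapse = ", "))
  if (n_pairs < 2L * length(bin_effects))
    stop("need at least 2 pairs per populated bin")
  if (!(within_sd_frac > 0)) stop("within_sd_frac must be > 0")
  if (within_sd_sdlog < 0) stop("within_sd_sdlog must be >= 0")
  if (suppress_prob < 0 || suppress_prob > 1)
    stop("suppress_prob must be in [0, 1]")
  if (between_study_sd < 0) stop("between_study_sd must be >= 0")
  stopifnot(length(replicates_range) == 2L,
            replicates_range[1L] >= 2L,
            replicates_range[2L] >= replicates_range[1L],
            length(duration_range) == 2L, duration_range[1L] > 0,
            duration_range[2L] >= duration_range[1L])
  structure(list(n_pairs = as.integer(n_pairs), bin_effects = bin_effects,
                 bins = bins, between_study_sd = between_study_sd,
                 within_sd_frac = within_sd_frac,
                 within_sd_sdlog = within_sd_sdlog,
                 replicates_range = as.integer(replicates_range),
                 duration_range = duration_range,
                 control_meanlog = control_meanlog,
                 control_sdlog = control_sdlog,
                 suppress_prob = suppress_prob,
                 suppress_side = suppress_side,
                 suppress_cutoff = suppress_cutoff,
                 suppress_max_n = suppress_max_n,
                 seed = as.integer(seed)),
            class = "warming_sim_config")
}

#' Generate paired warming/control MBC records with known true effects
#'
#' Each study draws a warming-magnitude bin (uniformly among the populated
#' bins), a magnitude within the bin, a study-level true LN(RR) = bin mean +
#' N(0, between_study_sd), and a log-normal control mean. Observed arm means
#' carry replicate sampling noise on the log scale
#' (sdlog = `within_sd_frac` / sqrt(n)), which keeps MBC strictly positive;
#' reported per-arm SDs equal `within_sd_frac` x the observed arm mean.
#' Studies whose observed LN(RR) falls on the configured side of the cutoff
#' are then dropped with probability `suppress_prob`.
#'
#' @param cfg a [warming_sim_config()].
#' @return data frame of records (one per surviving study) with columns
#'   `study_id`, `site_id`, `mbc_control`, `mbc_warmed`, `sd_control`,
#'   `sd_warmed`, `n_control`, `n_warmed`, `warming_magnitude`, `duration`,
#'   `bin`, and the generating `true_lnrr`.
#' @export
generate_warming_pairs <- function(cfg) {
  stopifnot(inherits(cfg, "warming_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_pairs
  labs <- names(cfg$bin_effects)
  edges <- cfg$bins$edges
  bin_idx_all <- match(labs, cfg$bins$labels)

  pick <- sample(seq_along(labs), n, replace = TRUE)
  bin <- labs[pick]
  lo <- edges[bin_idx_all[pick]]
  hi <- edges[bin_idx_all[pick] + 1L]
  warming <- runif(n, lo, hi)

  true_lnrr <- unname(cfg$bin_effects[pick]) + rnorm(n, 0, cfg$between_study_sd)
  ctrl_true <- exp(rnorm(n, cfg$control_meanlog, cfg$control_sdlog))
  n_c <- sample(cfg$replicates_range[1L]:cfg$replicates_range[2L], n, replace = TRUE)
  n_w <- sample(cfg$replicates_range[1L]:cfg$replicates_range[2L], n, replace = TRUE)

  cv <- cfg$within_sd_frac * exp(rnorm(n, 0, cfg$within_sd_sdlog))
  m_c <- ctrl_true * exp(rnorm(n, 0, cv / sqrt(n_c)))
  m_w <- ctrl_true * exp(true_lnrr) * exp(rnorm(n, 0, cv / sqrt(n_w)))

  rec <- data.frame(study_id = sprintf("S%03d", seq_len(n)),
                    site_id = sprintf("site%03d", seq_len(n)),
                    mbc_control = m_c, mbc_warmed = m_w,
                    sd_control = cv * m_c,
                    sd_warmed = cv * m_w,
                    n_control = n_c, n_warmed = n_w,
                    warming_magnitude = warming,
                    duration = runif(n, cfg$duration_range[1L], cfg$duration_range[2L]),
                    bin = bin, true_lnrr = true_lnrr)

  if (cfg$suppress_prob > 0) {
    lnrr_obs <- log(rec$mbc_warmed) - log(rec$mbc_control)
    eligible <- if (cfg$suppress_side == "high") {
      lnrr_obs > cfg$suppress_cutoff
    } else {
      lnrr_obs < cfg$suppress_cutoff
    }
    eligible <- eligible & (rec$n_control + rec$n_warmed) / 2 <= cfg$suppress_max_n
    drop <- eligible & (runif(n) < cfg$suppress_prob)
    rec <- rec[!drop, , drop = FALSE]
    rownames(rec) <- NULL
  }
  rec
}
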