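#' Analysis configuration
#'
#' Single container for every numeric constant of the analysis pipeline.
#' Defaults are the values used throughout: 1-ms EMG smoothing, a twitch
#' criterion of 3x the atonia baseline, 1-s minimum bouts, 1-s perievent
#' windows, 1000 interval-jitter surrogates over 500-ms cells, and the
#' latency windows that define corollary-discharge (within +/-10 ms of
#' event onset), premotor (more than 10 ms before) and reafferent (more
#' than 10 ms after) responses.
#'
#' @param smooth_tau EMG smoothing time constant, s.
#' @param twitch_multiplier Twitch criterion: threshold = multiplier x mean
#'   atonia baseline.
#' @param min_bout Minimum behavioural-state bout duration, s.
#' @param psth_window Perievent window length, s (centred on the trigger).
#' @param bin_width Histogram bin width, s (5, 10 or 20 ms by context).
#' @param cd_window Corollary-discharge latency window, s (two values).
#' @param reafferent_window Reafferent latency window for classification, s.
#' @param premotor_window Premotor latency window, s.
#' @param auc_cd_window,auc_reafferent_window Windows for area-under-curve
#'   summaries, s.
#' @param jitter_window Interval-jitter cell width (Delta), s.
#' @param n_surrogates Number of jitter surrogates (S).
#' @param band_alpha Family-wise alpha for the simultaneous bands.
#' @param outlier_sd Outlier rule: values beyond this many SD of their group
#'   are excluded.
#' @param pooled_smooth_tau Smoothing time constant for pooled histograms, s.
#' @param alpha Alpha for the state-dependence rank tests.
#' @param min_paired_bouts Minimum paired bouts per state comparison.
#' @param refractory Minimum separation between detected twitches, s.
#' @param smooth_filter EMG smoothing filter type, `"exponential"` or
#'   `"boxcar"`.
#' @param rng_seed Integer seed for all randomised steps.
#' @return An object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(smooth_tau = 0.001,
                            twitch_multiplier = 3,
                            min_bout = 1,
                            psth_window = 1,
                            bin_width = 0.010,
                            cd_window = c(-0.010, 0.010),
                            reafferent_window = c(0.010, 0.500),
                            premotor_window = c(-0.500, -0.010),
                            auc_cd_window = c(-0.010, 0.010),
                            auc_reafferent_window = c(0.020, 0.200),
                            jitter_window = 0.500,
                            n_surrogates = 1000,
                            band_alpha = 0.01,
                            outlier_sd = 3,
                            pooled_smooth_tau = 0.010,
                            alpha = 0.05,
                            min_paired_bouts = 5,
                            refractory = 0.200,
                            smooth_filter = c("exponential", "boxcar"),
                            rng_seed = 1L) {
  smooth_filter <- match.arg(smooth_filter)
  cfg <- list(smooth_tau = smooth_tau, twitch_multiplier = twitch_multiplier,
              min_bout = min_bout, psth_window = psth_window,
              bin_width = bin_width, cd_window = cd_window,
              reafferent_window = reafferent_window,
              premotor_window = premotor_window,
              auc_cd_window = auc_cd_window,
              auc_reafferent_window = auc_reafferent_window,
              jitter_window = jitter_window, n_surrogates = n_surrogates,
              band_alpha = band_alpha, outlier_sd = outlier_sd,
              pooled_smooth_tau = pooled_smooth_tau, alpha = alpha,
              min_paired_bouts = min_paired_bouts, refractory = refractory,
              smooth_filter = smooth_filter,
              rng_seed = as.integer(rng_seed))
  validate_analysis_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_analysis_config <- function(cfg) {
  pos <- c("smooth_tau", "min_bout", "psth_window", "bin_width",
           "jitter_window", "pooled_smooth_tau", "refractory")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop(sprintf("analysis_config: '%s' must be a positive scalar", f))
  if (cfg$band_alpha <= 0 || cfg$band_alpha >= 1)
    stop("analysis_config: 'band_alpha' must lie in (0, 1)")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("analysis_config: 'alpha' must lie in (0, 1)")
  if (cfg$n_surrogates < 100)
    stop("analysis_config: 'n_surrogates' must be at least 100")
  if (cfg$twitch_multiplier <= 1)
    stop("analysis_config: 'twitch_multiplier' must exceed 1")
  half <- cfg$psth_window / 2
  for (w in c("cd_window", "reafferent_window", "premotor_window",
              "auc_cd_window", "auc_reafferent_window")) {
    win <- cfg[[w]]
    if (length(win) != 2L || win[1L] >= win[2L])
      stop(sprintf("analysis_config: '%s' must be (start, end) with start < end", w))
    if (win[1L] < -half - 1e-12 || win[2L] > half + 1e-12)
      stop(sprintf("analysis_config: '%s' must lie inside the perievent window", w))
  }
  invisible(cfg)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (f in names(x))
    cat(sprintf("  %-22s %s\n", f, paste(format(x[[f]]), collapse = " ")))
  invisible(x)
}

#' Read / write an analysis configuration as JSON
#'
#' @param path File path.
#' @return `read_config` returns an `analysis_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param config An `analysis_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
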