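#' Per-bout firing rates with outlier-bout exclusion
#'
#' Computes each unit's firing rate in every behavioural-state bout
#' (spike count over the half-open bout divided by bout duration), then
#' excludes bouts whose rate lies beyond `outlier_sd` standard deviations
#' of that state's bout-rate distribution (mean and SD computed before any
#' exclusion; the rule is applied once, not iterated).
#'
#' @param spikes A [spike_train].
#' @param states A [state_intervals].
#' @param outlier_sd Exclusion multiple (default 3).
#' @return An object of class `state_rate_profile`: `bouts` (data.frame
#'   with state, bout index within state, start, end, duration, count,
#'   rate, excluded), `mean_rate` (named, per state, after exclusion),
#'   `n_excluded`.
#' @export
bout_rates <- function(spikes, states, outlier_sd = 3) {
  if (!inherits(states, "state_intervals"))
    stop("bout_rates: 'states' must be a state_intervals")
  sp <- if (inherits(spikes, "spike_train")) spikes$times else as.numeric(spikes)
  n <- nrow(states)
  cnt <- findInterval(states$end - 1e-12, sp) -
    findInterval(states$start - 1e-12, sp)
  dur <- states$end - states$start
  df <- data.frame(state = states$label,
                   bout = stats::ave(seq_len(n), states$label,
                                     FUN = seq_along),
                   start = states$start, end = states$end,
                   duration = dur, count = cnt, rate = cnt / dur,
                   excluded = FALSE, stringsAsFactors = FALSE)
  for (s in unique(df$state)) {
    sel <- df$state == s
    mu <- mean(df$rate[sel]); sdv <- stats::sd(df$rate[sel])
    if (is.finite(sdv) && sdv > 0)
      df$excluded[sel] <- abs(df$rate[sel] - mu) > outlier_sd * sdv
  }
  keep <- !df$excluded
  mr <- c(AW = NA_real_, BQ = NA_real_, AS = NA_real_)
  for (s in names(mr))
    if (any(keep & df$state == s))
      mr[s] <- mean(df$rate[keep & df$state == s])
  uid <- if (inherits(spikes, "spike_train")) spikes$unit_id else NA_character_
  structure(list(unit_id = uid, bouts = df, mean_rate = mr,
                 n_excluded = sum(df$excluded), outlier_sd = outlier_sd),
            class = "state_rate_profile")
}

#' @export
print.state_rate_profile <- function(x, ...) {
  cat(sprintf("<state_rate_profile> unit=%s: mean rate AW=%.3g BQ=%.3g AS=%.3g Hz (%d bout(s) excluded)\n",
              x$unit_id, x$mean_rate["AW"], x$mean_rate["BQ"],
              x$mean_rate["AS"], x$n_excluded))
  invisible(x)
}

# Pair the i-th bout of one state with the i-th bout of another
# (sleep-wake cycle pairing), truncating to the shorter list.
paired_bout_rates <- function(profile, a, b) {
  df <- profile$bouts[!profile$bouts$excluded, ]
  ra <- df$rate[df$state == a]
  rb <- df$rate[df$state == b]
  n <- min(length(ra), length(rb))
  list(a = ra[seq_len(n)], b = rb[seq_len(n)], n = n)
}

state_pair_test <- function(x, y, paired, exact_max = 25) {
  n <- length(x)
  if (paired) {
    if (all(x == y)) return(list(p = 1, direction = 0))
    p <- suppressWarnings(stats::wilcox.test(
      x, y, paired = TRUE, exact = n <= exact_max))$p.value
  } else {
    p <- suppressWarnings(stats::wilcox.test(x, y,
                                             exact = n <= exact_max))$p.value
  }
  list(p = p, direction = sign(mean(x) - mean(y)))
}

#' Classify a unit's behavioural-state dependence
#'
#' Pairwise comparison of per-bout firing rates across states using the
#' Wilcoxon matched-pairs signed-ranks test (bouts paired by sleep-wake
#' cycle index; an unpaired Mann-Whitney fallback is available). The
#' decision table: \emph{AS-on} if AS is significantly above both AW and
#' BQ; \emph{AW-on} symmetric; \emph{AS+AW-on} if AS vs AW is not
#' significant and both are significantly above BQ; \emph{state-independent}
#' if no pair differs. Patterns outside the table are labelled
#' `unclassified`; too few paired bouts give `indeterminate`.
#'
#' @param profile A `state_rate_profile` from [bout_rates()].
#' @param alpha Significance level for each pairwise test (default 0.05,
#'   uncorrected; set `bonferroni = TRUE` to divide by 3).
#' @param pairing `"cycle"` (matched pairs by cycle index, default) or
#'   `"unpaired"` (Mann-Whitney).
#' @param min_pairs Minimum bouts per comparison (default 5).
#' @param bonferroni Apply a 3-way Bonferroni correction to `alpha`?
#' @return An object of class `state_class` with fields `class`,
#'   `p_AS_AW`, `p_AS_BQ`, `p_AW_BQ`, `mean_rate`, `alpha`.
#' @export
classify_state <- function(profile, alpha = 0.05,
                           pairing = c("cycle", "unpaired"),
                           min_pairs = 5, bonferroni = FALSE) {
  pairing <- match.arg(pairing)
  paired <- pairing == "cycle"
  a_eff <- if (bonferroni) alpha / 3 else alpha
  pairs <- list(c("AS", "AW"), c("AS", "BQ"), c("AW", "BQ"))
  p <- c(AS_AW = NA_real_, AS_BQ = NA_real_, AW_BQ = NA_real_)
  dir <- c(AS_AW = 0, AS_BQ = 0, AW_BQ = 0)
  ok <- TRUE
  for (i in seq_along(pairs)) {
    pr <- paired_bout_rates(profile, pairs[[i]][1L], pairs[[i]][2L])
    if (pr$n < min_pairs) { ok <- FALSE; next }
    res <- state_pair_test(pr$a, pr$b, paired = paired)
    p[i] <- res$p; dir[i] <- res$direction
  }
  cls <- if (!ok) "indeterminate" else {
    sig <- !is.na(p) & p < a_eff
    as_gt_aw <- sig["AS_AW"] && dir["AS_AW"] > 0
    aw_gt_as <- sig["AS_AW"] && dir["AS_AW"] < 0
    as_gt_bq <- sig["AS_BQ"] && dir["AS_BQ"] > 0
    aw_gt_bq <- sig["AW_BQ"] && dir["AW_BQ"] > 0
    if (as_gt_aw && as_gt_bq) "AS-on"
    else if (aw_gt_as && aw_gt_bq) "AW-on"
    else if (!sig["AS_AW"] && as_gt_bq && aw_gt_bq) "AS+AW-on"
    else if (!any(sig)) "state-independent"
    else "unclassified"
  }
  structure(list(unit_id = profile$unit_id, class = cls,
                 p_AS_AW = p[["AS_AW"]], p_AS_BQ = p[["AS_BQ"]],
                 p_AW_BQ = p[["AW_BQ"]],
                 mean_rate = profile$mean_rate, alpha = a_eff,
                 pairing = pairing),
            class = "state_class")
}

#' @export
print.state_class <- function(x, ...) {
  cat(sprintf("<state_class> unit=%s: %s (p AS/AW=%.3g, AS/BQ=%.3g, AW/BQ=%.3g)\n",
              x$unit_id, x$class, x$p_AS_AW, x$p_AS_BQ, x$p_AW_BQ))
  invisible(x)
}
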