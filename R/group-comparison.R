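#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Pearson's chi-squared with 1 degree of freedom and \emph{no} continuity
#' correction (Yates' correction would not reproduce the uncorrected
#' statistics this analysis reports). Rows are groups, columns are
#' outcome yes/no.
#'
#' @param a,b First row (group 1: yes, no).
#' @param c,d Second row (group 2: yes, no). Alternatively pass a 2x2
#'   matrix as `a`.
#' @return List with `statistic`, `df` (always 1), `p`, `N`, `table`.
#' @export
chi_squared_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2L, 2L)
  if (!identical(dim(tab), c(2L, 2L)))
    stop("chi_squared_2x2: need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("chi_squared_2x2: counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi_squared_2x2: degenerate margins (zero row or column total)")
  # small expected counts are routine at these unit numbers; the
  # asymptotic caveat is inherent to the test as used
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = 1L,
       p = ht$p.value, N = sum(tab), table = tab)
}

#' Mann-Whitney U test with outlier exclusion
#'
#' Removes, once per group, values lying beyond `outlier_sd` standard
#' deviations of their own group, then computes the Mann-Whitney U
#' statistic, the tie-corrected normal Z, and the two-sided p-value.
#'
#' @param x,y Numeric samples for the two groups.
#' @param outlier_sd Exclusion multiple (default 3); `Inf` disables it.
#' @param group_names Labels for the two groups.
#' @return An object of class `two_group_result`: `U` (the smaller of the
#'   two U statistics), `U_x` (U for the first group), `Z`, `p`, per-group
#'   `n`, medians, and the excluded values.
#' @export
mann_whitney <- function(x, y, outlier_sd = 3,
                         group_names = c("A", "B")) {
  drop_outliers <- function(v) {
    if (!is.finite(outlier_sd) || length(v) < 3L)
      return(list(v = v, out = numeric(0)))
    mu <- mean(v); sdv <- stats::sd(v)
    bad <- sdv > 0 & abs(v - mu) > outlier_sd * sdv
    list(v = v[!bad], out = v[bad])
  }
  dx <- drop_outliers(x); dy <- drop_outliers(y)
  x <- dx$v; y <- dy$v
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    stop("mann_whitney: need at least 2 values per group after exclusion")
  r <- rank(c(x, y))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  mu <- n1 * n2 / 2
  nt <- n1 + n2
  ties <- table(c(x, y))
  sig2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
  if (sig2 <= 0) {
    Z <- 0; p <- 1
  } else {
    Z <- (U1 - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(Z))
  }
  structure(list(U = min(U1, U2), U_x = U1, Z = Z, p = min(p, 1),
                 n = stats::setNames(c(n1, n2), group_names),
                 median = stats::setNames(c(stats::median(x),
                                            stats::median(y)), group_names),
                 excluded = stats::setNames(list(dx$out, dy$out),
                                            group_names),
                 outlier_sd = outlier_sd),
            class = "two_group_result")
}

#' @export
print.two_group_result <- function(x, ...) {
  cat(sprintf("<two_group_result> U=%.1f, Z=%.2f, p=%.3g; n=%d/%d, medians %.3g vs %.3g%s\n",
              x$U, x$Z, x$p, x$n[1L], x$n[2L], x$median[1L], x$median[2L],
              if (sum(lengths(x$excluded))) sprintf(" (%d outlier(s) excluded)",
                                                    sum(lengths(x$excluded))) else ""))
  invisible(x)
}

twitch_trains_of <- function(sess) {
  sess$events[grepl("^twitch", vapply(sess$events, `[[`, "", "label"))]
}

#' Two-group comparison battery for twitch-triggered activity
#'
#' Runs the saline-vs-drug comparison pipeline across two groups of
#' sessions: (1) time in active sleep and twitches per minute of AS per
#' pup (Mann-Whitney); (2) per-unit AS firing rate (Mann-Whitney with
#' outlier exclusion); (3) per-unit peak-normalized PSTHs averaged per
#' group; (4) per-unit jitter significance, chi-squared on the proportion
#' of significant units and on the proportion with a sharp peak within
#' +/-10 ms; (5) pooled PSTHs of significant units per group with
#' simultaneous bands and exponential smoothing; (6) per-unit area under
#' the curve in the +/-10 ms and 20-200 ms windows (Mann-Whitney with
#' outlier exclusion per window).
#'
#' Sessions must carry scored states and twitch event trains (labels
#' beginning `twitch_`); sessions with EMG but no states are scored first
#' via [score_session()].
#'
#' @param sessions List of [session] objects with `group` labels.
#' @param groups Character vector of the two group labels to compare.
#' @param config An [analysis_config]; the apamin-style analysis uses
#'   10-ms bins and `alpha = 0.05` bands by default.
#' @param band_alpha Alpha for the per-unit and pooled jitter tests
#'   (default 0.05).
#' @param auc_mode `"per_event"` or `"counts"` for the AUC comparison.
#' @return An object of class `group_comparison`: a list of result tables
#'   (`behaviour`, `as_rate`, `unit_table`, `proportions`, `auc`,
#'   `normalized`, `pooled`) plus a `log` of exclusions and skipped steps.
#' @export
compare_groups <- function(sessions, groups = c("saline", "apamin"),
                           config = analysis_config(band_alpha = 0.05),
                           band_alpha = config$band_alpha,
                           auc_mode = c("per_event", "counts")) {
  auc_mode <- match.arg(auc_mode)
  set.seed(config$rng_seed)
  glab <- vapply(sessions, `[[`, "", "group")
  if (!all(groups %in% glab))
    stop(sprintf("compare_groups: missing group(s): %s",
                 paste(setdiff(groups, glab), collapse = ", ")))
  sessions <- sessions[glab %in% groups]
  glab <- glab[glab %in% groups]
  log <- character(0)

  # ensure states + twitches
  for (i in seq_along(sessions)) {
    if (is.null(sessions[[i]]$states)) {
      if (!length(sessions[[i]]$emg))
        stop(sprintf("compare_groups: session '%s' has neither states nor EMG",
                     sessions[[i]]$id))
      sessions[[i]] <- score_session(sessions[[i]], config)
      log <- c(log, sprintf("session %s scored from EMG", sessions[[i]]$id))
    }
    if (!length(twitch_trains_of(sessions[[i]])))
      stop(sprintf("compare_groups: session '%s' has no twitch events",
                   sessions[[i]]$id))
  }

  # (1) behaviour per pup
  beh <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    as_t <- state_times(s$states)[["AS"]]
    ntw <- sum(vapply(twitch_trains_of(s), function(e)
      length(e$times), 0L))
    data.frame(session = s$id, group = s$group, as_time_s = as_t,
               twitch_per_min_as = if (as_t > 0) ntw / (as_t / 60) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  mw_or_null <- function(x, y, sd_mult = config$outlier_sd) {
    if (length(x) >= 2L && length(y) >= 2L)
      mann_whitney(x, y, outlier_sd = sd_mult, group_names = groups)
    else NULL
  }
  beh_tests <- list(
    as_time = mw_or_null(beh$as_time_s[beh$group == groups[1L]],
                         beh$as_time_s[beh$group == groups[2L]], Inf),
    twitch_rate = mw_or_null(beh$twitch_per_min_as[beh$group == groups[1L]],
                             beh$twitch_per_min_as[beh$group == groups[2L]],
                             Inf))

  # per-unit quantities
  unit_rows <- list(); unit_psths <- list(); unit_data <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    tw <- twitch_trains_of(s)
    as_t <- state_times(s$states)[["AS"]]
    as_b <- state_bouts(s$states, "AS")
    for (u in s$spikes) {
      n_as <- sum(findInterval(as_b$end - 1e-12, u$times) -
                    findInterval(as_b$start - 1e-12, u$times))
      as_rate <- if (as_t > 0) n_as / as_t else NA_real_
      # per-muscle jitter tests; keep the strongest significant muscle
      jts <- lapply(tw, function(e)
        jitter_test(u, e, window = config$psth_window,
                    bin_width = config$bin_width,
                    delta = config$jitter_window,
                    n_surrogates = config$n_surrogates,
                    alpha = band_alpha))
      resp <- lapply(jts, function(j) classify_response(j$psth, j$bands))
      sel <- select_strongest_muscle(resp, lapply(jts, `[[`, "psth"))
      chosen <- if (is.na(sel$muscle)) names(tw)[1L] else sel$muscle
      jt <- jts[[chosen]]
      rc <- resp[[chosen]]
      sharp <- "cd" %in% rc$significant_windows
      unit_rows[[length(unit_rows) + 1L]] <- data.frame(
        session = s$id, group = s$group, unit_id = u$unit_id,
        muscle = chosen, as_rate_hz = as_rate,
        significant = jt$significant, sharp_cd_peak = sharp,
        auc_cd = area_under_curve(jt$psth, config$auc_cd_window,
                                  mode = auc_mode),
        auc_reafferent = area_under_curve(jt$psth,
                                          config$auc_reafferent_window,
                                          mode = auc_mode),
        stringsAsFactors = FALSE)
      unit_psths[[length(unit_psths) + 1L]] <- jt$psth
      unit_data[[length(unit_data) + 1L]] <-
        list(spikes = u, events = tw[[chosen]], group = s$group,
             significant = jt$significant)
    }
  }
  if (!length(unit_rows)) stop("compare_groups: no units found")
  units <- do.call(rbind, unit_rows)

  in_g <- lapply(groups, function(g) which(units$group == g))
  names(in_g) <- groups

  # (2) AS firing rate across groups
  as_rate_test <- mw_or_null(units$as_rate_hz[in_g[[1L]]],
                             units$as_rate_hz[in_g[[2L]]])

  # (3) normalized average per group
  normalized <- lapply(groups, function(g) {
    ps <- unit_psths[units$group == g]
    tryCatch(normalize_and_average(ps), error = function(e) NULL)
  })
  names(normalized) <- groups

  # (4) proportions
  prop_test <- function(flag) {
    tab <- vapply(groups, function(g)
      c(sum(units[[flag]][units$group == g]),
        sum(!units[[flag]][units$group == g])), numeric(2L))
    tab <- t(tab)
    tryCatch(chi_squared_2x2(tab), error = function(e) {
      log <<- c(log, sprintf("chi-squared on '%s' skipped: %s", flag,
                             conditionMessage(e)))
      NULL
    })
  }
  proportions <- list(significant = prop_test("significant"),
                      sharp_cd_peak = prop_test("sharp_cd_peak"))

  # (5) pooled significant units per group
  pooled <- lapply(groups, function(g) {
    sel <- vapply(unit_data, function(d)
      d$group == g && d$significant, TRUE)
    if (!any(sel)) {
      log <<- c(log, sprintf("no significant units in group '%s'; pooling skipped", g))
      return(NULL)
    }
    pl <- pool_units(unit_data[sel], window = config$psth_window,
                     bin_width = config$bin_width,
                     delta = config$jitter_window,
                     n_surrogates = config$n_surrogates,
                     alpha = band_alpha)
    pl$smoothed_rate <- smooth_psth(pl$psth, tau = config$pooled_smooth_tau)
    pl
  })
  names(pooled) <- groups

  # (6) AUC comparisons per window
  auc_tests <- list(
    cd = mw_or_null(units$auc_cd[in_g[[1L]]], units$auc_cd[in_g[[2L]]]),
    reafferent = mw_or_null(units$auc_reafferent[in_g[[1L]]],
                            units$auc_reafferent[in_g[[2L]]]))

  structure(list(groups = groups, behaviour = beh,
                 behaviour_tests = beh_tests, unit_table = units,
                 as_rate_test = as_rate_test, normalized = normalized,
                 proportions = proportions, pooled = pooled,
                 auc_tests = auc_tests, config = config,
                 band_alpha = band_alpha, auc_mode = auc_mode, log = log),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s: %d units (%s)\n",
              x$groups[1L], x$groups[2L], nrow(x$unit_table),
              paste(sprintf("%s n=%d", x$groups,
                            tabulate(factor(x$unit_table$group,
                                            levels = x$groups))),
                    collapse = ", ")))
  if (!is.null(x$proportions$significant))
    cat(sprintf("  significant units: chi2=%.2f p=%.3g\n",
                x$proportions$significant$statistic,
                x$proportions$significant$p))
  if (!is.null(x$proportions$sharp_cd_peak))
    cat(sprintf("  sharp +/-10 ms peaks: chi2=%.2f p=%.3g\n",
                x$proportions$sharp_cd_peak$statistic,
                x$proportions$sharp_cd_peak$p))
  for (w in names(x$auc_tests))
    if (!is.null(x$auc_tests[[w]]))
      cat(sprintf("  AUC %s: U=%.1f Z=%.2f p=%.3g\n", w,
                  x$auc_tests[[w]]$U, x$auc_tests[[w]]$Z,
                  x$auc_tests[[w]]$p))
  invisible(x)
}
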