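#' Interval-jitter surrogate event trains
#'
#' Partitions the session into contiguous cells of width `delta` and
#' redraws each event uniformly within its own cell, independently for each
#' surrogate. The event count per cell — and hence the total — is preserved
#' exactly, so coarse rate structure survives while fine-timescale locking
#' is destroyed. The final cell may be truncated by the session end; events
#' in it are redrawn within the truncated cell.
#'
#' @param events An [event_train].
#' @param delta Jitter cell width, s (default 0.5).
#' @param n_surrogates Number of surrogates S (default 1000).
#' @param seed Optional integer seed (uses current RNG state if `NULL`).
#' @return An object of class `jitter_surrogates`: original times, cell
#'   geometry, and an `n_events x S` matrix `jit` of redrawn times (column
#'   j is surrogate j). Use [surrogate_train()] to extract one surrogate as
#'   an [event_train].
#' @export
jitter_surrogates <- function(events, delta = 0.500, n_surrogates = 1000,
                              seed = NULL) {
  if (!inherits(events, "event_train"))
    stop("jitter_surrogates: 'events' must be an event_train")
  if (delta <= 0) stop("jitter_surrogates: 'delta' must be positive")
  S <- as.integer(n_surrogates)
  if (S < 1L) stop("jitter_surrogates: need at least one surrogate")
  if (!is.null(seed)) set.seed(seed)
  ev <- events$times
  dur <- events$session_duration
  cell <- floor(ev / delta)
  cs <- cell * delta
  cw <- pmin(delta, dur - cs)
  cw[cw < 0] <- 0
  ne <- length(ev)
  jit <- matrix(stats::runif(ne * S), ne, S) * cw + cs
  structure(list(times = ev, duration = dur, delta = delta, S = S,
                 cell_start = cs, cell_width = cw, jit = jit),
            class = "jitter_surrogates")
}

#' @export
print.jitter_surrogates <- function(x, ...) {
  cat(sprintf("<jitter_surrogates> %d events, S=%d, delta=%g s\n",
              length(x$times), x$S, x$delta))
  invisible(x)
}

#' Extract one surrogate as an event train
#' @param surr A [jitter_surrogates] object.
#' @param j Surrogate index (1..S).
#' @return An [event_train] with the j-th surrogate's (sorted) times.
#' @export
surrogate_train <- function(surr, j) {
  t <- sort(surr$jit[, j])
  # ties have probability zero but would violate strict monotonicity
  while (any(diff(t) <= 0)) t <- sort(t + c(0, cumsum(diff(t) <= 0)) * 1e-12)
  event_train(t, "surrogate", surr$duration)
}

#' Perievent histogram counts of every surrogate
#'
#' Computes, for each surrogate event train, the same lag histogram that
#' [build_psth()] computes for the original events. Vectorized across
#' surrogates in blocks.
#'
#' @param spikes A [spike_train] or numeric spike times.
#' @param surr A [jitter_surrogates] object.
#' @param window Window length, s.
#' @param bin_width Bin width, s.
#' @return Integer matrix `n_bins x S` of counts.
#' @export
surrogate_psth_counts <- function(spikes, surr, window = 1,
                                  bin_width = 0.010) {
  sp <- if (inherits(spikes, "spike_train")) spikes$times else as.numeric(spikes)
  half <- window / 2
  B <- as.integer(round(window / bin_width))
  if (!length(sp) || !length(surr$times)) return(matrix(0L, B, surr$S))
  cs <- surr$cell_start; cw <- surr$cell_width
  lo <- findInterval(cs - half - bin_width, sp)
  hi <- findInterval(cs + cw + half + bin_width, sp)
  jitter_lag_counts(sp, lo, hi, surr$jit, half, bin_width, B)
}

# Pure-R reference for jitter_lag_counts (independent of the compiled
# path; used to cross-check it).
surrogate_psth_counts_ref <- function(spikes, surr, window = 1,
                                      bin_width = 0.010) {
  sp <- if (inherits(spikes, "spike_train")) spikes$times else as.numeric(spikes)
  half <- window / 2
  B <- as.integer(round(window / bin_width))
  out <- matrix(0L, B, surr$S)
  for (j in seq_len(surr$S)) {
    lag <- as.vector(outer(sp, surr$jit[, j], "-"))
    bin <- floor((lag + half) / bin_width) + 1
    out[, j] <- tabulate(bin[bin >= 1 & bin <= B], B)
  }
  out
}

#' Simultaneous confidence bands from jitter surrogates
#'
#' Builds per-bin upper and lower acceptance limits calibrated so that the
#' probability that ANY analyzed bin of a null-consistent histogram falls
#' outside the band is at most `alpha` (family-wise control). Each bin is
#' studentized by its surrogate mean and SD; each surrogate's maximum
#' absolute studentized deviation across the analyzed bins is a single
#' continuous statistic, and the band height `t*` is its permutation
#' critical value at depth `floor(alpha * (S + 1))` (the observed
#' histogram counts as one member of the exchangeable pool, so the test
#' "any bin outside mean +/- t* SD" has family-wise level at most `alpha`
#' by exchangeability). Upper and lower limits share the budget, so a
#' breach on either side counts against the same `alpha`. Per-bin SDs are
#' floored at half a count to keep degenerate (constant) bins finite.
#'
#' @param psth The observed `psth`.
#' @param surrogate_counts `n_bins x S` matrix from
#'   [surrogate_psth_counts()], built with identical binning.
#' @param alpha Family-wise error level (needs `S >= 1/alpha - 1`).
#' @param span Optional `(lo, hi)` lag span (s) restricting the analyzed
#'   bins; bins outside it get `NA` bands and are never flagged.
#' @return An object of class `jitter_bands`: `upper`, `lower` (per bin),
#'   `alpha`, `t_crit` (band height in studentized units),
#'   `surrogate_mean`, `surrogate_sd`, `analyzed` (logical per bin),
#'   `escape_fraction` (fraction of surrogates outside their own band).
#' @export
simultaneous_bands <- function(psth, surrogate_counts, alpha = 0.01,
                               span = NULL) {
  M <- surrogate_counts
  B <- length(psth$counts)
  if (nrow(M) != B)
    stop("simultaneous_bands: surrogate histograms do not match the observed binning")
  S <- ncol(M)
  depth <- floor(alpha * (S + 1) + 1e-9)
  if (depth < 1L)
    stop(sprintf("simultaneous_bands: S = %d is too small for alpha = %g (need S >= 1/alpha - 1)", S, alpha))
  analyzed <- rep(TRUE, B)
  if (!is.null(span)) {
    l <- psth$bin_edges[-(B + 1L)]; r <- psth$bin_edges[-1L]
    analyzed <- l >= span[1L] - 1e-9 & r <= span[2L] + 1e-9
    if (!any(analyzed))
      stop("simultaneous_bands: analysis span contains no bins")
  }
  # studentizing moments over the full exchangeable pool (surrogates plus
  # the observed histogram), so observed and surrogates are symmetric
  pool <- cbind(M, psth$counts)
  mu <- rowMeans(pool)
  sdv <- sqrt(pmax(rowMeans(pool^2) - mu^2, 0) * (S + 1) / S)
  sdv_f <- pmax(sdv, 0.5)   # floor: half a count
  ab <- which(analyzed)
  Z <- abs(M[ab, , drop = FALSE] - mu[ab]) / sdv_f[ab]
  T_s <- apply(Z, 2L, max)
  t_crit <- sort(T_s, decreasing = TRUE)[depth]
  upper <- rep(NA_real_, B); lower <- rep(NA_real_, B)
  upper[ab] <- mu[ab] + t_crit * sdv_f[ab]
  lower[ab] <- pmax(mu[ab] - t_crit * sdv_f[ab], 0)
  structure(list(upper = upper, lower = lower, alpha = alpha,
                 t_crit = t_crit, n_surrogates = S,
                 surrogate_mean = mu, surrogate_sd = sdv,
                 analyzed = analyzed,
                 escape_fraction = sum(T_s > t_crit) / S),
            class = "jitter_bands")
}

#' @export
print.jitter_bands <- function(x, ...) {
  cat(sprintf("<jitter_bands> alpha=%g, S=%d, t*=%.2f, surrogate escape=%.4f\n",
              x$alpha, x$n_surrogates, x$t_crit, x$escape_fraction))
  invisible(x)
}

#' Does the observed histogram breach its bands?
#' @param psth The observed `psth`.
#' @param bands A `jitter_bands` object for it.
#' @return List of logical per-bin vectors `above` and `below` (never `TRUE`
#'   outside the analyzed span).
#' @export
band_breach <- function(psth, bands) {
  above <- psth$counts > bands$upper & bands$analyzed
  below <- psth$counts < bands$lower & bands$analyzed
  above[is.na(above)] <- FALSE
  below[is.na(below)] <- FALSE
  list(above = above, below = below)
}

#' Full jitter significance test for one unit and one trigger
#'
#' Convenience wrapper: observed PSTH, interval-jitter surrogates,
#' surrogate histograms, and simultaneous bands.
#'
#' @param spikes A [spike_train].
#' @param events An [event_train].
#' @param window,bin_width Histogram geometry, s.
#' @param delta Jitter cell width, s.
#' @param n_surrogates Number of surrogates.
#' @param alpha Family-wise alpha for the bands.
#' @param span Optional analysis span passed to [simultaneous_bands()].
#' @param seed Optional integer seed.
#' @return List with `psth`, `bands`, `breach` (from [band_breach()]) and
#'   `significant` (any analyzed bin outside the band).
#' @export
jitter_test <- function(spikes, events, window = 1, bin_width = 0.010,
                        delta = 0.500, n_surrogates = 1000, alpha = 0.01,
                        span = NULL, seed = NULL) {
  psth <- build_psth(spikes, events, window = window, bin_width = bin_width)
  surr <- jitter_surrogates(events, delta = delta,
                            n_surrogates = n_surrogates, seed = seed)
  M <- surrogate_psth_counts(spikes, surr, window = window,
                             bin_width = bin_width)
  bands <- simultaneous_bands(psth, M, alpha = alpha, span = span)
  br <- band_breach(psth, bands)
  list(psth = psth, bands = bands, breach = br,
       significant = any(br$above) || any(br$below))
}

#' Latency-window classification of a perievent response
#'
#' Assigns significance to the three latency windows of the corollary-
#' discharge taxonomy: premotor (more than 10 ms before event onset),
#' cd (within +/-10 ms), reafferent (more than 10 ms after). A window is
#' significant iff at least one of its bins lies above the upper band
#' (excitation); bins below the lower band are flagged separately as
#' suppression. Also records the peak bin, the latency of the first
#' breaching bin, and the primary window (the significant window holding
#' the largest breaching bin).
#'
#' @param psth The observed `psth`.
#' @param bands Its `jitter_bands`.
#' @param windows Named list of `(start, end)` lag windows in seconds;
#'   default the standard three.
#' @return An object of class `response_class`.
#' @export
classify_response <- function(psth, bands,
                              windows = list(premotor = c(-0.500, -0.010),
                                             cd = c(-0.010, 0.010),
                                             reafferent = c(0.010, 0.500))) {
  br <- band_breach(psth, bands)
  B <- length(psth$counts)
  l <- psth$bin_edges[-(B + 1L)]; r <- psth$bin_edges[-1L]
  centers <- psth_centers(psth)
  win_of_bin <- rep(NA_character_, B)
  sig <- character(0); sup <- character(0)
  for (w in names(windows)) {
    inw <- l >= windows[[w]][1L] - 1e-9 & r <= windows[[w]][2L] + 1e-9
    win_of_bin[inw] <- w
    if (any(br$above & inw)) sig <- c(sig, w)
    if (any(br$below & inw)) sup <- c(sup, w)
  }
  any_above <- any(br$above)
  peak_bin <- if (sum(psth$counts) > 0) which.max(psth$counts) else NA_integer_
  first_lat <- if (any_above) centers[which(br$above)[1L]] else NA_real_
  primary <- NA_character_
  if (any_above) {
    cand <- which(br$above)
    top <- cand[which.max(psth$counts[cand])]
    primary <- win_of_bin[top]
  }
  structure(list(unit_id = if (is.null(psth$units)) NA_character_ else
                   paste(psth$units, collapse = "+"),
                 trigger = psth$trigger,
                 significant_windows = sig,
                 suppressed_windows = sup,
                 primary_window = primary,
                 peak_bin_center = if (is.na(peak_bin)) NA_real_ else
                   centers[peak_bin],
                 peak_rate = max(psth_rate(psth)),
                 first_breach_latency = first_lat,
                 muscle = NA_character_),
            class = "response_class")
}

#' @export
print.response_class <- function(x, ...) {
  cat(sprintf("<response_class> unit=%s trigger=%s: significant={%s} primary=%s peak at %+.0f ms\n",
              x$unit_id, x$trigger,
              paste(x$significant_windows, collapse = ","),
              x$primary_window,
              1000 * x$peak_bin_center))
  invisible(x)
}

#' Select the muscle with the strongest twitch relationship
#'
#' Among muscles whose response is significant, picks the one whose PSTH
#' peak firing rate is highest; ties break by total in-window spike count,
#' then by the (fixed) order of the supplied list.
#'
#' @param responses Named list of `response_class` objects, one per muscle.
#' @param psths Named list of the matching `psth` objects.
#' @return List with `muscle` (chosen name, or `NA` if no muscle is
#'   significant — the unit is non-responsive) and `reason` (`"peak_rate"`,
#'   `"total_count"` or `"order"`).
#' @export
select_strongest_muscle <- function(responses, psths) {
  stopifnot(length(responses) == length(psths))
  nm <- names(responses)
  sig <- vapply(responses, function(r)
    length(r$significant_windows) > 0L, TRUE)
  if (!any(sig)) return(list(muscle = NA_character_, reason = "none_significant"))
  cand <- which(sig)
  pk <- vapply(cand, function(i) max(psth_rate(psths[[i]])), 0)
  best <- cand[pk >= max(pk) - 1e-12]
  reason <- "peak_rate"
  if (length(best) > 1L) {
    tot <- vapply(best, function(i) sum(psths[[i]]$counts), 0)
    best <- best[tot == max(tot)]
    reason <- "total_count"
  }
  if (length(best) > 1L) reason <- "order"
  list(muscle = nm[best[1L]], reason = reason)
}

#' Pool significant units into one histogram with a pooled jitter test
#'
#' Sums per-unit PSTH counts bin by bin (each unit triggered on its own
#' event train) and re-runs the jitter test on the pooled histogram by
#' jittering each unit's events independently and summing the surrogate
#' histograms.
#'
#' @param units List of `list(spikes=, events=)` pairs.
#' @param window,bin_width Histogram geometry, s.
#' @param delta Jitter cell width, s.
#' @param n_surrogates Number of surrogates.
#' @param alpha Family-wise alpha.
#' @param span Optional analysis span.
#' @param seed Optional integer seed.
#' @return List with pooled `psth`, `bands`, `breach`, `significant`.
#' @export
pool_units <- function(units, window = 1, bin_width = 0.010, delta = 0.500,
                       n_surrogates = 1000, alpha = 0.05, span = NULL,
                       seed = NULL) {
  if (!length(units)) stop("pool_units: empty unit list")
  if (!is.null(seed)) set.seed(seed)
  B <- as.integer(round(window / bin_width))
  counts <- integer(B)
  M <- matrix(0L, B, n_surrogates)
  n_events <- 0L
  ids <- character(0)
  trigger <- NULL
  for (u in units) {
    p <- build_psth(u$spikes, u$events, window = window,
                    bin_width = bin_width)
    counts <- counts + p$counts
    n_events <- n_events + p$n_events
    ids <- c(ids, if (is.null(p$units)) "unit" else p$units)
    if (is.null(trigger)) trigger <- p$trigger
    surr <- jitter_surrogates(u$events, delta = delta,
                              n_surrogates = n_surrogates)
    M <- M + surrogate_psth_counts(u$spikes, surr, window = window,
                                   bin_width = bin_width)
  }
  pooled <- structure(list(trigger = trigger, units = ids,
                           bin_edges = (seq_len(B + 1L) - B / 2 - 1L) * bin_width,
                           counts = counts, n_events = n_events,
                           bin_width = bin_width, window = window,
                           n_truncated = NA_integer_),
                      class = "psth")
  bands <- simultaneous_bands(pooled, M, alpha = alpha, span = span)
  br <- band_breach(pooled, bands)
  list(psth = pooled, bands = bands, breach = br,
       significant = any(br$above) || any(br$below))
}

#' Evoked response to exafferent stimulation
#'
#' Perievent histogram (default 20-ms bins) of unit activity triggered on
#' stimulation onsets, with the jitter test, plus the response latency:
#' the centre of the first post-onset bin above the upper band. Warns when
#' stimulation intervals fall below 5 s (protocol deviation).
#'
#' @param spikes A [spike_train].
#' @param stim_events An [event_train] of stimulation onsets.
#' @param bin_width Bin width, s (default 0.020).
#' @param window Window length, s.
#' @param min_events Minimum number of stimulations required (default 10).
#' @param min_interval Expected minimum stimulus spacing, s (default 5).
#' @param delta,n_surrogates,alpha,seed Jitter-test parameters.
#' @return List with `psth`, `bands`, `breach`, `significant`, `latency`
#'   (s, `NA` if no post-onset bin is significant).
#' @export
evoked_response <- function(spikes, stim_events, bin_width = 0.020,
                            window = 1, min_events = 10, min_interval = 5,
                            delta = 0.500, n_surrogates = 1000,
                            alpha = 0.05, seed = NULL) {
  if (length(stim_events$times) < min_events)
    stop(sprintf("evoked_response: need at least %d stimulations, got %d",
                 min_events, length(stim_events$times)))
  if (length(stim_events$times) > 1L &&
      min(diff(stim_events$times)) < min_interval)
    warning("evoked_response: stimulation intervals below the expected minimum spacing")
  jt <- jitter_test(spikes, stim_events, window = window,
                    bin_width = bin_width, delta = delta,
                    n_surrogates = n_surrogates, alpha = alpha, seed = seed)
  centers <- psth_centers(jt$psth)
  post <- jt$breach$above & centers > 0
  jt$latency <- if (any(post)) centers[which(post)[1L]] else NA_real_
  jt
}
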