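#' Rectify and smooth an EMG signal
#'
#' Full-wave rectification followed by smoothing. The default smoother is a
#' causal first-order exponential filter with time constant `tau`
#' (`y[n] = a*|x[n]| + (1-a)*y[n-1]`, `a = 1 - exp(-dt/tau)`); a centred
#' boxcar of width `tau` is available as an alternative. Output has the
#' same rate and length as the input and is flagged rectified.
#'
#' @param signal A [sampled_signal].
#' @param tau Smoothing time constant in seconds (> 0). Default 1 ms.
#' @param filter Smoother type: `"exponential"` (causal, default) or
#'   `"boxcar"` (centred running mean of width `tau`).
#' @return A rectified, smoothed [sampled_signal].
#' @export
rectify_smooth <- function(signal, tau = 0.001,
                           filter = c("exponential", "boxcar")) {
  filter <- match.arg(filter)
  if (!inherits(signal, "sampled_signal"))
    stop("rectify_smooth: 'signal' must be a sampled_signal")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("rectify_smooth: 'tau' must be a positive scalar")
  x <- abs(signal$samples)
  dt <- 1 / signal$rate
  if (filter == "exponential") {
    a <- 1 - exp(-dt / tau)
    # recursive filter seeded with the first rectified sample
    y <- as.numeric(stats::filter(a * x, 1 - a, method = "recursive",
                                  init = x[1L]))
  } else {
    w <- max(1L, round(tau / dt))
    k <- rep(1 / w, w)
    y <- as.numeric(stats::filter(x, k, method = "convolution", sides = 2))
    # edge samples where the kernel runs off the record: shrink the kernel
    nas <- which(is.na(y))
    for (i in nas) {
      lo <- max(1L, i - (w %/% 2)); hi <- min(length(x), lo + w - 1L)
      y[i] <- mean(x[lo:hi])
    }
  }
  sampled_signal(y, rate = signal$rate, channel = signal$channel,
                 t0 = signal$t0, rectified = TRUE)
}

#' Estimate the wake/sleep EMG threshold
#'
#' Computes the mean amplitude of high muscle tone and of atonia from
#' representative fixed-length segments of the rectified-smoothed trace and
#' returns their arithmetic midpoint as the scoring threshold. By default
#' segments are selected automatically: non-overlapping windows are ranked
#' by mean amplitude; the `n_segments` highest-mean windows give the
#' high-tone class and the `n_segments` lowest give the atonia class, after
#' discarding windows dominated by brief transients (peak-to-mean ratio
#' above `transient_ratio`). Manually chosen segments override selection.
#'
#' @param signal A rectified [sampled_signal] (see [rectify_smooth()]).
#' @param n_segments Number of representative segments per class (default 5).
#' @param seg_len Segment length in seconds (default 1).
#' @param manual_segments Optional list with elements `high` and `atonia`,
#'   each a two-column matrix/data.frame of (start, end) times in seconds.
#' @param transient_ratio Windows whose max/mean exceeds this are excluded
#'   from automatic selection (default 4).
#' @return An object of class `threshold_estimate` with fields `mean_high`,
#'   `mean_atonia`, `threshold`, `segments_used`.
#' @export
estimate_threshold <- function(signal, n_segments = 5, seg_len = 1,
                               manual_segments = NULL, transient_ratio = 4) {
  if (!inherits(signal, "sampled_signal"))
    stop("estimate_threshold: 'signal' must be a sampled_signal")
  if (!signal$rectified)
    stop("estimate_threshold: signal must be rectified (see rectify_smooth)")
  dur <- signal_duration(signal)
  if (is.null(manual_segments) && dur < 2 * n_segments * seg_len)
    stop("estimate_threshold: signal too short for requested segments")
  seg_mean <- function(seg) {
    i0 <- floor((seg[1L] - signal$t0) * signal$rate) + 1L
    i1 <- ceiling((seg[2L] - signal$t0) * signal$rate)
    if (i0 < 1L || i1 > length(signal$samples) || i1 <= i0)
      stop("estimate_threshold: segment out of range")
    mean(signal$samples[i0:i1])
  }
  if (!is.null(manual_segments)) {
    hs <- as.matrix(manual_segments$high)
    as_ <- as.matrix(manual_segments$atonia)
    segs <- rbind(hs, as_)
    o <- order(segs[, 1L])
    if (any(segs[o, 1L][-1L] < segs[o, 2L][-nrow(segs)]))
      stop("estimate_threshold: manual segments overlap")
    mh <- mean(apply(hs, 1L, seg_mean))
    ma <- mean(apply(as_, 1L, seg_mean))
    used <- list(high = hs, atonia = as_)
  } else {
    n_win <- floor(dur / seg_len)
    starts <- signal$t0 + (seq_len(n_win) - 1L) * seg_len
    spw <- round(seg_len * signal$rate)
    idx0 <- (seq_len(n_win) - 1L) * spw
    means <- vapply(seq_len(n_win), function(i)
      mean(signal$samples[(idx0[i] + 1L):(idx0[i] + spw)]), 0)
    maxs <- vapply(seq_len(n_win), function(i)
      max(signal$samples[(idx0[i] + 1L):(idx0[i] + spw)]), 0)
    ok <- maxs <= transient_ratio * means
    if (sum(ok) < 2 * n_segments)
      stop("estimate_threshold: too few transient-free windows")
    cand <- which(ok)
    ord <- cand[order(means[cand])]
    lo <- ord[seq_len(n_segments)]
    hi <- rev(ord)[seq_len(n_segments)]
    mh <- mean(means[hi]); ma <- mean(means[lo])
    used <- list(high = cbind(starts[hi], starts[hi] + seg_len),
                 atonia = cbind(starts[lo], starts[lo] + seg_len))
  }
  if (!(mh > ma) || !isTRUE((mh - ma) > 1e-12 * max(mh, 1)))
    stop("estimate_threshold: cannot distinguish tone classes (high mean not above atonia mean)")
  structure(list(mean_high = mh, mean_atonia = ma,
                 threshold = (mh + ma) / 2, segments_used = used),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> high=%.4g atonia=%.4g threshold=%.4g\n",
              x$mean_high, x$mean_atonia, x$threshold))
  invisible(x)
}

# Runs of supra-/sub-threshold samples with sub-min_bout runs merged into
# the preceding qualifying run (a leading short run joins the first
# qualifying run). Returns data.frame(start, end, above) on the sample grid.
threshold_runs <- function(signal, threshold, min_bout) {
  above <- signal$samples >= threshold
  r <- rle(above)
  n <- length(r$lengths)
  dt <- 1 / signal$rate
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-n])
  dur <- r$lengths * dt
  keep <- dur >= min_bout - dt / 2
  if (!any(keep))
    stop("segment_states: no run reaches the minimum bout duration")
  # assign each run to the nearest preceding qualifying run (or the first
  # following one, for a leading short run), then coalesce neighbours that
  # ended up on the same side of the threshold
  grp <- cumsum(keep)
  grp[grp == 0L] <- 1L
  qual_above <- r$values[keep]
  same <- c(FALSE, qual_above[-1L] == qual_above[-length(qual_above)])
  grp2_of_qual <- cumsum(!same)
  grp2 <- grp2_of_qual[grp]
  side <- qual_above[!same]
  # index/rate (not index * dt) so boundaries agree bit-for-bit with
  # signal_times()
  out_start <- tapply(starts, grp2, min) / signal$rate + signal$t0
  out_end <- tapply(ends, grp2, max) / signal$rate + signal$t0
  data.frame(start = as.numeric(out_start), end = as.numeric(out_end),
             above = side)
}

#' Segment behavioural states from a thresholded EMG trace
#'
#' Supra-threshold runs lasting at least `min_bout` become active wake (AW);
#' sub-threshold runs of the same minimum length become sleep. Shorter runs
#' are merged into the preceding qualifying state (so brief twitch
#' transients do not break sleep bouts, and brief dips do not break wake).
#' Each sleep run is then split at the first twitch (across all supplied
#' muscles): behavioural quiescence (BQ) from run start to that twitch, and
#' active sleep (AS) from the twitch to run end. A twitch-free sleep run is
#' all BQ.
#'
#' @param signal A rectified [sampled_signal].
#' @param twitches A list of [event_train]s of twitch onsets (may be empty
#'   or contain empty trains; all sleep is then BQ).
#' @param threshold EMG amplitude threshold (see [estimate_threshold()]).
#' @param min_bout Minimum bout duration, s (default 1).
#' @return A [state_intervals] object tiling the scored span.
#' @export
segment_states <- function(signal, twitches = list(), threshold,
                           min_bout = 1) {
  if (!inherits(signal, "sampled_signal"))
    stop("segment_states: 'signal' must be a sampled_signal")
  if (inherits(twitches, "event_train")) twitches <- list(twitches)
  tw <- sort(as.numeric(unlist(lapply(twitches, `[[`, "times"))))
  runs <- threshold_runs(signal, threshold, min_bout)
  start <- numeric(0); end <- numeric(0); lab <- character(0)
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]
    if (runs$above[i]) {
      start <- c(start, s); end <- c(end, e); lab <- c(lab, "AW")
    } else {
      first_tw <- tw[tw >= s & tw < e][1L]
      if (is.na(first_tw) || first_tw <= s) {
        if (!is.na(first_tw) && first_tw <= s) {
          start <- c(start, s); end <- c(end, e); lab <- c(lab, "AS")
        } else {
          start <- c(start, s); end <- c(end, e); lab <- c(lab, "BQ")
        }
      } else {
        start <- c(start, s, first_tw); end <- c(end, first_tw, e)
        lab <- c(lab, "BQ", "AS")
      }
    }
  }
  state_intervals(start, end, lab, threshold_used = threshold)
}

#' Detect myoclonic twitches in the rectified EMG
#'
#' Twitches are sharp EMG events during sleep whose amplitude reaches at
#' least `k` times the mean atonia baseline. The baseline is the mean of
#' the rectified-smoothed trace over the sleep mask after discarding
#' transient excursions (samples above twice an initial median estimate).
#' Onsets are upward first-crossings of `k * baseline` inside sleep
#' intervals, separated by at least `refractory` seconds. Supra-threshold
#' (wake) epochs never yield twitches.
#'
#' @param signal A rectified [sampled_signal].
#' @param sleep_mask data.frame of sleep intervals (columns `start`, `end`),
#'   or a [state_intervals] (its non-AW intervals are used).
#' @param k Criterion multiple of the atonia baseline (default 3).
#' @param refractory Minimum separation between onsets, s (default 0.2).
#' @param label Label for the returned train (default `"twitch"`).
#' @param onset `"rise_start"` (default): report the start of the rising
#'   transient (backtracked from the criterion crossing to the last sample
#'   at the atonia baseline); `"crossing"`: report the criterion-crossing
#'   sample itself.
#' @return An object of class `twitch_detection` with fields `onsets`
#'   (an [event_train]), `baseline`, `criterion` (`k * baseline`), `k`.
#' @export
detect_twitches <- function(signal, sleep_mask, k = 3, refractory = 0.200,
                            label = "twitch",
                            onset = c("rise_start", "crossing")) {
  onset <- match.arg(onset)
  if (!inherits(signal, "sampled_signal"))
    stop("detect_twitches: 'signal' must be a sampled_signal")
  if (inherits(sleep_mask, "state_intervals"))
    sleep_mask <- sleep_mask[sleep_mask$label != "AW", c("start", "end")]
  if (nrow(sleep_mask) == 0L)
    stop("detect_twitches: empty sleep mask")
  t <- signal_times(signal)
  dur <- signal$t0 + signal_duration(signal)
  in_sleep <- rep(FALSE, length(t))
  for (i in seq_len(nrow(sleep_mask)))
    in_sleep[t >= sleep_mask$start[i] & t < sleep_mask$end[i]] <- TRUE
  x <- signal$samples
  sleep_x <- x[in_sleep]
  if (!length(sleep_x)) stop("detect_twitches: sleep mask covers no samples")
  b0 <- stats::median(sleep_x)
  baseline <- mean(sleep_x[sleep_x <= 2 * b0])
  if (!is.finite(baseline) || baseline <= 0)
    baseline <- mean(sleep_x)
  crit <- k * baseline
  hot <- in_sleep & x >= crit
  onset_idx <- which(hot & !c(FALSE, hot[-length(hot)]))
  if (onset == "rise_start" && length(onset_idx)) {
    # walk back from the criterion crossing to where the transient left the
    # atonia baseline, so the reported onset is the start of the rise
    max_back <- round(0.1 * signal$rate)
    b_back <- b0   # atonia median: robust floor for the rise start
    for (j in seq_along(onset_idx)) {
      i <- onset_idx[j]
      lo <- max(1L, i - max_back)
      below <- which(x[lo:i] <= b_back)
      if (length(below) && max(below) < i - lo + 1L)
        onset_idx[j] <- lo + max(below)
    }
    onset_idx <- unique(onset_idx)
  }
  onsets <- t[onset_idx]
  if (length(onsets) > 1L) {
    keep <- rep(TRUE, length(onsets))
    last <- onsets[1L]
    for (i in seq_along(onsets)[-1L]) {
      if (onsets[i] - last < refractory) keep[i] <- FALSE else last <- onsets[i]
    }
    onsets <- onsets[keep]
  }
  structure(list(muscle = signal$channel,
                 onsets = event_train(onsets, label, dur),
                 baseline = baseline, criterion = crit, k = k),
            class = "twitch_detection")
}

#' @export
print.twitch_detection <- function(x, ...) {
  cat(sprintf("<twitch_detection> muscle=%s: %d onsets, baseline=%.4g, criterion=%.4g (k=%g)\n",
              x$muscle, length(x$onsets$times), x$baseline, x$criterion, x$k))
  invisible(x)
}

#' Detect wake-movement onsets
#'
#' One onset per active-wake bout, at the first supra-threshold sample of
#' the bout.
#'
#' @param signal A rectified [sampled_signal].
#' @param states A [state_intervals] with the scored session.
#' @param threshold EMG amplitude threshold.
#' @return An [event_train] labelled `"wake_onset"` (empty if no AW bout).
#' @export
detect_wake_onsets <- function(signal, states, threshold) {
  aw <- state_bouts(states, "AW")
  t <- signal_times(signal)
  dur <- signal$t0 + signal_duration(signal)
  onsets <- numeric(0)
  for (i in seq_len(nrow(aw))) {
    sel <- which(t >= aw$start[i] & t < aw$end[i] &
                   signal$samples >= threshold)
    if (length(sel)) onsets <- c(onsets, t[sel[1L]])
  }
  event_train(sort(onsets), "wake_onset", dur)
}

#' Score a session end to end
#'
#' Convenience wrapper running the full scoring chain on one EMG channel
#' (or several): rectify/smooth, threshold estimation, provisional sleep
#' segmentation, twitch detection per muscle, final AW/BQ/AS segmentation,
#' and wake-onset detection.
#'
#' @param sess A [session] with at least one raw or rectified EMG channel.
#' @param config An [analysis_config].
#' @return The session with `states` filled in and twitch / wake-onset
#'   event trains appended (labels `twitch_<channel>`, `wake_onset`), plus
#'   attribute `"scoring"` holding per-channel threshold and detection
#'   objects.
#' @export
score_session <- function(sess, config = analysis_config()) {
  if (!length(sess$emg)) stop("score_session: session has no EMG channel")
  smoothed <- lapply(sess$emg, rectify_smooth, tau = config$smooth_tau,
                     filter = config$smooth_filter)
  primary <- smoothed[[1L]]
  thr <- estimate_threshold(primary)
  prelim <- segment_states(primary, list(), thr$threshold,
                           min_bout = config$min_bout)
  sel <- prelim$label != "AW"
  sleep <- data.frame(start = prelim$start[sel], end = prelim$end[sel])
  detections <- lapply(smoothed, function(sig)
    detect_twitches(sig, sleep, k = config$twitch_multiplier,
                    refractory = config$refractory,
                    label = paste0("twitch_", sig$channel)))
  states <- segment_states(primary, lapply(detections, `[[`, "onsets"),
                           thr$threshold, min_bout = config$min_bout)
  wake <- detect_wake_onsets(primary, states, thr$threshold)
  sess$states <- states
  new_ev <- c(lapply(detections, `[[`, "onsets"), list(wake))
  keep <- !(vapply(sess$events, `[[`, "", "label") %in%
              vapply(new_ev, `[[`, "", "label"))
  sess$events <- c(sess$events[keep], new_ev)
  names(sess$events) <- vapply(sess$events, `[[`, "", "label")
  attr(sess, "scoring") <- list(threshold = thr, detections = detections)
  sess
}
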