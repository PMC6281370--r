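#' Sampled EMG signal
#'
#' Container for one EMG channel: an amplitude series sampled at a fixed
#' rate. Amplitude is in arbitrary units throughout the package; absolute
#' scale is never interpreted. The `rectified` flag records whether the
#' samples are a signed raw trace or a rectified envelope.
#'
#' @param samples Numeric vector of amplitude samples (finite).
#' @param rate Sampling rate in Hz (> 0).
#' @param channel Channel label, e.g. `"nuchal"`, `"forelimb_L"`.
#' @param t0 Start time in seconds on the session clock (default 0).
#' @param rectified Logical; `TRUE` if `samples` are already rectified.
#' @return An object of class `sampled_signal`.
#' @export
sampled_signal <- function(samples, rate, channel = "emg", t0 = 0,
                           rectified = FALSE) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("sampled_signal: 'rate' must be a single positive number")
  if (length(samples) == 0L)
    stop("sampled_signal: 'samples' must be non-empty (duration > 0)")
  if (!all(is.finite(samples)))
    stop("sampled_signal: all samples must be finite")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("sampled_signal: 't0' must be a single finite number")
  structure(
    list(channel = as.character(channel)[1L], rate = rate, t0 = t0,
         samples = samples, rectified = isTRUE(rectified)),
    class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> channel=%s rate=%g Hz n=%d duration=%.3f s%s\n",
              x$channel, x$rate, length(x$samples),
              length(x$samples) / x$rate,
              if (x$rectified) " (rectified)" else ""))
  invisible(x)
}

#' Duration of a sampled signal, in seconds
#' @param x A `sampled_signal`.
#' @export
signal_duration <- function(x) length(x$samples) / x$rate

#' Sample times of a sampled signal
#' @param x A `sampled_signal`.
#' @return Numeric vector of times (s), `t0 + (0:(n-1))/rate`.
#' @export
signal_times <- function(x) x$t0 + (seq_along(x$samples) - 1) / x$rate

#' Event train
#'
#' Labelled, strictly increasing event onset times (seconds) — twitch onsets
#' of one muscle, wake-movement onsets, or stimulation marks.
#'
#' @param times Numeric vector of onset times (s), strictly increasing.
#' @param label Train label, e.g. `"twitch_nuchal"`, `"wake_onset"`.
#' @param session_duration Session duration in seconds; all times must lie in
#'   `[0, session_duration]`.
#' @return An object of class `event_train`.
#' @export
event_train <- function(times, label, session_duration) {
  times <- as.numeric(times)
  if (!is.numeric(session_duration) || length(session_duration) != 1L ||
      !is.finite(session_duration) || session_duration <= 0)
    stop("event_train: 'session_duration' must be a single positive number")
  if (any(!is.finite(times)))
    stop("event_train: event times must be finite")
  if (is.unsorted(times, strictly = TRUE))
    stop(sprintf("event_train '%s': times must be strictly increasing", label))
  if (length(times) && (times[1L] < 0 || times[length(times)] > session_duration))
    stop(sprintf("event_train '%s': times must lie in [0, %g]",
                 label, session_duration))
  structure(list(label = as.character(label)[1L], times = times,
                 session_duration = session_duration),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %s: %d events over %.1f s\n",
              x$label, length(x$times), x$session_duration))
  invisible(x)
}

#' Spike train of one sorted unit
#'
#' Sorted spike times for a single unit, with provenance metadata. Spike
#' sorting itself happens upstream; this type is its output.
#'
#' @param times Numeric vector of spike times (s), sorted ascending,
#'   non-negative.
#' @param unit_id Unit identifier string.
#' @param structure Anatomical structure label (`"IO"`, `"LRN"`, `"MDJ"`, or
#'   `"other"`).
#' @param quality_flags Character vector of free-form quality annotations
#'   (e.g. movement-artifact exclusion notes).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, unit_id, structure = "other",
                        quality_flags = character()) {
  times <- as.numeric(times)
  if (any(!is.finite(times)))
    stop("spike_train: spike times must be finite")
  if (is.unsorted(times))
    stop(sprintf("spike_train '%s': times must be sorted ascending", unit_id))
  if (length(times) && times[1L] < 0)
    stop(sprintf("spike_train '%s': times must be non-negative", unit_id))
  structure(list(unit_id = as.character(unit_id)[1L],
                 structure = as.character(structure)[1L],
                 times = times,
                 quality_flags = as.character(quality_flags)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit=%s structure=%s n=%d spikes\n",
              x$unit_id, x$structure, length(x$times)))
  invisible(x)
}

#' Behavioural-state intervals
#'
#' Disjoint, time-ordered, half-open intervals `[start, end)` labelled with
#' one of the three behavioural states: active wake (AW), behavioural
#' quiescence (BQ), active sleep (AS).
#'
#' @param start,end Numeric vectors of interval bounds (s), `start < end`.
#' @param label Character vector of state labels in `c("AW","BQ","AS")`.
#' @param threshold_used EMG amplitude threshold used to score the intervals
#'   (optional, `NA` if not applicable).
#' @return An object of class `state_intervals` (also a data.frame with
#'   columns `start`, `end`, `label`).
#' @export
state_intervals <- function(start, end, label, threshold_used = NA_real_) {
  start <- as.numeric(start); end <- as.numeric(end)
  label <- as.character(label)
  if (length(start) != length(end) || length(start) != length(label))
    stop("state_intervals: start, end, label must have equal length")
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("state_intervals: interval bounds must be finite")
  if (any(end <= start))
    stop("state_intervals: every interval must satisfy start < end")
  if (length(start) > 1L) {
    if (is.unsorted(start, strictly = TRUE))
      stop("state_intervals: intervals must be time-ordered")
    if (any(start[-1L] < end[-length(end)] - 1e-12))
      stop("state_intervals: intervals must be pairwise disjoint")
  }
  bad <- setdiff(unique(label), c("AW", "BQ", "AS"))
  if (length(bad))
    stop(sprintf("state_intervals: unknown state label(s): %s",
                 paste(bad, collapse = ", ")))
  df <- data.frame(start = start, end = end, label = label,
                   stringsAsFactors = FALSE)
  structure(df, class = c("state_intervals", "data.frame"),
            threshold_used = threshold_used)
}

#' @export
print.state_intervals <- function(x, ...) {
  tot <- tapply(x$end - x$start, x$label, sum)
  cat(sprintf("<state_intervals> %d intervals; time per state: %s\n",
              nrow(x),
              paste(sprintf("%s=%.1f s", names(tot), tot), collapse = ", ")))
  invisible(x)
}

#' Total time per state, in seconds
#' @param states A `state_intervals` object.
#' @return Named numeric vector with entries AW, BQ, AS (0 if absent).
#' @export
state_times <- function(states) {
  out <- c(AW = 0, BQ = 0, AS = 0)
  if (nrow(states)) {
    tot <- tapply(states$end - states$start, states$label, sum)
    out[names(tot)] <- tot
  }
  out
}

#' Intervals of one state
#' @param states A `state_intervals` object.
#' @param label State label to keep.
#' @return data.frame with columns start, end.
#' @export
state_bouts <- function(states, label) {
  sel <- states$label == label
  data.frame(start = states$start[sel], end = states$end[sel])
}

#' Recording session
#'
#' Bundles all components of one recording session on a common clock that
#' starts at 0: EMG channels, sorted spike trains, event trains, optional
#' scored states, a group label, and (for synthetic sessions) ground truth.
#'
#' @param id Session identifier string.
#' @param emg List of [sampled_signal] objects.
#' @param spikes List of [spike_train] objects.
#' @param events List of [event_train] objects.
#' @param states Optional [state_intervals].
#' @param group Group label (e.g. `"saline"`, `"apamin"`, `"none"`).
#' @param duration Session duration (s); inferred from components if `NULL`.
#' @param ground_truth Optional ground-truth list as produced by
#'   [simulate_session()].
#' @return An object of class `session`.
#' @export
session <- function(id, emg = list(), spikes = list(), events = list(),
                    states = NULL, group = "none", duration = NULL,
                    ground_truth = NULL) {
  stopifnot(is.list(emg), is.list(spikes), is.list(events))
  for (s in emg) if (!inherits(s, "sampled_signal"))
    stop("session: 'emg' must be a list of sampled_signal objects")
  for (s in spikes) if (!inherits(s, "spike_train"))
    stop("session: 'spikes' must be a list of spike_train objects")
  for (s in events) if (!inherits(s, "event_train"))
    stop("session: 'events' must be a list of event_train objects")
  if (!is.null(states) && !inherits(states, "state_intervals"))
    stop("session: 'states' must be a state_intervals object or NULL")
  if (is.null(duration)) {
    cand <- c(vapply(emg, function(s) s$t0 + signal_duration(s), 0),
              vapply(events, function(e) e$session_duration, 0),
              vapply(spikes, function(s) if (length(s$times))
                max(s$times) else 0, 0),
              if (!is.null(states) && nrow(states)) max(states$end) else 0)
    duration <- if (length(cand)) max(cand) else 0
  }
  if (duration <= 0) stop("session: duration must be positive")
  for (e in events)
    if (length(e$times) && max(e$times) > duration + 1e-9)
      stop(sprintf("session: events '%s' extend beyond duration", e$label))
  for (s in spikes)
    if (length(s$times) && max(s$times) > duration + 1e-9)
      stop(sprintf("session: spikes '%s' extend beyond duration", s$unit_id))
  names(emg) <- vapply(emg, `[[`, "", "channel")
  names(spikes) <- vapply(spikes, `[[`, "", "unit_id")
  names(events) <- vapply(events, `[[`, "", "label")
  structure(list(id = as.character(id)[1L], duration = duration,
                 emg = emg, spikes = spikes, events = events,
                 states = states, group = as.character(group)[1L],
                 ground_truth = ground_truth),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf(
    "<session> %s (group=%s): %.1f s, %d EMG channel(s), %d unit(s), %d event train(s)%s%s\n",
    x$id, x$group, x$duration, length(x$emg), length(x$spikes),
    length(x$events),
    if (!is.null(x$states)) sprintf(", %d state intervals", nrow(x$states)) else "",
    if (!is.null(x$ground_truth)) ", ground truth" else ""))
  invisible(x)
}
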