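#' Build a perievent time histogram
#'
#' Counts spikes by lag relative to each trigger event over a window
#' centred on the event, accumulating across events. Bins are half-open
#' `[left, right)` and 0 is always a bin edge. Events whose window extends
#' past the session edges still contribute (partial windows permitted; the
#' number of such events is recorded).
#'
#' @param spikes A [spike_train] or numeric vector of spike times (s).
#' @param events An [event_train] or numeric vector of event times (s);
#'   must be non-empty.
#' @param window Window length in seconds (default 1, i.e. +/-0.5 s).
#' @param bin_width Bin width in seconds; must divide `window/2` so that 0
#'   is an edge.
#' @param trigger Trigger label (taken from `events` if available).
#' @param units Contributing unit id(s) (taken from `spikes` if available).
#' @return An object of class `psth` with fields `counts`, `bin_edges`,
#'   `n_events`, `bin_width`, `window`, `trigger`, `units`, `n_truncated`.
#' @export
build_psth <- function(spikes, events, window = 1, bin_width = 0.010,
                       trigger = NULL, units = NULL) {
  sp <- if (inherits(spikes, "spike_train")) spikes$times else as.numeric(spikes)
  if (inherits(events, "event_train")) {
    if (is.null(trigger)) trigger <- events$label
    ses_dur <- events$session_duration
    ev <- events$times
  } else {
    ev <- as.numeric(events)
    ses_dur <- NA_real_
  }
  if (is.null(units) && inherits(spikes, "spike_train"))
    units <- spikes$unit_id
  if (!length(ev))
    stop("build_psth: 'events' is empty (a histogram needs at least one trigger)")
  half <- window / 2
  nb <- half / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stop("build_psth: 'bin_width' must divide window/2 so that 0 is a bin edge")
  nb <- as.integer(round(nb))
  edges <- (seq_len(2L * nb + 1L) - nb - 1L) * bin_width
  counts <- count_lags(sp, ev, half, bin_width)
  n_trunc <- if (is.na(ses_dur)) NA_integer_ else
    sum(ev < half | ev > ses_dur - half)
  structure(list(trigger = if (is.null(trigger)) "event" else trigger,
                 units = units, bin_edges = edges, counts = counts,
                 n_events = length(ev), bin_width = bin_width,
                 window = window, n_truncated = n_trunc),
            class = "psth")
}

# Vectorized lag counting: counts[b] = #{(s,e): s - e in [edge_b, edge_{b+1})}
count_lags <- function(sp, ev, half, bw) {
  B <- as.integer(round(2 * half / bw))
  if (!length(sp)) return(integer(B))
  lo <- findInterval(ev - half - bw, sp)
  hi <- findInterval(ev + half + bw, sp)
  ncand <- hi - lo
  if (sum(ncand) == 0) return(integer(B))
  idx <- sequence(ncand) + rep(lo, ncand)
  lag <- sp[idx] - rep(ev, ncand)
  bin <- floor((lag + half) / bw) + 1
  bin <- bin[bin >= 1 & bin <= B]
  tabulate(bin, B)
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> trigger=%s units=%s: %d bins of %g ms, %d events, %d spikes in window\n",
              x$trigger, paste(x$units, collapse = "+"),
              length(x$counts), x$bin_width * 1000, x$n_events,
              sum(x$counts)))
  invisible(x)
}

#' Bin centres of a PSTH, in seconds
#' @param psth A `psth`.
#' @export
psth_centers <- function(psth)
  psth$bin_edges[-length(psth$bin_edges)] + psth$bin_width / 2

#' Firing-rate view of a PSTH
#' @param psth A `psth`.
#' @return Per-bin rate in Hz: `counts / (n_events * bin_width)`.
#' @export
psth_rate <- function(psth) psth$counts / (psth$n_events * psth$bin_width)

#' Peak-normalized rate view of a PSTH
#' @param psth A `psth`.
#' @return Per-bin rate divided by the peak rate (so the peak is 1); errors
#'   if the histogram is empty.
#' @export
psth_normalized <- function(psth) {
  r <- psth_rate(psth)
  pk <- max(r)
  if (pk <= 0) stop("psth_normalized: histogram has zero peak rate")
  r / pk
}

#' Average peak-normalized histograms across units
#'
#' Each unit's rate view is divided by its own peak rate; the mean and SEM
#' of the normalized rate are then taken per bin across units. Units with
#' zero peak rate cannot be normalized and are excluded (recorded in the
#' result).
#'
#' @param psths List of `psth` objects with identical binning.
#' @return List with `mean`, `sem` (per-bin), `centers`, `n_units`,
#'   `excluded_units` (ids or indices of zero-peak units).
#' @export
normalize_and_average <- function(psths) {
  if (!length(psths)) stop("normalize_and_average: no histograms supplied")
  check_same_binning(psths)
  peaks <- vapply(psths, function(p) max(psth_rate(p)), 0)
  zero <- peaks <= 0
  if (all(zero))
    stop("normalize_and_average: all units have zero peak rate")
  ids <- vapply(seq_along(psths), function(i) {
    u <- psths[[i]]$units
    if (is.null(u)) as.character(i) else paste(u, collapse = "+")
  }, "")
  keep <- which(!zero)
  mat <- vapply(keep, function(i) psth_normalized(psths[[i]]),
                numeric(length(psths[[1L]]$counts)))
  mat <- matrix(mat, ncol = length(keep))
  n <- length(keep)
  mu <- rowMeans(mat)
  sem <- if (n > 1L) apply(mat, 1L, stats::sd) / sqrt(n) else rep(0, nrow(mat))
  list(mean = mu, sem = sem, centers = psth_centers(psths[[1L]]),
       n_units = n, excluded_units = ids[zero])
}

check_same_binning <- function(psths) {
  e1 <- psths[[1L]]$bin_edges
  for (p in psths[-1L])
    if (length(p$bin_edges) != length(e1) ||
        any(abs(p$bin_edges - e1) > 1e-9))
      stop("histograms do not share the same binning")
  invisible(TRUE)
}

#' Smooth a PSTH rate profile
#'
#' Kernel smoothing of the rate view with a normalized exponential kernel
#' of time constant `tau` (symmetric two-sided by default, causal
#' one-sided optionally). The kernel sums to one, so total mass is
#' preserved up to edge truncation.
#'
#' @param psth A `psth`.
#' @param tau Kernel time constant, s (default 10 ms).
#' @param causal If `TRUE`, use a one-sided (causal) kernel.
#' @return Numeric vector of smoothed rates (Hz), one per bin.
#' @export
smooth_psth <- function(psth, tau = 0.010, causal = FALSE) {
  if (tau <= 0) stop("smooth_psth: 'tau' must be positive")
  r <- psth_rate(psth)
  bw <- psth$bin_width
  H <- max(1L, ceiling(6 * tau / bw))
  off <- if (causal) 0:H else (-H):H
  w <- exp(-abs(off) * bw / tau)
  w <- w / sum(w)
  n <- length(r)
  out <- numeric(n)
  for (j in seq_along(off)) {
    o <- off[j]
    src <- seq_len(n) - o
    ok <- src >= 1L & src <= n
    out[ok] <- out[ok] + w[j] * r[src[ok]]
  }
  out
}

#' Area under the curve of a PSTH within a lag window
#'
#' Sums histogram counts over the bins that fall inside the window. The
#' window must be aligned to bin edges. The default mode divides by the
#' number of trigger events (spikes per event), which makes units triggered
#' on different numbers of events comparable; raw counts are available.
#'
#' @param psth A `psth`.
#' @param window Numeric `(start, end)` lag window in seconds.
#' @param mode `"per_event"` (counts / n_events, default) or `"counts"`.
#' @return Scalar area.
#' @export
area_under_curve <- function(psth, window,
                             mode = c("per_event", "counts")) {
  mode <- match.arg(mode)
  e <- psth$bin_edges
  tol <- 1e-9
  for (w in window)
    if (min(abs(e - w)) > tol)
      stop(sprintf("area_under_curve: window bound %g s is not aligned to bin edges", w))
  l <- e[-length(e)]; r <- e[-1L]
  sel <- l >= window[1L] - tol & r <= window[2L] + tol
  total <- sum(psth$counts[sel])
  if (mode == "per_event") total / psth$n_events else total
}
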