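#' Unit archetype specification
#'
#' Describes one synthetic unit as a state-dependent base rate plus
#' event-locked Gaussian rate kernels and an optional post-event plateau.
#' The archetypes encode the response shapes the analysis must detect:
#' \describe{
#'   \item{cd}{sharp corollary-discharge peak centred on event onset
#'     (Gaussian kernel, centre 0, sd 4 ms).}
#'   \item{motor}{broad twitch-preceding peak (centre -30 ms, sd 20 ms).}
#'   \item{sensory}{twitch-following reafferent peak (centre +30 ms,
#'     sd 12 ms).}
#'   \item{motor_reafferent}{both motor and sensory kernels.}
#'   \item{apamin_cd}{cd kernel plus a rate plateau over +20 to +200 ms,
#'     the prolonged-tail shape seen after SK-channel blockade.}
#'   \item{null}{state-dependent base rate only, no event locking.}
#' }
#'
#' @param archetype One of `"cd"`, `"motor"`, `"sensory"`,
#'   `"motor_reafferent"`, `"apamin_cd"`, `"null"`.
#' @param unit_id Unit identifier.
#' @param structure Anatomical structure label.
#' @param base_rate Named numeric vector of firing rates (Hz) per state
#'   (`AW`, `BQ`, `AS`).
#' @param kernels data.frame with columns `center` (s), `width` (s, Gaussian
#'   sd) and `gain` (Hz, peak rate elevation); `NULL` uses the archetype
#'   default. Gains must be non-negative and centres within +/-0.5 s.
#' @param plateau Numeric `(start, end, gain)` of a uniform post-event rate
#'   elevation, or `NULL`.
#' @param trigger_muscle Muscle whose twitches drive the kernels (default
#'   the session's first muscle).
#' @return An object of class `unit_spec`.
#' @export
unit_spec <- function(archetype = c("cd", "motor", "sensory",
                                    "motor_reafferent", "apamin_cd", "null"),
                      unit_id = archetype, structure = "IO",
                      base_rate = c(AW = 1, BQ = 0.5, AS = 2),
                      kernels = NULL, plateau = NULL,
                      trigger_muscle = NULL) {
  archetype <- match.arg(archetype)
  if (is.null(kernels)) {
    kernels <- switch(archetype,
      cd = data.frame(center = 0, width = 0.004, gain = 80),
      motor = data.frame(center = -0.030, width = 0.020, gain = 15),
      sensory = data.frame(center = 0.030, width = 0.012, gain = 25),
      motor_reafferent = data.frame(center = c(-0.030, 0.030),
                                    width = c(0.020, 0.012),
                                    gain = c(15, 25)),
      apamin_cd = data.frame(center = 0, width = 0.004, gain = 80),
      null = data.frame(center = numeric(0), width = numeric(0),
                        gain = numeric(0)))
  }
  if (is.null(plateau) && archetype == "apamin_cd")
    plateau <- c(start = 0.020, end = 0.200, gain = 2)
  if (!all(c("AW", "BQ", "AS") %in% names(base_rate)))
    stop("unit_spec: 'base_rate' must name AW, BQ and AS")
  if (any(base_rate < 0)) stop("unit_spec: base rates must be >= 0")
  if (nrow(kernels)) {
    if (any(kernels$gain < 0))
      stop("unit_spec: kernel gains must be non-negative")
    if (any(kernels$width <= 0))
      stop("unit_spec: kernel widths must be positive")
    if (any(abs(kernels$center) > 0.5))
      stop("unit_spec: kernel centres must lie within +/-0.5 s")
  }
  if (!is.null(plateau)) {
    plateau <- as.numeric(plateau)
    if (length(plateau) != 3L || plateau[1L] >= plateau[2L] || plateau[3L] < 0)
      stop("unit_spec: 'plateau' must be (start, end, gain) with start < end, gain >= 0")
  }
  structure(list(archetype = archetype, unit_id = as.character(unit_id)[1L],
                 structure = structure,
                 base_rate = base_rate[c("AW", "BQ", "AS")],
                 kernels = kernels, plateau = plateau,
                 trigger_muscle = trigger_muscle),
            class = "unit_spec")
}

#' Simulation configuration
#'
#' Parameters of the synthetic-session generator. The generator emits EMG
#' directly on the rectified-envelope scale (the analysis only consumes the
#' rectified-smoothed trace): state-dependent mean level plus Gaussian
#' noise, with half-sine twitch transients injected during active sleep.
#' Behavioural states cycle AW -> BQ -> AS with exponential bout durations
#' above a configurable floor. Spikes are drawn from an inhomogeneous
#' Poisson process whose rate is the per-state base rate plus the
#' event-locked kernels of each [unit_spec].
#'
#' @param duration Session duration, s.
#' @param bout_means Named mean bout durations (s) for `AW`, `BQ`, `AS`.
#' @param bout_floor Minimum bout duration, s (added to the exponential
#'   draw; keeps every bout scorable under the 1-s rule).
#' @param twitch_rate Twitch rate per muscle during AS, events/min.
#' @param muscles Character vector of muscle/EMG channel names.
#' @param min_intertwitch Minimum inter-twitch interval per muscle, s.
#' @param twitch_duration Duration of a twitch EMG transient, s.
#' @param twitch_amp_mult Peak twitch amplitude as a multiple of the atonia
#'   mean; must exceed the detection criterion multiple so injected twitches
#'   are detectable by construction.
#' @param atonia_mean,atonia_sd,wake_mean,wake_sd EMG level model (arbitrary
#'   units): mean and noise sd during atonia (BQ/AS) and wake (AW).
#' @param emg_rate EMG sampling rate, Hz.
#' @param unit_specs List of [unit_spec] objects.
#' @param include_emg Generate EMG channels? When `FALSE` the session
#'   carries ground-truth states and event trains only (used for spike-level
#'   simulations where EMG scoring is not under study).
#' @param detect_multiplier The twitch-detection multiple the session must
#'   remain detectable under (`twitch_amp_mult` must exceed it).
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 600,
                       bout_means = c(AW = 20, BQ = 10, AS = 60),
                       bout_floor = 5,
                       twitch_rate = 30,
                       muscles = "nuchal",
                       min_intertwitch = 0.200,
                       twitch_duration = 0.060,
                       twitch_amp_mult = 6,
                       atonia_mean = 1, atonia_sd = 0.1,
                       wake_mean = 5, wake_sd = 0.5,
                       emg_rate = 1000,
                       unit_specs = list(),
                       include_emg = TRUE,
                       detect_multiplier = 3,
                       seed = 1L) {
  if (duration <= 0) stop("sim_config: 'duration' must be positive")
  if (!all(c("AW", "BQ", "AS") %in% names(bout_means)))
    stop("sim_config: 'bout_means' must name AW, BQ and AS")
  if (any(bout_means <= bout_floor))
    stop("sim_config: bout means must exceed the bout floor")
  if (twitch_rate < 0) stop("sim_config: 'twitch_rate' must be >= 0")
  if (twitch_amp_mult <= detect_multiplier)
    stop("sim_config: 'twitch_amp_mult' must exceed 'detect_multiplier' so injected twitches are detectable")
  if (atonia_mean <= 0 || wake_mean <= atonia_mean)
    stop("sim_config: need 0 < atonia_mean < wake_mean")
  for (u in unit_specs) if (!inherits(u, "unit_spec"))
    stop("sim_config: 'unit_specs' must be a list of unit_spec objects")
  structure(list(duration = duration,
                 bout_means = bout_means[c("AW", "BQ", "AS")],
                 bout_floor = bout_floor, twitch_rate = twitch_rate,
                 muscles = muscles, min_intertwitch = min_intertwitch,
                 twitch_duration = twitch_duration,
                 twitch_amp_mult = twitch_amp_mult,
                 atonia_mean = atonia_mean, atonia_sd = atonia_sd,
                 wake_mean = wake_mean, wake_sd = wake_sd,
                 emg_rate = emg_rate, unit_specs = unit_specs,
                 include_emg = include_emg,
                 detect_multiplier = detect_multiplier,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# AW -> BQ -> AS cycle with (floored) exponential bout durations.
# Uses the current RNG state.
simulate_states_ <- function(duration, bout_means, bout_floor) {
  labs <- character(0); start <- numeric(0); end <- numeric(0)
  t <- 0; i <- 0L
  order3 <- c("AW", "BQ", "AS")
  while (t < duration) {
    lab <- order3[(i %% 3L) + 1L]
    d <- bout_floor + stats::rexp(1L, 1 / (bout_means[[lab]] - bout_floor))
    e <- min(t + d, duration)
    if (e > t) { start <- c(start, t); end <- c(end, e); labs <- c(labs, lab) }
    t <- e; i <- i + 1L
  }
  state_intervals(start, end, labs)
}

# Renewal event train with a hard refractory period on [t0, t1): gaps are
# refractory + Exp(mean 1/rate - refractory), so the asymptotic event rate
# equals `rate` exactly.
sim_refractory_poisson <- function(rate, t0, t1, refractory) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  mean_gap <- 1 / rate
  if (mean_gap <= refractory)
    stop("event rate too high for the refractory period")
  exr <- 1 / (mean_gap - refractory)
  out <- numeric(0)
  t <- t0 + stats::rexp(1L, exr)   # no dead time against the left edge
  repeat {
    n <- max(16L, ceiling((t1 - t) * rate * 1.5))
    tt <- t + cumsum(c(0, refractory + stats::rexp(n, exr)))
    out <- c(out, tt[tt < t1])
    if (tt[length(tt)] >= t1) break
    t <- tt[length(tt)] + refractory + stats::rexp(1L, exr)
  }
  out
}

# Simple homogeneous Poisson train on [0, duration).
sim_poisson_train <- function(rate, duration) {
  if (rate <= 0) return(numeric(0))
  n <- stats::rpois(1L, rate * duration)
  sort(stats::runif(n) * duration)
}

#' Simulate one unit's spike train
#'
#' Draws spikes from an inhomogeneous Poisson process whose rate is the
#' spec's per-state base rate plus its event-locked kernels, by
#' superposition of independent Poisson components (exact for non-negative
#' gains): homogeneous base spikes per state bout, `Poisson(gain * width *
#' sqrt(2*pi))` Gaussian-displaced spikes per kernel per event, and uniform
#' plateau spikes per event.
#'
#' @param spec A [unit_spec].
#' @param states A [state_intervals] giving the base-rate schedule.
#' @param trigger_events Numeric vector of event (twitch) times the kernels
#'   lock to.
#' @param duration Session duration, s.
#' @return A [spike_train]. Uses the current RNG state.
#' @export
simulate_unit <- function(spec, states, trigger_events, duration) {
  sp <- numeric(0)
  for (i in seq_len(nrow(states))) {
    r <- spec$base_rate[[states$label[i]]]
    d <- states$end[i] - states$start[i]
    if (r > 0) {
      n <- stats::rpois(1L, r * d)
      sp <- c(sp, states$start[i] + stats::runif(n) * d)
    }
  }
  ne <- length(trigger_events)
  if (ne && nrow(spec$kernels)) {
    for (j in seq_len(nrow(spec$kernels))) {
      kc <- spec$kernels$center[j]; kw <- spec$kernels$width[j]
      mu <- spec$kernels$gain[j] * kw * sqrt(2 * pi)
      n_per <- stats::rpois(ne, mu)
      tot <- sum(n_per)
      if (tot)
        sp <- c(sp, stats::rnorm(tot,
                                 mean = rep(trigger_events + kc, n_per),
                                 sd = kw))
    }
  }
  if (ne && !is.null(spec$plateau)) {
    pl <- spec$plateau
    mu <- pl[3L] * (pl[2L] - pl[1L])
    n_per <- stats::rpois(ne, mu)
    tot <- sum(n_per)
    if (tot)
      sp <- c(sp, rep(trigger_events + pl[1L], n_per) +
                stats::runif(tot) * (pl[2L] - pl[1L]))
  }
  sp <- sort(sp[sp >= 0 & sp < duration])
  spike_train(sp, unit_id = spec$unit_id, structure = spec$structure)
}

#' Simulate a synthetic recording session with ground truth
#'
#' Generates alternating AW/BQ/AS state bouts, rectified-scale EMG per
#' muscle (tonic during wake, near-baseline atonia during sleep, half-sine
#' twitch transients during AS), ground-truth twitch and wake-onset event
#' trains, and one spike train per [unit_spec], all deterministically from
#' the seed. The first twitch of every sleep bout is placed exactly at the
#' AS onset (the scoring rule defines AS as starting at the first twitch),
#' and twitch transients keep clear of bout boundaries so that they never
#' perturb state segmentation.
#'
#' @param sim A [sim_config].
#' @param id Session id.
#' @param group Group label (e.g. `"saline"`, `"apamin"`).
#' @return A [session] with `ground_truth` populated: `true_states`,
#'   `true_twitches` (list of [event_train] per muscle), `true_wake_onsets`,
#'   `unit_specs`, and the EMG model parameters.
#' @export
simulate_session <- function(sim, id = "synthetic", group = "none") {
  if (!inherits(sim, "sim_config"))
    stop("simulate_session: 'sim' must be a sim_config")
  set.seed(sim$seed)
  dur <- sim$duration
  states <- simulate_states_(dur, sim$bout_means, sim$bout_floor)
  if (sim$twitch_rate == 0) {
    # no twitches means no scorable active sleep: sleep is all quiescence
    lab <- states$label
    lab[lab == "AS"] <- "BQ"
    keep <- c(TRUE, lab[-1L] != lab[-length(lab)])
    grp <- cumsum(keep)
    states <- state_intervals(tapply(states$start, grp, min),
                              tapply(states$end, grp, max),
                              lab[keep])
  }

  # ground-truth twitches per muscle, confined to AS and clear of bout ends
  guard <- sim$twitch_duration + 0.1
  rate_s <- sim$twitch_rate / 60
  as_bouts <- state_bouts(states, "AS")
  tw <- stats::setNames(vector("list", length(sim$muscles)), sim$muscles)
  for (m in seq_along(sim$muscles)) tw[[m]] <- numeric(0)
  for (i in seq_len(nrow(as_bouts))) {
    s <- as_bouts$start[i]; e <- as_bouts$end[i] - guard
    for (m in seq_along(sim$muscles)) {
      t0 <- if (m == 1L) s + sim$min_intertwitch else s
      extra <- if (e > t0)
        sim_refractory_poisson(rate_s, t0, e, sim$min_intertwitch)
      else numeric(0)
      # the first twitch of the bout marks AS onset; it belongs to muscle 1
      if (m == 1L) extra <- c(s, extra)
      tw[[m]] <- c(tw[[m]], extra)
    }
  }
  true_twitches <- lapply(seq_along(sim$muscles), function(m)
    event_train(sort(unique(tw[[m]])),
                paste0("twitch_", sim$muscles[m]), dur))
  names(true_twitches) <- sim$muscles
  aw_starts <- state_bouts(states, "AW")$start
  true_wake <- event_train(sort(aw_starts), "wake_onset", dur)

  emg <- list()
  if (sim$include_emg) {
    n <- round(dur * sim$emg_rate)
    t_samp <- (seq_len(n) - 1L) / sim$emg_rate
    st_idx <- findInterval(t_samp, states$start)
    lab <- states$label[pmax(st_idx, 1L)]
    is_aw <- lab == "AW"
    level <- ifelse(is_aw, sim$wake_mean, sim$atonia_mean)
    sdv <- ifelse(is_aw, sim$wake_sd, sim$atonia_sd)
    for (m in seq_along(sim$muscles)) {
      x <- level + (if (any(sdv > 0)) stats::rnorm(n, 0, sdv) else 0)
      bump_amp <- (sim$twitch_amp_mult - 1) * sim$atonia_mean
      for (tt in true_twitches[[m]]$times) {
        i0 <- floor(tt * sim$emg_rate) + 1L
        i1 <- min(n, i0 + round(sim$twitch_duration * sim$emg_rate) - 1L)
        if (i1 >= i0) {
          ph <- (t_samp[i0:i1] - tt) / sim$twitch_duration
          x[i0:i1] <- x[i0:i1] + bump_amp * sin(pi * pmin(pmax(ph, 0), 1))
        }
      }
      emg[[m]] <- sampled_signal(pmax(x, 0), rate = sim$emg_rate,
                                 channel = sim$muscles[m], rectified = TRUE)
    }
  }

  spikes <- lapply(sim$unit_specs, function(spec) {
    tm <- spec$trigger_muscle
    if (is.null(tm)) tm <- sim$muscles[1L]
    simulate_unit(spec, states, true_twitches[[tm]]$times, dur)
  })

  session(id = id, emg = emg, spikes = spikes,
          events = c(true_twitches, list(wake_onset = true_wake)),
          states = states, group = group, duration = dur,
          ground_truth = list(true_states = states,
                              true_twitches = true_twitches,
                              true_wake_onsets = true_wake,
                              unit_specs = sim$unit_specs,
                              emg_model = sim[c("atonia_mean", "atonia_sd",
                                                "wake_mean", "wake_sd",
                                                "twitch_amp_mult",
                                                "twitch_duration")]))
}

#' Simulate an independent event/spike pair (calibration null)
#'
#' Events and spikes are mutually independent homogeneous Poisson
#' processes; used to estimate the family-wise type-I error of the jitter
#' band procedure.
#'
#' @param event_rate,spike_rate Rates in events/s and spikes/s (>= 0; the
#'   event rate must be > 0).
#' @param duration Duration, s.
#' @param seed Optional integer seed (uses current RNG state if `NULL`).
#' @return List with elements `events` (an [event_train]) and `spikes`
#'   (a [spike_train]).
#' @export
simulate_null_pair <- function(event_rate, spike_rate, duration,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (event_rate <= 0) stop("simulate_null_pair: 'event_rate' must be > 0")
  if (spike_rate < 0) stop("simulate_null_pair: 'spike_rate' must be >= 0")
  ev <- sim_poisson_train(event_rate, duration)
  # strict monotonicity for the event-train contract
  ev <- unique(ev)
  sp <- sim_poisson_train(spike_rate, duration)
  list(events = event_train(ev, "null_event", duration),
       spikes = spike_train(sp, "null_unit"))
}

#' Simulate an event-locked unit outside a full session
#'
#' Convenience generator for archetype-recovery studies: a single active
#' sleep span of the length needed for `n_events` expected twitches, a
#' refractory Poisson twitch train on it, and one unit simulated from
#' `spec`.
#'
#' @param spec A [unit_spec].
#' @param n_events Target number of trigger events.
#' @param event_rate Event rate, events/s (default 0.5).
#' @param refractory Minimum event separation, s.
#' @param seed Optional integer seed.
#' @return List with `events` ([event_train]), `spikes` ([spike_train]) and
#'   `duration`.
#' @export
simulate_locked_unit <- function(spec, n_events = 2000, event_rate = 0.5,
                                 refractory = 0.200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dur <- n_events / event_rate
  ev <- sim_refractory_poisson(event_rate, 0.5, dur - 0.5, refractory)
  states <- state_intervals(0, dur, "AS")
  sp <- simulate_unit(spec, states, ev, dur)
  list(events = event_train(ev, "twitch_nuchal", dur), spikes = sp,
       duration = dur)
}
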