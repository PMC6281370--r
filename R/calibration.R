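#' Family-wise false-positive rate of the jitter band procedure
#'
#' Empirical calibration of the simultaneous confidence bands: simulates
#' independent homogeneous Poisson event and spike trains (a true null —
#' no event locking at any timescale), runs the full jitter test on each
#' replicate, and reports the fraction of replicates in which any analyzed
#' bin breaches the band. Under correct calibration this fraction is at
#' most `alpha`.
#'
#' @param n_reps Number of null replicates.
#' @param duration Session duration per replicate, s.
#' @param event_rate,spike_rate Poisson rates, events/s and spikes/s.
#' @param window,bin_width,delta,n_surrogates,alpha Jitter-test parameters
#'   (defaults: 1-s window, 10-ms bins, 500-ms jitter cells, 1000
#'   surrogates, alpha 0.01).
#' @param seed Integer seed for the whole study.
#' @return List with `fwer` (breach fraction), `n_breach`, `n_reps`, and
#'   the binomial 95 percent upper confidence bound `upper95` on the true
#'   rate.
#' @export
jitter_fwer <- function(n_reps = 500, duration = 600, event_rate = 0.5,
                        spike_rate = 5, window = 1, bin_width = 0.010,
                        delta = 0.500, n_surrogates = 1000, alpha = 0.01,
                        seed = 1L) {
  set.seed(seed)
  breach <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    np <- simulate_null_pair(event_rate, spike_rate, duration)
    jt <- jitter_test(np$spikes, np$events, window = window,
                      bin_width = bin_width, delta = delta,
                      n_surrogates = n_surrogates, alpha = alpha)
    breach[i] <- jt$significant
  }
  nb <- sum(breach)
  list(fwer = nb / n_reps, n_breach = nb, n_reps = n_reps,
       upper95 = stats::qbeta(0.95, nb + 1, n_reps - nb))
}
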