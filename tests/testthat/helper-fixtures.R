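# Small sessions and signals built in code for the tests.

make_signal <- function(x, rate = 1000, channel = "nuchal",
                        rectified = TRUE) {
  sampled_signal(x, rate = rate, channel = channel, rectified = rectified)
}

# square-wave envelope: alternating blocks of two levels
square_envelope <- function(levels = c(10, 2), block_s = 2, n_blocks = 6,
                            rate = 1000) {
  x <- rep(rep(levels, length.out = n_blocks), each = block_s * rate)
  make_signal(x, rate = rate)
}

tiny_session <- function(seed = 1, duration = 120, include_emg = TRUE,
                         emg_rate = 200, units = list(unit_spec("cd"))) {
  simulate_session(sim_config(duration = duration, emg_rate = emg_rate,
                              unit_specs = units, include_emg = include_emg,
                              seed = seed),
                   id = sprintf("tiny%d", seed))
}

# brute-force lag histogram (O(n^2) oracle)
oracle_psth_counts <- function(sp, ev, window = 1, bw = 0.01) {
  half <- window / 2
  B <- round(window / bw)
  lag <- as.vector(outer(sp, ev, "-"))
  vapply(seq_len(B), function(b) {
    l <- -half + (b - 1) * bw
    sum(lag >= l & lag < l + bw)
  }, 0L)
}
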