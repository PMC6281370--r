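test_that("rectify_smooth limits: zero signal, tiny tau, RC step response", {
  z <- make_signal(rep(0, 500))
  expect_equal(rectify_smooth(z, 0.01)$samples, rep(0, 500))

  x <- make_signal(sin(seq(0, 20, length.out = 2000)), rectified = FALSE)
  y <- rectify_smooth(x, tau = 1e-9)
  expect_equal(y$samples, abs(x$samples), tolerance = 1e-9)
  expect_true(y$rectified)

  # unit step: output follows 1 - exp(-t/tau) within discretization error
  step <- make_signal(c(rep(0, 100), rep(1, 900)))
  ys <- rectify_smooth(step, tau = 0.1)$samples
  tt <- (1:900) / 1000
  expect_equal(ys[100 + (1:900)], 1 - exp(-tt / 0.1), tolerance = 0.01)

  expect_error(rectify_smooth(step, tau = 0), "tau")
})

test_that("threshold is the midpoint of high-tone and atonia means", {
  sq <- square_envelope(levels = c(10, 2), block_s = 2, n_blocks = 10)
  thr <- estimate_threshold(sq)
  expect_equal(thr$mean_high, 10)
  expect_equal(thr$mean_atonia, 2)
  expect_equal(thr$threshold, 6)
  expect_identical(thr$threshold, (thr$mean_high + thr$mean_atonia) / 2)

  flat <- make_signal(rep(3, 20000))
  expect_error(estimate_threshold(flat), "cannot distinguish")

  expect_error(estimate_threshold(make_signal(rep(1, 500))), "too short")
})

test_that("manual threshold segments are honoured exactly", {
  sq <- square_envelope(levels = c(8, 2), block_s = 2, n_blocks = 6)
  thr <- estimate_threshold(sq, manual_segments = list(
    high = rbind(c(0.5, 1.5)), atonia = rbind(c(2.5, 3.5))))
  expect_equal(thr$threshold, 5)
  expect_error(
    estimate_threshold(sq, manual_segments = list(high = rbind(c(0, 1)),
                                                  atonia = rbind(c(0.5, 1.5)))),
    "overlap")
})

test_that("threshold on a synthetic session is close to the true midpoint", {
  sim <- sim_config(duration = 200, seed = 21)
  s <- simulate_session(sim)
  thr <- estimate_threshold(rectify_smooth(s$emg[[1]], 0.001))
  true_mid <- (sim$wake_mean + sim$atonia_mean) / 2
  expect_lt(abs(thr$threshold - true_mid) / true_mid, 0.05)
})

test_that("segment_states applies the stated AW/BQ/AS rules", {
  # always above threshold: one AW interval
  hi <- make_signal(rep(10, 5000))
  st <- segment_states(hi, list(), threshold = 6)
  expect_equal(nrow(st), 1)
  expect_equal(st$label, "AW")

  # 10 s wake, 10 s sleep with a twitch 3 s into the sleep run
  x <- make_signal(c(rep(10, 10000), rep(2, 10000)))
  tw <- event_train(13, "twitch_nuchal", 20)
  st <- segment_states(x, list(tw), threshold = 6)
  expect_equal(st$label, c("AW", "BQ", "AS"))
  expect_equal(st$start, c(0, 10, 13), tolerance = 2e-3)
  expect_equal(st$end, c(10, 13, 20), tolerance = 2e-3)

  # a 0.5-s sub-threshold dip inside wake does not break the bout
  xd <- make_signal(c(rep(10, 5000), rep(2, 500), rep(10, 5000)))
  std <- segment_states(xd, list(), threshold = 6)
  expect_equal(nrow(std), 1)
  expect_equal(std$label, "AW")

  # twitch-free sleep is all BQ
  st2 <- segment_states(x, list(), threshold = 6)
  expect_equal(st2$label, c("AW", "BQ"))
})

test_that("twitch detection obeys the criterion, refractory and sleep mask", {
  # flat atonia with no sample at criterion: zero twitches
  flat <- make_signal(rep(1, 20000))
  mask <- data.frame(start = 0, end = 20)
  td <- detect_twitches(flat, mask, k = 3)
  expect_equal(length(td$onsets$times), 0)
  expect_equal(td$baseline, 1)

  # transient during wake is not counted
  x <- rep(1, 20000)
  x[5000:5060] <- 6   # inside [0,20) but outside the sleep mask below
  sig <- make_signal(x)
  td2 <- detect_twitches(sig, data.frame(start = 10, end = 20), k = 3)
  expect_equal(length(td2$onsets$times), 0)

  # same transient inside the mask is found once
  td3 <- detect_twitches(sig, data.frame(start = 0, end = 10), k = 3)
  expect_equal(length(td3$onsets$times), 1)
  expect_equal(td3$onsets$times, 5, tolerance = 2e-3)

  expect_error(detect_twitches(sig, data.frame(start = numeric(0),
                                               end = numeric(0))),
               "empty sleep mask")
})

test_that("raising k never increases the number of detected twitches", {
  s <- tiny_session(seed = 22, duration = 300, emg_rate = 500)
  sig <- rectify_smooth(s$emg[[1]], 0.001)
  mask <- s$states[s$states$label != "AW", ]
  mask <- data.frame(start = mask$start, end = mask$end)
  n <- vapply(c(1.5, 2, 3, 4, 5, 8),
              function(k) length(detect_twitches(sig, mask, k = k)$onsets$times),
              0L)
  expect_true(all(diff(n) <= 0))
})

test_that("noise-free sessions are scored exactly", {
  sim <- sim_config(duration = 400, atonia_sd = 0, wake_sd = 0, seed = 23)
  s <- simulate_session(sim)
  sc <- score_session(s)
  ts <- s$ground_truth$true_states; ss <- sc$states
  dt <- 1 / sim$emg_rate
  expect_equal(nrow(ss), nrow(ts))
  expect_equal(ss$label, ts$label)
  expect_lt(max(abs(ss$start - ts$start)), dt + 1e-9)
  expect_lt(max(abs(ss$end - ts$end)), dt + 1e-9)

  # twitch detection: precision = recall = 1, onsets within a rise time
  ttw <- s$ground_truth$true_twitches$nuchal$times
  dtw <- sc$events$twitch_nuchal$times
  expect_equal(length(dtw), length(ttw))
  err <- vapply(dtw, function(x) min(abs(x - ttw)), 0)
  expect_true(all(err < sim$twitch_duration))

  # wake onsets recovered within one sample
  two <- s$ground_truth$true_wake_onsets$times
  dwo <- sc$events$wake_onset$times
  expect_equal(length(dwo), length(two))
  expect_lt(max(abs(dwo - two)), dt + 1e-9)
})

test_that("scored twitches always lie inside AS intervals", {
  s <- tiny_session(seed = 24, duration = 300, emg_rate = 500)
  sc <- score_session(s)
  as_b <- state_bouts(sc$states, "AS")
  for (tt in sc$events$twitch_nuchal$times)
    expect_true(any(tt >= as_b$start - 1e-9 & tt < as_b$end))
})

test_that("wake-onset detection handles sessions without wake", {
  x <- make_signal(rep(2, 5000))
  st <- segment_states(x, list(), threshold = 6)
  expect_equal(length(detect_wake_onsets(x, st, 6)$times), 0)
})
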