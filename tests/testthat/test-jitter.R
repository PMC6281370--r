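test_that("surrogates preserve the event count per jitter cell exactly", {
  np <- simulate_null_pair(0.5, 5, 200, seed = 51)
  surr <- jitter_surrogates(np$events, delta = 0.5, n_surrogates = 50,
                            seed = 52)
  cells <- floor(np$events$times / 0.5)
  for (j in c(1, 17, 50)) {
    sj <- floor(surr$jit[, j] / 0.5)
    expect_identical(as.vector(table(sj)), as.vector(table(cells)))
    expect_identical(names(table(sj)), names(table(cells)))
  }
  # every surrogate keeps the event count
  expect_true(all(colSums(!is.na(surr$jit)) == length(np$events$times)))
  # surrogate_train returns a valid sorted train
  tr <- surrogate_train(surr, 3)
  expect_s3_class(tr, "event_train")
  expect_false(is.unsorted(tr$times, strictly = TRUE))
})

test_that("tiny jitter windows keep surrogates near the original", {
  ev <- event_train(c(1.2345, 5.6789, 9.999), "tw", 12)
  surr <- jitter_surrogates(ev, delta = 1e-4, n_surrogates = 20, seed = 53)
  expect_true(all(abs(surr$jit - ev$times) <= 1e-4))
})

test_that("compiled surrogate counting equals the plain-R reference", {
  lu <- simulate_locked_unit(unit_spec("sensory"), n_events = 150,
                             event_rate = 0.5, seed = 54)
  surr <- jitter_surrogates(lu$events, delta = 0.5, n_surrogates = 40,
                            seed = 55)
  a <- surrogate_psth_counts(lu$spikes, surr)
  b <- sleepspikes:::surrogate_psth_counts_ref(lu$spikes, surr)
  expect_true(all(a == b))
})

test_that("surrogate averaging flattens an event-locked peak", {
  lu <- simulate_locked_unit(unit_spec("cd"), n_events = 1000, seed = 56)
  p <- build_psth(lu$spikes, lu$events)
  surr <- jitter_surrogates(lu$events, n_surrogates = 200, seed = 57)
  M <- surrogate_psth_counts(lu$spikes, surr)
  ratio_obs <- max(p$counts) / mean(p$counts)
  avg <- rowMeans(M)
  ratio_surr <- max(avg) / mean(avg)
  expect_gt(ratio_obs, 2 * ratio_surr)
})

test_that("identical surrogates yield no breach at any alpha", {
  p <- build_psth(sort(runif(200, 0, 50)), sort(runif(20, 1, 49)))
  M <- matrix(p$counts, length(p$counts), 200)
  for (a in c(0.05, 0.01)) {
    bands <- simultaneous_bands(p, M, alpha = a)
    br <- band_breach(p, bands)
    expect_false(any(br$above) || any(br$below))
  }
})

test_that("bands at alpha 0.01 contain bands at alpha 0.05", {
  np <- simulate_null_pair(0.5, 5, 300, seed = 58)
  p <- build_psth(np$spikes, np$events)
  surr <- jitter_surrogates(np$events, n_surrogates = 400, seed = 59)
  M <- surrogate_psth_counts(np$spikes, surr)
  b05 <- simultaneous_bands(p, M, alpha = 0.05)
  b01 <- simultaneous_bands(p, M, alpha = 0.01)
  expect_true(all(b01$upper >= b05$upper))
  expect_true(all(b01$lower <= b05$lower))
  expect_true(all(b01$upper >= b01$lower))
  expect_true(all(b01$lower >= 0))
})

test_that("too few surrogates for the requested alpha is an error", {
  p <- build_psth(c(1, 2), c(1.5))
  M <- matrix(0L, length(p$counts), 50)
  expect_error(simultaneous_bands(p, M, alpha = 0.01), "too small")
})

test_that("the analysis span restricts which bins can be flagged", {
  lu <- simulate_locked_unit(unit_spec("cd"), n_events = 800, seed = 60)
  jt <- jitter_test(lu$spikes, lu$events, n_surrogates = 300,
                    alpha = 0.05, span = c(-0.25, 0.25), seed = 61)
  centers <- psth_centers(jt$psth)
  outside <- abs(centers) > 0.25
  expect_true(all(is.na(jt$bands$upper[outside])))
  expect_false(any(jt$breach$above[outside]))
  expect_true(jt$significant)
})

test_that("archetypes are classified into their latency windows", {
  cases <- list(
    cd = list(win = "cd"),
    motor = list(win = "premotor"),
    sensory = list(win = "reafferent"))
  for (a in names(cases)) {
    lu <- simulate_locked_unit(unit_spec(a), n_events = 2000,
                               seed = 70 + match(a, names(cases)))
    jt <- jitter_test(lu$spikes, lu$events, alpha = 0.01, seed = 80)
    rc <- classify_response(jt$psth, jt$bands)
    expect_true(cases[[a]]$win %in% rc$significant_windows,
                label = sprintf("%s window flagged for %s archetype",
                                cases[[a]]$win, a))
    expect_equal(rc$primary_window, cases[[a]]$win)
  }
  # sensory first-breach latency in (10, 60] ms
  lu <- simulate_locked_unit(unit_spec("sensory"), n_events = 2000,
                             seed = 74)
  jt <- jitter_test(lu$spikes, lu$events, alpha = 0.01, seed = 81)
  rc <- classify_response(jt$psth, jt$bands)
  expect_gt(rc$first_breach_latency, 0.010)
  expect_lte(rc$first_breach_latency, 0.060)
})

test_that("an all-zero histogram has no significant window", {
  p <- build_psth(numeric(0), c(1, 2, 3))
  M <- matrix(0L, length(p$counts), 200)
  bands <- simultaneous_bands(p, M, alpha = 0.05)
  rc <- classify_response(p, bands)
  expect_length(rc$significant_windows, 0)
  expect_true(is.na(rc$first_breach_latency))
})

test_that("strongest-muscle selection follows peak rate with stable ties", {
  mk_rc <- function(sig) structure(list(significant_windows = sig),
                                   class = "response_class")
  mk_p <- function(counts, n_events) {
    p <- build_psth(numeric(0), seq_len(n_events))
    p$counts <- counts
    p
  }
  B <- 100
  hi <- mk_p(c(rep(0, 50), 120, rep(0, 49)), 10)   # peak rate 1200 Hz
  lo <- mk_p(c(rep(0, 50), 80, rep(0, 49)), 10)
  r <- select_strongest_muscle(list(nuchal = mk_rc("cd"),
                                    forelimb = mk_rc("cd")),
                               list(nuchal = hi, forelimb = lo))
  expect_equal(r$muscle, "nuchal")
  # only one significant muscle: that one, regardless of peaks
  r2 <- select_strongest_muscle(list(nuchal = mk_rc(character(0)),
                                     forelimb = mk_rc("reafferent")),
                                list(nuchal = hi, forelimb = lo))
  expect_equal(r2$muscle, "forelimb")
  # exact tie: deterministic, first in fixed order
  r3 <- select_strongest_muscle(list(fore = mk_rc("cd"), hind = mk_rc("cd")),
                                list(fore = lo, hind = lo))
  expect_equal(r3$muscle, "fore")
  expect_equal(r3$reason, "order")
  # none significant: non-responsive
  r4 <- select_strongest_muscle(list(a = mk_rc(character(0))),
                                list(a = lo))
  expect_true(is.na(r4$muscle))
})

test_that("pooling one unit is the identity and counts are additive", {
  lu1 <- simulate_locked_unit(unit_spec("cd"), n_events = 300, seed = 91)
  lu2 <- simulate_locked_unit(unit_spec("cd"), n_events = 250, seed = 92)
  p1 <- build_psth(lu1$spikes, lu1$events)
  p2 <- build_psth(lu2$spikes, lu2$events)
  pool1 <- pool_units(list(lu1), n_surrogates = 200, seed = 93)
  expect_equal(pool1$psth$counts, p1$counts)
  expect_equal(pool1$psth$n_events, p1$n_events)
  pool2 <- pool_units(list(lu1, lu2), n_surrogates = 200, seed = 94)
  expect_equal(pool2$psth$counts, p1$counts + p2$counts)
  expect_equal(pool2$psth$n_events, p1$n_events + p2$n_events)
  expect_error(pool_units(list()), "empty")
})

test_that("pooled cd units breach the +/-10 ms window at alpha 0.01", {
  units <- lapply(1:10, function(i)
    simulate_locked_unit(unit_spec("cd"), n_events = 200, seed = 100 + i))
  pool <- pool_units(units, alpha = 0.01, n_surrogates = 1000, seed = 111)
  rc <- classify_response(pool$psth, pool$bands)
  expect_true(pool$significant)
  expect_true("cd" %in% rc$significant_windows)
})

test_that("evoked responses report a plausible latency and protocol warnings", {
  # sensory-like unit stimulated 30 times, >= 5 s apart
  spec <- unit_spec("sensory", kernels = data.frame(center = 0.040,
                                                    width = 0.012,
                                                    gain = 40))
  set.seed(120)
  stim <- event_train(seq(5, 5 * 30, by = 5), "stim_forelimb", 160)
  states <- state_intervals(0, 160, "AS")
  sp <- simulate_unit(spec, states, stim$times, 160)
  er <- evoked_response(sp, stim, alpha = 0.05, seed = 121)
  expect_true(er$significant)
  expect_gt(er$latency, 0.020)
  expect_lte(er$latency, 0.060)

  # no-response unit: nothing significant
  sp0 <- simulate_unit(unit_spec("null"), states, stim$times, 160)
  er0 <- evoked_response(sp0, stim, alpha = 0.05, seed = 122)
  expect_false(er0$significant)
  expect_true(is.na(er0$latency))

  # too few stimulations is an error; tight spacing only warns
  expect_error(evoked_response(sp, event_train(c(5, 10), "stim", 160)),
               "at least")
  tight <- event_train(seq(2, 60, by = 2), "stim", 160)
  spt <- simulate_unit(spec, states, tight$times, 160)
  expect_warning(evoked_response(spt, tight, alpha = 0.05, seed = 123),
                 "spacing")
})
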