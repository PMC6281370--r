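mk_states <- function(rates_by_cycle) {
  # build n cycles of AW/BQ/AS bouts of 10 s each
  n <- nrow(rates_by_cycle)
  start <- seq(0, by = 10, length.out = 3 * n)
  state_intervals(start, start + 10, rep(c("AW", "BQ", "AS"), n))
}

# spikes at a given exact rate per bout (evenly spaced)
mk_spikes <- function(states, rates) {
  t <- unlist(lapply(seq_len(nrow(states)), function(i) {
    r <- rates[i]
    if (r <= 0) return(numeric(0))
    n <- round(r * (states$end[i] - states$start[i]))
    states$start[i] + (seq_len(n) - 0.5) / r
  }))
  spike_train(sort(t), "u")
}

test_that("bout rates are count/duration on half-open bouts", {
  st <- mk_states(matrix(0, 3, 3))
  sp <- spike_train(c(0.5, 1.5, 25, 35, 35.5, 36), "u")
  pr <- bout_rates(sp, st)
  expect_equal(pr$bouts$count[pr$bouts$state == "AW"], c(2, 3, 0))
  expect_equal(pr$bouts$rate, pr$bouts$count / 10)
  # a spike exactly at a bout start belongs to that bout
  sp2 <- spike_train(c(10), "u")
  pr2 <- bout_rates(sp2, st)
  expect_equal(pr2$bouts$count[pr2$bouts$state == "BQ"], c(1, 0, 0))
})

test_that("a zero-spike unit has all-zero rates and no exclusions", {
  st <- mk_states(matrix(0, 4, 3))
  pr <- bout_rates(spike_train(numeric(0), "empty"), st)
  expect_true(all(pr$bouts$rate == 0))
  expect_equal(pr$n_excluded, 0)
})

test_that("the 3 SD rule is a weak filter at small n: {1,1,1,1,100} keeps the 100", {
  # five AS bouts with rates 1,1,1,1,100: mean 20.8, sd 44.3, so 100 is
  # within 3 SD and must NOT be excluded
  st <- state_intervals(seq(0, 40, by = 10), seq(10, 50, by = 10),
                        rep("AS", 5))
  sp <- mk_spikes(st, c(1, 1, 1, 1, 100))
  pr <- bout_rates(sp, st, outlier_sd = 3)
  expect_equal(pr$bouts$rate, c(1, 1, 1, 1, 100))
  expect_false(any(pr$bouts$excluded))
  # but a genuinely extreme bout against many quiet ones is excluded
  st2 <- state_intervals(seq(0, 110, by = 10), seq(10, 120, by = 10),
                         rep("AS", 12))
  sp2 <- mk_spikes(st2, c(rep(1, 11), 100))
  pr2 <- bout_rates(sp2, st2, outlier_sd = 3)
  expect_true(pr2$bouts$excluded[12])
  expect_equal(pr2$n_excluded, 1)
})

test_that("identical rates in all states give state-independent with p = 1", {
  st <- mk_states(matrix(0, 8, 3))
  sp <- mk_spikes(st, rep(4, 24))
  cls <- classify_state(bout_rates(sp, st))
  expect_equal(cls$class, "state-independent")
  expect_equal(cls$p_AS_AW, 1)
})

test_that("AS = AW > BQ gives AS+AW-on", {
  st <- mk_states(matrix(0, 10, 3))
  rates <- rep(c(4, 0, 4), 10)    # AW = 4, BQ = 0, AS = 4
  cls <- classify_state(bout_rates(mk_spikes(st, rates), st))
  expect_equal(cls$class, "AS+AW-on")
})

test_that("too few paired bouts give indeterminate", {
  st <- mk_states(matrix(0, 3, 3))
  cls <- classify_state(bout_rates(mk_spikes(st, rep(1, 9)), st),
                        min_pairs = 5)
  expect_equal(cls$class, "indeterminate")
})

test_that("relabelling AS and AW swaps AS-on and AW-on exactly", {
  set.seed(31)
  for (rep_i in 1:20) {
    n <- 8
    st <- mk_states(matrix(0, n, 3))
    counts <- rpois(3 * n, rep(c(20, 5, 60), n))   # AW, BQ, AS means
    t <- unlist(lapply(seq_len(3 * n), function(i)
      sort(st$start[i] + runif(counts[i]) * 10)))
    sp <- spike_train(sort(t), "u")
    cls <- classify_state(bout_rates(sp, st))
    # swap labels
    lab2 <- c(AW = "AS", BQ = "BQ", AS = "AW")[st$label]
    st2 <- state_intervals(st$start, st$end, lab2)
    cls2 <- classify_state(bout_rates(sp, st2))
    swap <- c("AS-on" = "AW-on", "AW-on" = "AS-on",
              "AS+AW-on" = "AS+AW-on",
              "state-independent" = "state-independent",
              "unclassified" = "unclassified",
              "indeterminate" = "indeterminate")
    expect_equal(cls2$class, unname(swap[cls$class]))
    expect_equal(cls2$p_AS_BQ, cls$p_AW_BQ)
  }
})

test_that("a simulated AS-on archetype is classified AS-on in most replicates", {
  hits <- 0L
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    sim <- sim_config(duration = 700,
                      bout_means = c(AW = 8, BQ = 6, AS = 12),
                      bout_floor = 3, include_emg = FALSE,
                      seed = 4000 + i,
                      unit_specs = list(unit_spec("null",
                        base_rate = c(AW = 2, BQ = 2, AS = 6))))
    s <- simulate_session(sim)
    cls <- classify_state(bout_rates(s$spikes[[1]],
                                     s$ground_truth$true_states))
    if (cls$class == "AS-on") hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("null units are rarely classified state-dependent", {
  set.seed(32)
  n_rep <- 400
  nonind <- 0L
  for (i in seq_len(n_rep)) {
    n <- 10
    st <- mk_states(matrix(0, n, 3))
    counts <- rpois(3 * n, 30)
    t <- unlist(lapply(seq_len(3 * n), function(j)
      sort(st$start[j] + runif(counts[j]) * 10)))
    cls <- classify_state(bout_rates(spike_train(sort(t), "u"), st))
    if (!cls$class %in% c("state-independent", "indeterminate"))
      nonind <- nonind + 1L
  }
  # three tests at alpha = 0.05: expect well under ~3 x alpha overall
  expect_lte(nonind / n_rep, 0.15 + 2 * sqrt(0.15 * 0.85 / n_rep))
})
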