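test_that("2x2 chi-squared without continuity correction matches hand arithmetic", {
  # hand formula: X2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  hand_chi2 <- function(a, b, c, d) {
    N <- a + b + c + d
    N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  set.seed(131)
  for (i in 1:20) {
    t4 <- rpois(4, 10) + 1
    r <- chi_squared_2x2(t4[1], t4[2], t4[3], t4[4])
    expect_equal(r$statistic, hand_chi2(t4[1], t4[2], t4[3], t4[4]))
    expect_equal(r$p, pchisq(r$statistic, 1, lower.tail = FALSE))
    expect_equal(r$df, 1L)
  }
})

test_that("chi-squared is invariant to swapping rows or columns", {
  r0 <- chi_squared_2x2(5, 16, 11, 7)
  expect_equal(chi_squared_2x2(11, 7, 5, 16)$statistic, r0$statistic)
  expect_equal(chi_squared_2x2(16, 5, 7, 11)$statistic, r0$statistic)
})

test_that("proportional rows give chi-squared 0 and degenerate margins error", {
  r <- chi_squared_2x2(10, 10, 5, 5)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_error(chi_squared_2x2(0, 0, 3, 4), "margins")
  expect_error(chi_squared_2x2(1.5, 2, 3, 4), "integers")
})

test_that("mann_whitney matches the pairwise-comparison oracle, ties included", {
  oracle_U <- function(x, y) {
    s <- 0
    for (xi in x) for (yi in y)
      s <- s + (xi > yi) + 0.5 * (xi == yi)
    s
  }
  set.seed(132)
  for (i in 1:50) {
    x <- round(rnorm(sample(4:12, 1), 0, 2), 1)
    y <- round(rnorm(sample(4:12, 1), 0.5, 2), 1)
    r <- mann_whitney(x, y, outlier_sd = Inf)
    expect_equal(r$U_x, oracle_U(x, y))
    # p agrees with the tie-corrected normal approximation in base R
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                       correct = FALSE))
    expect_equal(r$p, wt$p.value, tolerance = 1e-12)
  }
})

test_that("mann_whitney handles identical and fully separated groups", {
  r_same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4), outlier_sd = Inf)
  expect_equal(r_same$Z, 0)
  expect_equal(r_same$p, 1)
  r_sep <- mann_whitney(c(1, 2, 3), c(10, 11, 12), outlier_sd = Inf)
  expect_equal(r_sep$U, 0)
  expect_equal(r_sep$U_x, 0)
  expect_lt(r_sep$p, 0.1)
})

test_that("the 3 SD outlier rule removes extreme values once and is logged", {
  x <- c(rnorm(20), 100)
  set.seed(133)
  r <- mann_whitney(x, rnorm(15), outlier_sd = 3)
  expect_equal(unname(r$n[1]), 20)
  expect_equal(unname(r$excluded[[1]]), 100)
  expect_error(mann_whitney(c(1, 2), c(1)), "at least 2")
})

make_cohort <- function(n_saline = 4, n_apamin = 4, units_per = 2,
                        seed = 1, duration = 500) {
  sessions <- list()
  for (i in seq_len(n_saline + n_apamin)) {
    apamin <- i > n_saline
    specs <- lapply(seq_len(units_per), function(j)
      unit_spec(if (apamin) "apamin_cd" else "cd",
                unit_id = sprintf("p%02du%d", i, j)))
    s <- simulate_session(
      sim_config(duration = duration, include_emg = FALSE,
                 unit_specs = specs, seed = seed * 1000 + i),
      id = sprintf("pup%02d", i),
      group = if (apamin) "apamin" else "saline")
    sessions[[i]] <- s
  }
  sessions
}

test_that("the two-group battery reproduces the broadened-peak pattern", {
  sessions <- make_cohort(n_saline = 5, n_apamin = 4, seed = 7)
  rep_ <- compare_groups(sessions,
                         config = analysis_config(band_alpha = 0.05,
                                                  rng_seed = 71))
  expect_s3_class(rep_, "group_comparison")
  expect_equal(nrow(rep_$behaviour), 9)
  expect_equal(nrow(rep_$unit_table), 18)
  # every cd/apamin_cd unit should be twitch-locked
  expect_true(all(rep_$unit_table$significant))
  # apamin-archetype units carry the post-twitch tail: larger 20-200 ms AUC
  expect_lt(rep_$auc_tests$reafferent$p, 0.05)
  med <- rep_$auc_tests$reafferent$median
  expect_gt(med[["apamin"]], med[["saline"]])
  # pooled histograms exist for both groups with a smoothed trace
  expect_false(is.null(rep_$pooled$saline))
  expect_length(rep_$pooled$apamin$smoothed_rate, 100)
  # normalized averages have peak <= 1
  expect_lte(max(rep_$normalized$saline$mean), 1)
})

test_that("the battery is deterministic under a fixed seed", {
  sessions <- make_cohort(n_saline = 2, n_apamin = 2, units_per = 1,
                          seed = 9, duration = 400)
  r1 <- compare_groups(sessions, config = analysis_config(band_alpha = 0.05,
                                                          rng_seed = 5))
  r2 <- compare_groups(sessions, config = analysis_config(band_alpha = 0.05,
                                                          rng_seed = 5))
  expect_identical(r1$unit_table, r2$unit_table)
  expect_identical(r1$auc_tests$reafferent$p, r2$auc_tests$reafferent$p)
})

test_that("missing groups and twitch-free sessions fail cleanly", {
  sessions <- make_cohort(n_saline = 2, n_apamin = 2, units_per = 1,
                          seed = 11, duration = 400)
  expect_error(compare_groups(sessions, groups = c("saline", "muscimol")),
               "missing group")
  bad <- sessions
  bad[[1]]$events <- list()
  expect_error(compare_groups(bad), "no twitch events")
})

test_that("single-unit groups skip the proportion tests with a logged reason", {
  sessions <- make_cohort(n_saline = 1, n_apamin = 1, units_per = 1,
                          seed = 13, duration = 400)
  r <- compare_groups(sessions)
  # both units are event-locked, so the significant/not table has an empty
  # column and the chi-squared step must be skipped, not forced
  expect_null(r$proportions$significant)
  expect_true(any(grepl("skipped", r$log)))
  # rank tests cannot run with one unit per group
  expect_null(r$auc_tests$reafferent)
})
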