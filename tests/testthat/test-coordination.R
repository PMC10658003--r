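test_that("identical series give unit synchrony at zero lag", {
  set.seed(1)
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), 6400))
  w <- wclc_synchrony(x, x, 0.01)
  expect_equal(w$summary, 1, tolerance = 1e-9)
  expect_true(all(abs(w$per_window$peak_lag_s) < 1e-9))
})

test_that("a 1 s shift is recovered as the peak lag", {
  set.seed(2)
  x <- as.numeric(stats::arima.sim(list(ar = 0.95), 6400))
  y <- c(rep(0, 100), x[1:6300])      # y trails x by 1 s
  w <- wclc_synchrony(x, y, 0.01)
  expect_gt(w$summary, 0.95)
  expect_equal(stats::median(w$per_window$peak_lag_s), 1, tolerance = 1e-9)
})

test_that("the fast WCLC equals the naive loop on gappy noise", {
  set.seed(3)
  n <- 6400
  a <- stats::rnorm(n) + 60
  b <- stats::rnorm(n) + 55
  a[sample(n, 600)] <- NA
  b[sample(n, 500)] <- NA
  cfg <- wclc_config()
  fast <- wclc_synchrony(a, b, 0.01, cfg)
  ref <- naive_wclc(a, b, 0.01, cfg)
  expect_equal(fast$summary, ref$summary, tolerance = 1e-10)
  expect_equal(fast$per_window$peak_r[fast$per_window$used], ref$peaks,
               tolerance = 1e-10)
  # and under the absolute-peak rule
  cfg2 <- wclc_config(peak_rule = "max_abs")
  expect_equal(wclc_synchrony(a, b, 0.01, cfg2)$summary,
               naive_wclc(a, b, 0.01, cfg2)$summary, tolerance = 1e-10)
})

test_that("swapping the series negates the peak lags window by window", {
  set.seed(4)
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), 3200)) + 60
  y <- as.numeric(stats::arima.sim(list(ar = 0.9), 3200)) + 55
  wxy <- wclc_synchrony(x, y, 0.01)
  wyx <- wclc_synchrony(y, x, 0.01)
  expect_equal(wxy$per_window$peak_r, wyx$per_window$peak_r,
               tolerance = 1e-10)
  expect_equal(wxy$per_window$peak_lag_s, -wyx$per_window$peak_lag_s,
               tolerance = 1e-10)
})

test_that("synchrony is invariant to shifting and positive scaling", {
  set.seed(5)
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), 3200))
  y <- as.numeric(stats::arima.sim(list(ar = 0.9), 3200))
  w1 <- wclc_synchrony(x, y, 0.01)
  w2 <- wclc_synchrony(x * 3 + 10, y * 0.25 - 7, 0.01)
  expect_equal(w1$summary, w2$summary, tolerance = 1e-9)
  expect_true(w1$summary >= -1 && w1$summary <= 1)
  wa <- wclc_synchrony(x, y, 0.01, wclc_config(peak_rule = "max_abs"))
  expect_true(wa$summary >= 0 && wa$summary <= 1)
})

test_that("degenerate WCLC inputs raise the documented errors", {
  expect_error(wclc_synchrony(rnorm(100), rnorm(100), 0.01),
               "shorter than one window")
  expect_error(wclc_synchrony(rep(1, 3200), rep(1, 3200), 0.01),
               "no usable windows")
  expect_error(wclc_config(window_s = 3, max_lag_s = 2), "twice max_lag_s")
  expect_error(wclc_config(step_s = 20), "exceed window_s")
})

test_that("turn adaptation is the lag-one cross-turn correlation", {
  tp <- data.frame(turn_id = 1:8, speaker = rep(c("A", "B"), 4),
                   gap_before_s = 0,
                   mean_pitch_hz = c(100, 100, 150, 150, 120, 120, 180, 180),
                   mean_intensity_db = c(60, 61, 62, 63, 64, 65, 66, 67),
                   n_syllables = 5,
                   articulation_rate_sps = c(4, 4, 5, 5, 3, 3, 6, 6))
  # B copies A's previous turn exactly -> perfect adaptation
  ad <- turn_adaptation(tp, "B")
  expect_equal(ad$adapt_pitch, 1)
  expect_equal(ad$adapt_articulation, 1)
  # constant own values -> zero variance -> undefined
  tp2 <- tp
  tp2$mean_pitch_hz[tp2$speaker == "B"] <- 130
  expect_error(turn_adaptation(tp2, "B"), "zero variance")
  # too few turns -> undefined
  expect_error(turn_adaptation(tp[1:4, ], "B"), "fewer than 3")
})

test_that("surrogate machinery is deterministic given the seed", {
  set.seed(10)
  x <- stats::rnorm(3200) + 60
  y <- stats::rnorm(3200) + 58
  s1 <- pseudo_synchrony(x, y, 0.01, n_surrogates = 100, seed = 77)
  s2 <- pseudo_synchrony(x, y, 0.01, n_surrogates = 100, seed = 77)
  expect_identical(s1$surrogates, s2$surrogates)
  expect_length(s1$surrogates, 100L)
  expect_equal(s1$surrogate_mean, mean(s1$surrogates))
  s3 <- pseudo_synchrony(x, y, 0.01, n_surrogates = 100, seed = 78)
  expect_false(identical(s1$surrogates, s3$surrogates))
})

test_that("segment shuffling permutes whole blocks and keeps the tail", {
  v <- 1:10
  set.seed(1)
  s <- shuffle_segments(v, 3)
  expect_equal(sort(s[1:9]), 1:9)
  expect_equal(s[10], 10)
  expect_equal(sort(unique((s[1:9] - 1) %/% 3)), 0:2)
})

test_that("planted intensity adaptation of 0.6 is recovered in range", {
  vals <- numeric(0)
  for (rep in 1:10) {
    cfg <- generator_config(n_mixed_dyads = 0, n_nonautistic_dyads = 10,
                            tasks = "hobbies", seed = 400 + rep,
                            adapt_gain = c(pitch = 0.35, intensity = 0.6,
                                           articulation = 0.35))
    for (r in generate_corpus(cfg)$records) {
      ts <- segment_turns(r$annotations)
      tp <- turn_prosody(ts, r$tracks)
      for (sp in r$annotations$speakers)
        vals <- c(vals, turn_adaptation(tp, sp)$adapt_intensity)
    }
  }
  expect_gte(length(vals), 200L)
  expect_gt(mean(vals), 0.3)
  expect_lt(mean(vals), 0.9)
})

test_that("paired Bayes factor behaves at the null and under strong effects", {
  # all-zero differences favour the null rather than erroring
  expect_lt(compare_to_pseudo(rep(0.3, 30), rep(0.3, 30)), 0)
  # d = 1 with n = 40 is decisive
  set.seed(6)
  d <- stats::rnorm(40, 1, 1)
  obs <- stats::rnorm(40, 5); lb <- compare_to_pseudo(obs + d, obs)
  expect_gt(lb, 4.6)
  expect_equal(grade_evidence(lb)$label, "decisive")
})

test_that("the JZS routine matches an independent quadrature oracle", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    t <- stats::rt(1, n - 1) + stats::runif(1, -1, 3)
    one <- sample(c(TRUE, FALSE), 1)
    mine <- jzs_logbf_t(t, n, n - 1, one_sided = one)
    ora <- trapz_jzs_logbf(t, n, n - 1, one_sided = one)
    # relative agreement of the Bayes factors themselves
    expect_lt(abs(exp(mine - ora) - 1), 0.01)
  }
})
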