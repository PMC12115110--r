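test_that("multi-level smoothing behaves like a centred moving average", {
  plan <- smoothing_plan(4, 250)
  expect_equal(plan$windows, c(100, 250, 500, 1000))
  cst <- smooth_multilevel(rep(3.2, 2000), plan)
  for (s in cst) expect_equal(s, rep(3.2, 2000))
  # unit impulse, window 5 -> plateau of 1/5 over 5 samples
  imp <- numeric(101); imp[51] <- 1
  sm <- moving_average_for_test <- smooth_multilevel(imp, structure(
    list(windows = 5L, fractions = NA), class = "smoothing_plan"))[[1]]
  expect_equal(sm[49:53], rep(0.2, 5))
  expect_equal(sum(sm > 0), 5)
  # white noise variance non-increasing across levels
  set.seed(3)
  wn <- rnorm(5000)
  v <- vapply(smooth_multilevel(wn, plan), stats::var, numeric(1))
  expect_true(all(diff(v) < 0))
  expect_error(smooth_multilevel(rnorm(500), plan), "exceeds")
})

test_that("cross-correlation recovers constructed shifts with the stated sign convention", {
  set.seed(6)
  a <- rnorm(600)
  xc0 <- xcorr_best_lag(a, a, 100)
  expect_equal(xc0$best_lag, 0L)
  expect_equal(xc0$peak_abs_r, 1)
  # b = a delayed by k samples -> best_lag = -k (first series leads)
  for (k in c(7, 40)) {
    b <- c(numeric(k), a[1:(600 - k)])
    expect_equal(xcorr_best_lag(a, b, 100)$best_lag, -k)
  }
  z <- xcorr_best_lag(rep(1, 100), rnorm(100), 20)
  expect_equal(z$flag, "zero_variance")
  expect_true(is.na(z$peak_abs_r))
  expect_error(xcorr_best_lag(a, a, 400), "max_lag")
})

test_that("xcf is invariant to shift and positive scaling (Pearson normalization)", {
  set.seed(8)
  a <- rnorm(500); b <- rnorm(500)
  r1 <- xcorr_best_lag(a, b, 80)
  r2 <- xcorr_best_lag(3 * a + 10, 0.2 * b - 4, 80)
  expect_equal(r1$xcf, r2$xcf, tolerance = 1e-12)
})

test_that("independent white noise stays under the family-wise null bound", {
  # the per-lag 99.9% envelope is 3.29/sqrt(n); the maximum over 2L+1 lags
  # needs the Sidak-corrected bound instead
  set.seed(10)
  n <- 2000; L <- 500
  xc <- xcorr_best_lag(rnorm(n), rnorm(n), L)
  bound <- stats::qnorm(1 - 0.001 / (2 * (2 * L + 1))) / sqrt(n)
  expect_lt(xc$peak_abs_r, bound)
  # permutation check: the observed peak is not extreme under shuffling
  set.seed(11)
  a <- rnorm(n); b <- rnorm(n)
  obs <- xcorr_best_lag(a, b, L)$peak_abs_r
  null_peaks <- replicate(30, xcorr_best_lag(sample(a), b, L)$peak_abs_r)
  expect_gt(mean(null_peaks >= obs), 0.05)
})

test_that("the correlation study honours its contracts on a small session", {
  ses <- fx_cached("ses_corr3", function() {
    generate_session(n_motion = 3, n_static = 1, config = trial_config(),
                     seed = 17)
  })
  cs <- correlate_study(ses, "stft", decoding_bandset())
  expect_equal(nrow(cs$table), 15 * 1 * 3)   # electrodes x bands x segments
  expect_true(all(cs$table$peak_abs_r >= 0 & cs$table$peak_abs_r <= 1))
  expect_true(all(cs$aggregates$mean_abs_r >= 0 & cs$aggregates$mean_abs_r <= 1))
  # documented aggregation order: mean of |r| over electrodes
  for (i in seq_len(nrow(cs$aggregates))) {
    sel <- cs$table$band == cs$aggregates$band[i] &
      cs$table$segment == cs$aggregates$segment[i]
    expect_equal(cs$aggregates$mean_abs_r[i], mean(cs$table$peak_abs_r[sel]))
  }
  # even 3 trials put the bulk of electrode-level leads at the injected 2 s
  # (segment-level means are noisy at this trial count; the 11-trial study
  # in the acceptance suite checks the mean strictly)
  expect_lt(abs(stats::median(cs$table$lead_s) - 2), 0.25)
  ses_static <- generate_session(n_motion = 0, n_static = 1, seed = 3)
  expect_error(correlate_study(ses_static, "stft"), "no motion trials")
})

test_that("without coupling the aggregate correlation collapses to the noise level", {
  ses0 <- fx_cached("ses_gain0", function() {
    generate_session(n_motion = 3, n_static = 0,
                     config = trial_config(coupling_gain = 0), seed = 17)
  })
  ses1 <- fx_cached("ses_corr3", function() {
    generate_session(n_motion = 3, n_static = 1, config = trial_config(),
                     seed = 17)
  })
  r0 <- correlate_study(ses0, "stft", decoding_bandset())$aggregates$mean_abs_r
  r1 <- correlate_study(ses1, "stft", decoding_bandset())$aggregates$mean_abs_r
  expect_true(all(r0 < r1))
  expect_lt(mean(r0), 0.5)
})
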