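fs <- 250

test_that("high-pass kills DC and matches the closed-form Butterworth response", {
  n <- 20 * fs
  t <- (0:(n - 1)) / fs
  # closed-form magnitude of a 2nd-order high-pass Butterworth at f (fc = 1)
  hmag <- function(f, fc = 1) (f / fc)^2 / sqrt(1 + (f / fc)^4)
  post <- function(x) prefilter(matrix(x, 1), fs = fs)[1, (5 * fs):n]
  expect_lt(max(abs(post(rep(3, n)))), 1e-4)
  amp10 <- stats::sd(post(sin(2 * pi * 10 * t))) * sqrt(2)
  expect_lt(abs(amp10 - hmag(10)), 0.01)
  amp01 <- stats::sd(post(sin(2 * pi * 0.1 * t))) * sqrt(2)
  expect_lt(abs(amp01 / hmag(0.1) - 1), 0.05)
  expect_error(prefilter(matrix(0, 1, 10), filter_spec(highpass_fc = 130),
                         fs = fs), "Nyquist")
})

test_that("prefilter and hinf_clean are causal (prefix equality)", {
  set.seed(8)
  n <- 4 * fs
  x <- matrix(rnorm(2 * n), 2)
  eog <- matrix(rnorm(4 * n), 4)
  full <- prefilter(x, fs = fs)
  half <- prefilter(x[, 1:(n / 2)], fs = fs)
  expect_equal(full[, 1:(n / 2)], half)
  hf <- hinf_clean(x, eog)$cleaned
  hh <- hinf_clean(x[, 1:(n / 2)], eog[, 1:(n / 2)])$cleaned
  expect_equal(hf[, 1:(n / 2)], hh)
})

test_that("H-infinity cleaning removes a known EOG mix and spares clean rhythm", {
  tr <- fx_trial()
  eog <- tr$recording$eog
  n <- ncol(eog)
  v <- eog[1, ] - eog[2, ]
  h <- eog[4, ] - eog[3, ]
  art <- matrix(c(0.3, 0.1, 0.15, -0.05), 2, 2) %*% rbind(v, h)
  set.seed(2)
  noise <- matrix(rnorm(2 * n, 0, 1), 2, n)
  cleaned <- hinf_clean(art + noise, eog)$cleaned
  conv <- (15 * fs):n  # after the protocol's convergence window
  excess <- pmax(0, rowMeans(cleaned[, conv]^2) - 1)  # residual beyond noise
  expect_true(all(excess / rowMeans(art[, conv]^2) < 0.05))
  # a 10 Hz rhythm uncorrelated with the EOG passes within 10%
  s10 <- sin(2 * pi * 10 * (0:(n - 1)) / fs)
  out <- hinf_clean(rbind(s10 + art[1, ]), eog)$cleaned[1, conv]
  expect_lt(abs(stats::sd(out) / stats::sd(s10[conv]) - 1), 0.1)
})

test_that("H-infinity weights converge within the 15 s window", {
  tr <- fx_trial()
  eog <- tr$recording$eog
  v <- eog[1, ] - eog[2, ]
  h <- eog[4, ] - eog[3, ]
  eeg <- matrix(0.3 * v + 0.1 * h, 1)
  hc <- hinf_clean(eeg, eog)
  wp <- hc$weight_path
  dw <- sqrt(rowSums(diff(wp)^2))
  expect_lt(mean(dw[(14 * fs):(15 * fs)]), 0.25 * mean(dw[fs:(2 * fs)]))
  expect_error(hinf_clean(eeg, eog, list(gamma = 0.9)), "gamma")
})

test_that("with zero EOG and no bias term, cleaning is the identity", {
  set.seed(3)
  x <- matrix(rnorm(400), 2)
  z <- matrix(0, 4, 200)
  out <- hinf_clean(x, z, list(include_bias = FALSE))$cleaned
  expect_equal(out, x)
})

test_that("channel selection reduces and reorders; unknown labels are named", {
  rec <- fx_trial()$recording
  sel <- select_channels(rec)
  expect_equal(sel$channel_names, motor_montage())
  expect_equal(nrow(sel$eeg), 15)
  expect_equal(sel$eeg[6, ], rec$eeg[match("CZ", rec$channel_names), ])
  ident <- select_channels(rec, rec$channel_names)
  expect_equal(ident$eeg, rec$eeg)
  expect_error(select_channels(rec, c("CZ", "XX")), "XX")
})

test_that("MVT normalization reproduces the worked value and its invariances", {
  st <- new_mvt_state(1)
  mv <- mvt_normalize(matrix(1:10, 1), st)
  expect_equal(unname(mv$state$current_mvt), 7.5)  # mean of {10,9,8,7,6,5}
  expect_equal(mv$normalized[1, ], (1:10) / 7.5)
  # scale invariance: all channels scaled by c > 0 leaves SV unchanged
  set.seed(5)
  w <- matrix(rnorm(60), 3)
  a <- mvt_normalize(w, new_mvt_state(3))$normalized
  b <- mvt_normalize(5.7 * w, new_mvt_state(3))$normalized
  expect_equal(a, b)
  # single constant channel normalizes to 1
  cc <- mvt_normalize(matrix(4, 1, 20), new_mvt_state(1))$normalized
  expect_equal(unname(cc), matrix(1, 1, 20))
  expect_error(mvt_normalize(matrix(1:4, 1), new_mvt_state(1)), "n_top")
  # determinism of the state trajectory
  s1 <- new_mvt_state(3); s2 <- new_mvt_state(3)
  for (i in 1:4) {
    wi <- matrix(rnorm(30), 3)
    s1 <- mvt_normalize(wi, s1)$state
    s2 <- mvt_normalize(wi, s2)$state
  }
  expect_identical(s1, s2)
})

test_that("IMU resampling interpolates linearly onto the EEG grid", {
  expect_equal(ncol(resample_imu(matrix(1, 1, 1000), 100, 250)), 2500)
  cst <- resample_imu(matrix(7, 2, 300), 100, 250)
  expect_true(all(cst == 7))
  t100 <- (0:999) / 100
  s <- sin(2 * pi * 1 * t100)
  r <- resample_imu(matrix(s, 1), 100, 250)[1, ]
  truth <- sin(2 * pi * 1 * (0:2499) / 250)
  # compare where interpolation is defined; past the last source sample the
  # output is clamped by design
  ok <- (0:2499) / 250 <= max(t100)
  expect_lt(sqrt(mean((r - truth)[ok]^2)) / sqrt(mean(truth^2)), 1e-3)
  expect_error(resample_imu(matrix(1, 1, 1), 100, 250), "two samples")
})
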