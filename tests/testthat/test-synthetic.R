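test_that("trials follow the protocol timing to one sample", {
  tr <- fx_trial()
  rec <- tr$recording
  expect_equal(ncol(rec$eeg), 78 * 250)          # 15+15+28+15+5 s
  expect_equal(ncol(rec$imu), 78 * 100)
  ann <- rec$annotations
  expect_equal(ann$label, c("converge", "relax1", "mi", "relax2", "return"))
  expect_equal(ann$start_s, c(0, 15, 30, 58, 73))
  expect_equal(ann$end_s, c(15, 30, 58, 73, 78))
  # boundaries land exactly on samples
  expect_true(all(abs(ann$start_s * 250 - round(ann$start_s * 250)) == 0))
  expect_equal(nrow(rec$eeg), 28)
  expect_equal(nrow(rec$eog), 4)
  expect_equal(rec$imu_names, c("wheel_L", "wheel_R", "insole_L", "insole_R"))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(trial_config(segment_durations_s = c(converge = -1, relax1 = 15,
                                                    mi = 28, relax2 = 15,
                                                    return = 5)),
               "converge")
  expect_error(trial_config(fs_eeg = 0), "fs_eeg")
  expect_error(trial_config(fs_imu = 300), "fs_imu")
  expect_error(trial_config(erd_depth = 1.5), "erd_depth")
})

test_that("generation is bit-identical under a fixed seed and varies across seeds", {
  a <- generate_trial(trial_config(), seed = 21)
  b <- generate_trial(trial_config(), seed = 21)
  c <- generate_trial(trial_config(), seed = 22)
  expect_identical(a$recording$eeg, b$recording$eeg)
  expect_identical(a$recording$imu, b$recording$imu)
  expect_false(identical(a$recording$eeg, c$recording$eeg))
  s1 <- generate_session(n_motion = 1, n_static = 1, seed = 5)
  s2 <- generate_session(n_motion = 1, n_static = 1, seed = 5)
  expect_identical(s1$trials[[1]]$recording$eeg, s2$trials[[1]]$recording$eeg)
})

test_that("sessions alternate trial kinds and honour the counts", {
  ses <- fx_session_small()
  expect_equal(ses$trial_kinds, c("motion", "static", "motion", "static"))
  ses1 <- generate_session(n_motion = 1, n_static = 0, seed = 2)
  expect_equal(length(ses1$trials), 1L)
  expect_equal(ses1$trial_kinds, "motion")
})

test_that("static trials carry only sensor noise on the IMU", {
  tr <- generate_trial(trial_config(trial_kind = "static",
                                    sensor_noise_deg = 0), seed = 4)
  expect_equal(stats::var(as.numeric(tr$recording$imu)), 0)
  tr2 <- generate_trial(trial_config(trial_kind = "static",
                                     sensor_noise_deg = 0.3), seed = 4)
  expect_lt(stats::sd(as.numeric(tr2$recording$imu)), 0.5)
})

test_that("MI-segment 8-20 Hz energy is non-increasing in erd_depth", {
  fs <- 250
  mi_energy <- vapply(c(0, 0.25, 0.5, 0.75), function(d) {
    tr <- generate_trial(trial_config(erd_depth = d), seed = 31)
    x <- tr$recording$eeg[10, ]  # CZ
    e <- stft_energy(x, c(8, 20), fs = fs)$values
    mean(e[(31 * fs):(57 * fs)])
  }, numeric(1))
  expect_true(all(diff(mi_energy) < 0))
})

test_that("the injected energy-IMU lag is recoverable exactly in the noiseless limit", {
  for (lag in c(2.0, 1.2)) {
    cfg <- trial_config(sensor_noise_deg = 0, movement_amplitude_deg = 0,
                        coupling_lag_s = lag)
    tr <- generate_trial(cfg, seed = 11)
    expect_equal(tr$ground_truth$injected_lag_samples, round(lag * 250))
    env <- tr$ground_truth$envelope
    imu <- resample_imu(tr$recording$imu["insole_L", , drop = FALSE],
                        100, 250)[1, ]
    seg <- (16 * 250):(72 * 250)   # inside the movement window
    xc <- xcorr_best_lag(env[seg], imu[seg], round(lag * 250) + 200)
    expect_lte(abs(xc$best_lag + round(lag * 250)), 1)
    expect_gt(xc$peak_abs_r, 0.99)
  }
})

test_that("with erd_depth = 0 the MI energy distribution matches relax", {
  # independent trials; MI means from one half, relax1 means from the other,
  # over matched 15 s windows, so the two samples are independent and the
  # marginals coincide under the null
  fs <- 250
  n_tr <- 30
  seeds <- 1000 + seq_len(n_tr)
  vals <- vapply(seeds, function(s) {
    tr <- generate_trial(trial_config(erd_depth = 0), seed = s)
    e <- stft_energy(tr$recording$eeg[10, ], c(8, 20), fs = fs)$values
    c(mi = mean(e[(30 * fs + 1):(45 * fs)]),
      rx = mean(e[(15 * fs + 1):(30 * fs)]))
  }, numeric(2))
  ks <- suppressWarnings(stats::ks.test(vals["mi", 1:15], vals["rx", 16:30]))
  expect_gt(ks$p.value, 0.01)
})
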