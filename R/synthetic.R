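# Synthetic session generator.
#
# Emulates the statistical structure the analyses assume, with known ground
# truth: pink-noise EEG background, band-limited sensorimotor rhythms whose
# 8-30 Hz components undergo event-related desynchronization (ERD) during
# motor imagery, ocular artifacts linearly mixed into the EEG, and - for
# motion trials - a cyclic dorsiflexion/plantarflexion angle trace coupled to
# a lag-shifted copy of the sensorimotor-rhythm energy envelope. The
# movement is exoskeleton-driven and identical in every trial, so the
# movement-locked part of the rhythm modulation is shared across a session's
# motion trials; that is what survives the trial averaging the correlation
# study performs.

EEG_CHANNELS_28 <- c("AF3", "F3", "FZ", "FC3", "FC1", "FCZ", "C5", "C3", "C1",
                     "CZ", "CP3", "CP1", "CPZ", "P3", "PZ", "PO3", "AF4", "F4",
                     "FC2", "FC4", "C2", "C4", "C6", "CP2", "CP4", "P4", "POZ",
                     "PO4")
EOG_CHANNELS <- c("VU", "VD", "HL", "HR")
IMU_STREAMS <- c("wheel_L", "wheel_R", "insole_L", "insole_R")

#' The fifteen motor-area electrodes used for analysis
#' @return Character vector of channel labels.
#' @export
motor_montage <- function() {
  c("FC3", "FC1", "FCZ", "C3", "C1", "CZ", "CP3", "CP1", "CPZ",
    "FC2", "FC4", "C2", "C4", "CP2", "CP4")
}

default_eog_mixing <- function(channel_names) {
  prefix_gain_v <- c(AF = 0.25, F = 0.18, FC = 0.12, C = 0.07, CP = 0.045,
                     P = 0.03, PO = 0.02)
  prefix_gain_h <- c(AF = 0.10, F = 0.08, FC = 0.05, C = 0.03, CP = 0.02,
                     P = 0.015, PO = 0.015)
  pref <- sub("[0-9Z]+$", "", channel_names)
  cbind(v = unname(prefix_gain_v[pref]), h = unname(prefix_gain_h[pref]))
}

#' Trial configuration for the synthetic generator
#'
#' Defaults follow the experimental protocol: 250 Hz EEG/EOG, 100 Hz IMU,
#' segments converge (15 s), relax1 (15 s), MI (28 s), relax2 (15 s), return
#' (5 s) - a 78 s trial - and five rhythm components at 0.6, 6, 15, 32 and
#' 64 Hz. See the methods vignette for the rationale behind each default.
#'
#' @param trial_kind `"motion"` or `"static"`.
#' @param fs_eeg,fs_imu Sampling rates, Hz (`fs_imu < fs_eeg`).
#' @param segment_durations_s Named durations in seconds.
#' @param rhythm_components Data frame with `center` (Hz), `bw` (Hz),
#'   `amp` (uV sd of the component).
#' @param erd_depth Fractional amplitude reduction of the 8-30 Hz components
#'   during the MI segment, in \[0, 1\].
#' @param coupling_lag_s EEG-energy-to-IMU lag, seconds (energy leads).
#' @param coupling_gain Dimensionless gain on the envelope leak into the IMU.
#' @param coupling_amp_deg Angle sd (degrees) of a unit-gain envelope leak.
#' @param movement_period_s Seconds per DF-PF cycle.
#' @param movement_amplitude_deg Peak cycle amplitude, degrees.
#' @param sensor_noise_deg IMU sensor noise sd, degrees.
#' @param eog_mixing Channels x 2 matrix (vertical, horizontal source gains);
#'   `NULL` = frontally weighted default.
#' @param noise_exponent Pink-noise 1/f^beta slope.
#' @param noise_sd Broadband background sd, uV.
#' @param shared_mod_depth,trial_mod_depth Depths of the movement-locked
#'   (session-shared) and idiosyncratic amplitude modulation of the
#'   sensorimotor component.
#' @param modulation_bw_hz Bandwidth of the modulation processes, Hz.
#' @param coupled_band Band (Hz) whose component envelope leaks into the IMU.
#' @param seed Optional default seed stored with the config.
#' @return Object of class `trial_config`.
#' @export
trial_config <- function(trial_kind = c("motion", "static"),
                         fs_eeg = 250, fs_imu = 100,
                         segment_durations_s = c(converge = 15, relax1 = 15,
                                                 mi = 28, relax2 = 15,
                                                 return = 5),
                         rhythm_components = data.frame(
                           center = c(0.6, 6, 15, 32, 64),
                           bw = c(0.4, 1.5, 4, 5, 8),
                           amp = c(8, 5, 8, 4, 2.5)),
                         erd_depth = 0.3,
                         coupling_lag_s = 2.0,
                         coupling_gain = 1.0,
                         coupling_amp_deg = 12,
                         movement_period_s = 4,
                         movement_amplitude_deg = 5,
                         sensor_noise_deg = 0.3,
                         eog_mixing = NULL,
                         noise_exponent = 1,
                         noise_sd = 5,
                         shared_mod_depth = 0.4,
                         trial_mod_depth = 0.4,
                         modulation_bw_hz = 1.2,
                         coupled_band = c(8, 20),
                         seed = 1L) {
  trial_kind <- match.arg(trial_kind)
  if (fs_eeg <= 0) stop_field("trial_config: fs_eeg must be positive (got %s)", fs_eeg)
  if (fs_imu <= 0) stop_field("trial_config: fs_imu must be positive (got %s)", fs_imu)
  if (fs_imu >= fs_eeg) stop_field("trial_config: fs_imu must be < fs_eeg")
  if (any(segment_durations_s <= 0)) {
    bad <- names(segment_durations_s)[which(segment_durations_s <= 0)[1]]
    stop_field("trial_config: segment_durations_s['%s'] must be positive", bad)
  }
  if (erd_depth < 0 || erd_depth > 1) {
    stop_field("trial_config: erd_depth must be in [0, 1] (got %s)", erd_depth)
  }
  if (movement_period_s <= 0) stop_field("trial_config: movement_period_s must be positive")
  structure(list(trial_kind = trial_kind, fs_eeg = fs_eeg, fs_imu = fs_imu,
                 segment_durations_s = segment_durations_s,
                 rhythm_components = rhythm_components,
                 erd_depth = erd_depth, coupling_lag_s = coupling_lag_s,
                 coupling_gain = coupling_gain,
                 coupling_amp_deg = coupling_amp_deg,
                 movement_period_s = movement_period_s,
                 movement_amplitude_deg = movement_amplitude_deg,
                 sensor_noise_deg = sensor_noise_deg,
                 eog_mixing = eog_mixing, noise_exponent = noise_exponent,
                 noise_sd = noise_sd, shared_mod_depth = shared_mod_depth,
                 trial_mod_depth = trial_mod_depth,
                 modulation_bw_hz = modulation_bw_hz,
                 coupled_band = coupled_band, seed = seed),
            class = "trial_config")
}

# 1/f^beta noise, unit sd, via FFT spectral shaping
pink_noise <- function(n, beta) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index, DC treated as f=1
  X <- X / f^(beta / 2)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# unit-variance narrowband noise centred on fc with Gaussian bandwidth bw
narrowband_noise <- function(n, fs, fc, bw) {
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f[f > fs / 2] <- f[f > fs / 2] - fs
  mask <- exp(-(abs(f) - fc)^2 / (2 * (bw / 2)^2))
  x <- Re(stats::fft(X * mask, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# smooth standardized random modulation, lowpass at bw_hz
smooth_modulation <- function(n, fs, bw_hz) {
  bf <- signal::butter(4, min(0.99, 2 * bw_hz / fs), type = "low")
  m <- signal::filtfilt(bf, stats::rnorm(n))
  as.numeric(scale(m))
}

# raised-cosine ramped gate over [t0, t1] seconds with ramp_s edges
gate <- function(t, t0, t1, ramp_s = 0.5) {
  g <- numeric(length(t))
  g[t >= t0 & t <= t1] <- 1
  up <- t >= t0 - ramp_s & t < t0
  g[up] <- 0.5 - 0.5 * cos(pi * (t[up] - (t0 - ramp_s)) / ramp_s)
  dn <- t > t1 & t <= t1 + ramp_s
  g[dn] <- 0.5 + 0.5 * cos(pi * (t[dn] - t1) / ramp_s)
  g
}

blink_train <- function(t, fs, rate_hz = 0.2, amp_mean = 150, width_s = 0.3) {
  n <- length(t)
  v <- numeric(n)
  n_ev <- stats::rpois(1, rate_hz * t[n])
  if (n_ev > 0) {
    times <- sort(stats::runif(n_ev, 0, t[n]))
    amps <- stats::rnorm(n_ev, amp_mean, 20)
    for (i in seq_len(n_ev)) {
      u <- (t - times[i]) / width_s
      sel <- u > -1 & u < 1
      v[sel] <- v[sel] + amps[i] * (0.5 + 0.5 * cos(pi * u[sel]))^2
    }
  }
  v
}

saccade_train <- function(t, fs, rate_hz = 0.1, amp_sd = 45, ramp_s = 0.05) {
  n <- length(t)
  h <- numeric(n)
  n_ev <- stats::rpois(1, rate_hz * t[n])
  if (n_ev > 0) {
    times <- sort(stats::runif(n_ev, 0, t[n]))
    amps <- stats::rnorm(n_ev, 0, amp_sd)
    level <- 0
    for (i in seq_len(n_ev)) {
      u <- (t - times[i]) / ramp_s
      h <- h + amps[i] * stats::plogis(u * 6)
    }
  }
  h - mean(h)
}

#' Generate one synthetic trial
#'
#' @param config A [trial_config()].
#' @param seed Integer seed; identical (config, seed) gives bit-identical
#'   output.
#' @param shared_mod Optional session-level movement-locked modulation series
#'   (length = EEG samples). `NULL` derives one from the seed, so standalone
#'   trials remain self-contained.
#' @return List with `recording` (class `tf_recording`) and `ground_truth`
#'   (class `synth_ground_truth`: `injected_lag_samples`, `erd_depth`,
#'   `component_freqs`, `segment_labels`, `envelope` - the standardized
#'   energy-envelope copy the IMU couples to, on the EEG grid).
#' @export
generate_trial <- function(config = trial_config(), seed = config$seed,
                           shared_mod = NULL) {
  stopifnot(inherits(config, "trial_config"))
  with_seed(seed, generate_trial_impl(config, shared_mod, seed))
}

generate_trial_impl <- function(config, shared_mod, seed) {
  fs <- config$fs_eeg
  durs <- config$segment_durations_s
  total_s <- sum(durs)
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1) / fs
  n_imu <- round(total_s * config$fs_imu)
  t_imu <- (seq_len(n_imu) - 1) / config$fs_imu

  edges <- cumsum(c(0, durs))
  annotations <- data.frame(label = names(durs),
                            start_s = edges[-length(edges)],
                            end_s = edges[-1],
                            stringsAsFactors = FALSE)
  mi_row <- annotations[annotations$label == "mi", ]

  nch <- length(EEG_CHANNELS_28)
  if (is.null(shared_mod)) {
    shared_mod <- if (config$trial_kind == "motion") {
      smooth_modulation(n, fs, config$modulation_bw_hz)
    } else numeric(n)
  }
  trial_mod <- smooth_modulation(n, fs, config$modulation_bw_hz)

  # ERD gain: smooth amplitude reduction of 8-30 Hz components during MI
  erd_gain <- 1 - config$erd_depth *
    gate(t, mi_row$start_s, mi_row$end_s, ramp_s = 0.5)

  comps <- config$rhythm_components
  in_coupled <- comps$center >= config$coupled_band[1] &
    comps$center <= config$coupled_band[2]
  in_erd <- comps$center >= 8 & comps$center <= 30

  sm_depth <- if (config$trial_kind == "motion") config$shared_mod_depth else
    sqrt(config$shared_mod_depth^2 + config$trial_mod_depth^2)
  td <- if (config$trial_kind == "motion") config$trial_mod_depth else 0
  # static trials carry the same total modulation variance, but none of it is
  # movement-locked (there is no movement)
  sm_series <- if (config$trial_kind == "motion") shared_mod else trial_mod
  td_series <- if (config$trial_kind == "motion") trial_mod else numeric(n)
  # multiplicative (log-normal) amplitude modulation, the usual model for
  # EEG band-power fluctuation. ERD desynchronizes the movement-locked
  # rhythm modulation during MI: the shared log-depth shrinks with the same
  # gain as the amplitude, while the idiosyncratic per-trial modulation is
  # cognitive-state independent. The exoskeleton-driven envelope feeding
  # the IMU is not attenuated.
  mod_coupled <- exp(sm_depth * erd_gain * sm_series + td * td_series)
  mod_envelope <- exp(sm_depth * sm_series + td * td_series)

  eeg <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    x <- config$noise_sd * pink_noise(n, config$noise_exponent)
    for (j in seq_len(nrow(comps))) {
      carrier <- narrowband_noise(n, fs, comps$center[j], comps$bw[j])
      gain_ch <- stats::rnorm(1, 1, 0.1)
      modj <- rep(1, n)
      if (in_coupled[j]) modj <- mod_coupled
      if (in_erd[j]) modj <- modj * erd_gain
      x <- x + comps$amp[j] * abs(gain_ch) * modj * carrier
    }
    eeg[ch, ] <- x
  }

  # ocular sources and their leak-through
  v_src <- blink_train(t, fs)
  h_src <- saccade_train(t, fs)
  eog <- rbind(VU = v_src, VD = -0.3 * v_src, HL = -0.8 * h_src,
               HR = 0.8 * h_src) + matrix(stats::rnorm(4 * n, 0, 2), 4, n)
  mix <- config$eog_mixing
  if (is.null(mix)) mix <- default_eog_mixing(EEG_CHANNELS_28)
  eeg <- eeg + mix %*% rbind(v_src, h_src)

  # IMU: deterministic DF-PF cycle plus the lag-shifted envelope copy
  move_t0 <- durs[["converge"]]
  move_t1 <- total_s - durs[["return"]]
  env <- mod_envelope^2
  env_z <- if (stats::sd(env) > 0) as.numeric(scale(env)) else env * 0

  imu <- matrix(0, length(IMU_STREAMS), n_imu)
  rownames(imu) <- IMU_STREAMS
  if (config$trial_kind == "motion") {
    g_mv <- gate(t_imu, move_t0, move_t1, ramp_s = 1)
    cycle <- config$movement_amplitude_deg *
      sin(2 * pi * (t_imu - move_t0) / config$movement_period_s) * g_mv
    env_lag <- stats::approx(t + config$coupling_lag_s, env_z, xout = t_imu,
                             rule = 2)$y
    lead <- config$coupling_gain * config$coupling_amp_deg * env_lag * g_mv
    imu["insole_L", ] <- cycle + lead
    imu["insole_R", ] <- cycle + lead
    imu["wheel_L", ] <- 3 * cycle
    imu["wheel_R", ] <- 3 * cycle
  }
  imu <- imu + matrix(stats::rnorm(length(imu), 0, config$sensor_noise_deg),
                      nrow(imu), ncol(imu))
  rownames(imu) <- IMU_STREAMS

  seg_labels <- annotations$label
  names(seg_labels) <- NULL
  rec <- structure(list(eeg = eeg, channel_names = EEG_CHANNELS_28,
                        eog = eog, eog_names = EOG_CHANNELS,
                        imu = imu, imu_names = IMU_STREAMS,
                        fs_eeg = fs, fs_imu = config$fs_imu,
                        annotations = annotations,
                        trial_kind = config$trial_kind,
                        subject_id = "synthetic"),
                   class = "tf_recording")
  gt <- structure(list(injected_lag_samples = round(config$coupling_lag_s * fs),
                       erd_depth = config$erd_depth,
                       component_freqs = comps$center,
                       segment_labels = seg_labels,
                       envelope = env_z,
                       seed = seed),
                  class = "synth_ground_truth")
  list(recording = rec, ground_truth = gt)
}

#' Generate a full synthetic session
#'
#' Alternates motion and static trials (motion first), with per-trial seeds
#' derived from one master seed, and a single movement-locked modulation
#' realization shared by all motion trials.
#'
#' @param n_motion,n_static Trial counts (`n_motion + n_static >= 1`).
#' @param config Base [trial_config()]; `trial_kind` is overridden per trial.
#' @param seed Master seed.
#' @param subject_id Label stored in each recording.
#' @return Object of class `tf_session`: list with `trials` (each a
#'   `list(recording, ground_truth)`), `config`, `seed`, `subject_id`.
#' @export
generate_session <- function(n_motion = 11, n_static = 11,
                             config = trial_config(), seed = 1L,
                             subject_id = "S1") {
  if (n_motion + n_static < 1L) stop_field("generate_session: need at least one trial")
  kinds <- character(0)
  i <- j <- 0L
  while (i < n_motion || j < n_static) {
    if (i < n_motion) { kinds <- c(kinds, "motion"); i <- i + 1L }
    if (j < n_static) { kinds <- c(kinds, "static"); j <- j + 1L }
  }
  seeds <- derive_seeds(seed, length(kinds) + 1L)
  n <- round(sum(config$segment_durations_s) * config$fs_eeg)
  shared <- with_seed(seeds[1], smooth_modulation(n, config$fs_eeg,
                                                  config$modulation_bw_hz))
  trials <- vector("list", length(kinds))
  for (k in seq_along(kinds)) {
    cfg_k <- config
    cfg_k$trial_kind <- kinds[k]
    trials[[k]] <- generate_trial(cfg_k, seed = seeds[k + 1L],
                                  shared_mod = if (kinds[k] == "motion") shared else NULL)
    trials[[k]]$recording$subject_id <- subject_id
  }
  structure(list(trials = trials, trial_kinds = kinds, config = config,
                 seed = seed, subject_id = subject_id,
                 shared_mod = shared),
            class = "tf_session")
}

#' @export
print.tf_session <- function(x, ...) {
  cat(sprintf("<tf_session %s: %d trials (%d motion, %d static)>\n",
              x$subject_id, length(x$trials),
              sum(x$trial_kinds == "motion"), sum(x$trial_kinds == "static")))
  invisible(x)
}
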