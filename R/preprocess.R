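# Causal preprocessing chain: optional notch, H-infinity ocular-artifact
# suppression (per-channel recursive worst-case regression on the EOG
# derivations), 2nd-order Butterworth high-pass, motor-area channel
# selection, running maximum-visual-threshold (MVT) normalization, and IMU
# resampling onto the EEG grid. All filters are single-pass causal: the
# pipeline targets real-time operation, so no zero-phase filtering is used.

#' Software filter specification
#'
#' @param highpass_order Butterworth order (default 2).
#' @param highpass_fc High-pass cutoff, Hz (default 1).
#' @param notch_center Notch centre, Hz (default 50; mains emulation).
#' @param notch_bw Notch -3 dB bandwidth, Hz.
#' @param notch_enabled Apply the notch before the high-pass? Default FALSE
#'   (synthetic data carries no mains interference).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(highpass_order = 2, highpass_fc = 1,
                        notch_center = 50, notch_bw = 2,
                        notch_enabled = FALSE) {
  if (highpass_fc <= 0) stop_field("filter_spec: highpass_fc must be > 0")
  structure(list(highpass_order = highpass_order, highpass_fc = highpass_fc,
                 notch_center = notch_center, notch_bw = notch_bw,
                 notch_enabled = notch_enabled), class = "filter_spec")
}

causal_filter_rows <- function(mat, filt) {
  t(apply(mat, 1, function(x) as.numeric(signal::filter(filt, x))))
}

#' Causal high-pass (and optional notch) filtering of the EEG channels
#'
#' Applies, per channel and in one causal pass, an optional 2nd-order IIR
#' notch followed by the configured Butterworth high-pass (a state-space
#' recursion; no zero-phase filtering).
#'
#' @param recording A `tf_recording` (or channels x samples matrix with `fs`).
#' @param spec A [filter_spec()].
#' @param fs Sampling rate when `recording` is a bare matrix.
#' @return Same type as the input, with filtered EEG.
#' @export
prefilter <- function(recording, spec = filter_spec(), fs = NULL) {
  is_rec <- inherits(recording, "tf_recording")
  mat <- if (is_rec) recording$eeg else recording
  if (is_rec) fs <- recording$fs_eeg
  if (is.null(fs)) stop_field("prefilter: fs required for matrix input")
  if (spec$highpass_fc >= fs / 2) {
    stop_field("prefilter: highpass_fc (%g) must be below Nyquist (%g)",
               spec$highpass_fc, fs / 2)
  }
  if (isTRUE(spec$notch_enabled)) {
    if (spec$notch_center >= fs / 2) stop_field("prefilter: notch_center above Nyquist")
    # standard 2nd-order IIR notch biquad
    w0 <- 2 * pi * spec$notch_center / fs
    alpha <- sin(w0) * sinh(log(2) / 2 * (spec$notch_bw / spec$notch_center) *
                              w0 / sin(w0))
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    mat <- causal_filter_rows(mat, signal::Arma(b / a[1], a / a[1]))
  }
  bf <- signal::butter(spec$highpass_order, spec$highpass_fc / (fs / 2),
                       type = "high")
  mat <- causal_filter_rows(mat, bf)
  if (is_rec) { recording$eeg <- mat; recording } else mat
}

#' H-infinity ocular-artifact suppression
#'
#' Treats each EEG channel as an independent subsystem and recursively
#' regresses it on the reference vector \[vEOG, hEOG, 1\] (vEOG = VU - VD,
#' hEOG = HR - HL; the constant term absorbs drift and bias) with a
#' worst-case (H-infinity) time-varying weight update. Returns the
#' regression residual. Causal, single pass; the weight/gain recursion is
#' shared across channels because it depends only on the reference.
#'
#' @param eeg Channels x samples matrix.
#' @param eog 4 x samples matrix in the order VU, VD, HL, HR.
#' @param params List: `gamma` (> 1, disturbance attenuation bound, default
#'   1.15), `q` (weight random-walk intensity, default 1e-10), `p0` (initial
#'   weight covariance scale, default 0.5), `include_bias` (default TRUE).
#' @return List: `cleaned` (channels x samples), `weights` (3 x channels
#'   final weights), `weight_path` (samples x 3 norm trajectory of the first
#'   channel's weights), `infeasible` (count of clamped steps).
#' @export
hinf_clean <- function(eeg, eog, params = list()) {
  p <- utils::modifyList(list(gamma = 1.15, q = 1e-10, p0 = 0.5,
                              include_bias = TRUE), params)
  if (p$gamma <= 1) stop_field("hinf_clean: gamma must be > 1 (got %s)", p$gamma)
  if (ncol(eeg) != ncol(eog)) stop_field("hinf_clean: eeg and eog sample counts differ")
  if (nrow(eog) != 4L) stop_field("hinf_clean: eog must have 4 rows (VU, VD, HL, HR)")
  n <- ncol(eeg)
  C <- nrow(eeg)
  veog <- eog[1, ] - eog[2, ]
  heog <- eog[4, ] - eog[3, ]
  d <- if (p$include_bias) 3L else 2L
  R <- rbind(veog, heog, if (p$include_bias) rep(1, n))
  W <- matrix(0, d, C)
  P <- diag(p$p0, d)
  g2 <- 1 / p$gamma^2
  qI <- diag(p$q, d)
  cleaned <- matrix(0, C, n)
  wpath <- matrix(0, n, d)
  infeasible <- 0L
  for (t in seq_len(n)) {
    r <- R[, t]
    Pr <- P %*% r
    denom <- 1 - g2 * sum(r * Pr)
    if (denom < 1e-8) { denom <- 1e-8; infeasible <- infeasible + 1L }
    Pt <- P + (g2 / denom) * (Pr %*% t(Pr))
    Ptr <- Pt %*% r
    s <- 1 + sum(r * Ptr)
    K <- Ptr / s
    e <- eeg[, t] - as.numeric(crossprod(W, r))
    cleaned[, t] <- e
    W <- W + K %*% t(e)
    P <- Pt - (Ptr %*% t(Ptr)) / s + qI
    wpath[t, ] <- W[, 1]
  }
  list(cleaned = cleaned, weights = W, weight_path = wpath,
       infeasible = infeasible)
}

#' Select and reorder channels
#'
#' @param recording A `tf_recording`.
#' @param montage Character vector of channel labels; default the fifteen
#'   motor-area electrodes ([motor_montage()]).
#' @return The recording reduced and reordered to the montage.
#' @export
select_channels <- function(recording, montage = motor_montage()) {
  idx <- match(montage, recording$channel_names)
  if (anyNA(idx)) {
    stop_field("unknown channel %s", paste(montage[is.na(idx)], collapse = ", "))
  }
  recording$eeg <- recording$eeg[idx, , drop = FALSE]
  recording$channel_names <- montage
  recording
}

#' Fresh MVT normalization state
#'
#' @param n_channels Channel count.
#' @param n_top How many of the largest absolute amplitudes are averaged per
#'   window (default 6).
#' @return Object of class `mvt_state`.
#' @export
new_mvt_state <- function(n_channels, n_top = 6L) {
  structure(list(n_top = as.integer(n_top),
                 history = matrix(numeric(0), nrow = 0, ncol = n_channels),
                 current_mvt = rep(NA_real_, n_channels)),
            class = "mvt_state")
}

#' MVT normalization of one analysis window
#'
#' Per channel, this window's maximum visual threshold (MVT) is the mean of
#' its `n_top` largest absolute amplitudes; it is appended to the per-channel
#' history and the running MVT is the history mean. The window is divided by
#' the across-channel mean of the running MVTs, so the output is scale-free:
#' scaling all channels by a constant leaves it unchanged. The first window
#' processed bootstraps the state from itself.
#'
#' @param eeg_window Channels x samples matrix (one analysis window).
#' @param state An `mvt_state` (from [new_mvt_state()]).
#' @return List: `normalized` (same shape as input), `state` (updated).
#' @export
mvt_normalize <- function(eeg_window, state) {
  stopifnot(inherits(state, "mvt_state"))
  if (!is.matrix(eeg_window)) eeg_window <- matrix(eeg_window, nrow = 1)
  if (ncol(eeg_window) < state$n_top) {
    stop_field("mvt_normalize: window (%d samples) shorter than n_top (%d)",
               ncol(eeg_window), state$n_top)
  }
  if (ncol(state$history) != nrow(eeg_window)) {
    stop_field("mvt_normalize: state has %d channels, window has %d",
               ncol(state$history), nrow(eeg_window))
  }
  w_mvt <- apply(abs(eeg_window), 1, function(v) {
    mean(sort(v, decreasing = TRUE)[seq_len(state$n_top)])
  })
  state$history <- rbind(state$history, w_mvt)
  state$current_mvt <- colMeans(state$history)
  denom <- mean(state$current_mvt)
  if (denom == 0) denom <- 1  # all-zero history: leave the window untouched
  list(normalized = eeg_window / denom, state = state)
}

#' Resample IMU streams onto a target (EEG) grid
#'
#' Linear interpolation; creates no content above the source Nyquist and
#' clamps the endpoints.
#'
#' @param imu Streams x samples matrix at `fs_in`.
#' @param fs_in Source sampling rate, Hz.
#' @param target_fs Target rate, Hz (default 250).
#' @return Streams x round(n * target_fs / fs_in) matrix.
#' @export
resample_imu <- function(imu, fs_in = 100, target_fs = 250) {
  if (!is.matrix(imu)) imu <- matrix(imu, nrow = 1)
  n <- ncol(imu)
  if (n < 2L) stop_field("resample_imu: need at least two samples")
  n_out <- round(n * target_fs / fs_in)
  t_in <- (seq_len(n) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / target_fs
  out <- t(apply(imu, 1, function(x) {
    stats::approx(t_in, x, xout = t_out, rule = 2)$y
  }))
  rownames(out) <- rownames(imu)
  out
}

#' Full causal preprocessing of one recording
#'
#' Notch (if enabled) and H-infinity ocular suppression, then the high-pass,
#' then montage reduction - the causal chain in acquisition order.
#'
#' @param recording A `tf_recording`.
#' @param spec [filter_spec()].
#' @param hinf_params Parameters for [hinf_clean()].
#' @param montage Channels kept (default [motor_montage()]).
#' @return The preprocessed recording.
#' @export
preprocess_recording <- function(recording, spec = filter_spec(),
                                 hinf_params = list(),
                                 montage = motor_montage()) {
  hc <- hinf_clean(recording$eeg, recording$eog, hinf_params)
  recording$eeg <- hc$cleaned
  recording <- prefilter(recording, spec)
  select_channels(recording, montage)
}
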