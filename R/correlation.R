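# Study 1: lagged cross-correlation between trial-averaged band energy and
# the trial-averaged ankle angle, per electrode / band / mental-task segment,
# with multi-level moving-average smoothing of the energy series.

#' Multi-level smoothing plan
#'
#' Window lengths are fractions of one movement period (in samples), so the
#' smoothing levels stay comparable across frequency bands.
#'
#' @param movement_period_s Seconds per DF-PF cycle.
#' @param fs Sampling rate, Hz.
#' @param fractions Window sizes as fractions of the period (default 0.1,
#'   0.25, 0.5, 1.0).
#' @return Object of class `smoothing_plan` with `windows` (samples,
#'   strictly increasing).
#' @export
smoothing_plan <- function(movement_period_s = 4, fs = 250,
                           fractions = c(0.1, 0.25, 0.5, 1.0)) {
  w <- pmax(1L, as.integer(round(movement_period_s * fs * fractions)))
  if (any(diff(w) <= 0)) stop_field("smoothing_plan: windows must be strictly increasing")
  structure(list(windows = w, fractions = fractions), class = "smoothing_plan")
}

#' Apply every smoothing level to a series
#'
#' Centred moving averages (reflection-padded, same length out), one per
#' level of the plan.
#'
#' @param energy Numeric series.
#' @param plan A [smoothing_plan()].
#' @return List of smoothed series, one per level.
#' @export
smooth_multilevel <- function(energy, plan) {
  if (max(plan$windows) > length(energy)) {
    stop_field("smooth_multilevel: largest window (%d) exceeds series length (%d)",
               max(plan$windows), length(energy))
  }
  lapply(plan$windows, function(w) moving_average(energy, w))
}

#' Pearson-normalized cross-correlation and its best lag
#'
#' Computes the normalized cross-correlation at every lag in
#' `[-max_lag, max_lag]` and returns the lag maximizing `|xcf|` (ties go to
#' the smallest `|lag|`). Sign convention: a negative best lag means the
#' first series (EEG energy) leads the second (IMU angle).
#'
#' @param a,b Equal-length numeric series.
#' @param max_lag Maximum lag in samples (`< length/2`).
#' @return List: `lags`, `xcf`, `best_lag`, `peak_abs_r`, `flag` (`NULL` or
#'   `"zero_variance"`).
#' @export
xcorr_best_lag <- function(a, b, max_lag) {
  n <- length(a)
  if (length(b) != n) stop_field("xcorr_best_lag: series lengths differ")
  if (max_lag >= n / 2) stop_field("xcorr_best_lag: max_lag must be < length/2")
  lags <- seq.int(-max_lag, max_lag)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(lags = lags, xcf = rep(NA_real_, length(lags)),
                best_lag = NA_integer_, peak_abs_r = NA_real_,
                flag = "zero_variance"))
  }
  # xcf(l) = cor(a_t, b_{t-l}) over the overlap, all lags at once:
  # cross-products by FFT, marginal moments by prefix sums
  m <- next_pow2(2L * n)
  A <- stats::fft(c(a, numeric(m - n)))
  B <- stats::fft(c(b, numeric(m - n)))
  cc <- Re(stats::fft(A * Conj(B), inverse = TRUE)) / m
  ca <- cumsum(a); caa <- cumsum(a^2)
  cb <- cumsum(b); cbb <- cumsum(b^2)
  xcf <- vapply(lags, function(l) {
    ml <- n - abs(l)
    if (l >= 0) {
      sa <- ca[n] - (if (l > 0) ca[l] else 0)
      saa <- caa[n] - (if (l > 0) caa[l] else 0)
      sb <- cb[n - l]; sbb <- cbb[n - l]
      sab <- cc[l + 1L]
    } else {
      sa <- ca[n + l]; saa <- caa[n + l]
      sb <- cb[n] - cb[-l]; sbb <- cbb[n] - cbb[-l]
      sab <- cc[m + l + 1L]
    }
    va <- saa - sa^2 / ml
    vb <- sbb - sb^2 / ml
    if (va <= 0 || vb <= 0) return(0)
    (sab - sa * sb / ml) / sqrt(va * vb)
  }, numeric(1))
  best <- order(-abs(xcf), abs(lags))[1]
  list(lags = lags, xcf = xcf, best_lag = lags[best],
       peak_abs_r = abs(xcf[best]), flag = NULL)
}

#' Lagged EEG-energy / ankle-angle correlation study
#'
#' For the motion trials of a session: computes each electrode's band energy
#' per trial, averages energies across trials, averages the (resampled)
#' insole angle traces across trials, then - per electrode, band and
#' mental-task segment - sweeps the smoothing levels, keeps the level with
#' the largest peak `|xcf|`, and aggregates `|r|` across the montage.
#'
#' @param session A `tf_session`.
#' @param transform `"stft"`, `"st"`, `"hht"` or `"ct"`.
#' @param bandset A `bandset` (defaults to all five canonical bands).
#' @param plan A [smoothing_plan()] (default derived from the session's
#'   movement period).
#' @param max_lag_s Lag search range, seconds (default 5; additionally
#'   clamped to a quarter of the segment so the overlap stays large).
#' @param cfg [tf_config()].
#' @param preprocess Run the causal preprocessing chain first (default TRUE).
#' @param montage Electrodes analyzed.
#' @param transition_guard_s Seconds dropped at the start and end of every
#'   mental-task segment before correlating (default 2.5 and 1.5). Task
#'   transitions carry large ERD/ERS energy transients (smeared further by
#'   the transform window and the smoothing); like the transition-epoch
#'   removal in the decoding study, the guard keeps them out of the
#'   segment-wise correlations.
#' @return Object of class `correlation_study`: `table` (one row per
#'   electrode x band x segment), `aggregates` (mean `|r|` per band x
#'   segment), `lag_summary` (per band: mean best lag in samples and the
#'   mean lead time in seconds, energy leading positive).
#' @export
correlate_study <- function(session, transform = "stft",
                            bandset = canonical_bands(), plan = NULL,
                            max_lag_s = 5, cfg = tf_config(),
                            preprocess = TRUE, montage = motor_montage(),
                            transition_guard_s = c(2.5, 1.5)) {
  stopifnot(inherits(session, "tf_session"))
  kinds <- session$trial_kinds
  motion <- which(kinds == "motion")
  if (length(motion) == 0L) stop_field("correlate_study: session has no motion trials")
  if (is.null(plan)) {
    plan <- smoothing_plan(session$config$movement_period_s,
                           session$config$fs_eeg)
  }
  fs <- session$config$fs_eeg
  max_lag <- round(max_lag_s * fs)

  energy_sum <- NULL
  imu_sum <- NULL
  ann <- NULL
  for (i in motion) {
    rec <- session$trials[[i]]$recording
    ann <- rec$annotations
    prep <- if (preprocess) preprocess_recording(rec, montage = montage) else
      select_channels(rec, montage)
    es <- band_energy(prep, transform, bandset, cfg)
    if (is.null(energy_sum)) {
      energy_sum <- lapply(es, function(e) e$values)
    } else {
      for (j in seq_along(es)) energy_sum[[j]] <- energy_sum[[j]] + es[[j]]$values
    }
    insole <- rec$imu[c("insole_L", "insole_R"), , drop = FALSE]
    ang <- colMeans(insole)
    ang250 <- resample_imu(ang, rec$fs_imu, fs)[1, ]
    n <- ncol(energy_sum[[1]])
    ang250 <- ang250[seq_len(min(n, length(ang250)))]
    if (length(ang250) < n) ang250 <- c(ang250, rep(ang250[length(ang250)], n - length(ang250)))
    imu_sum <- if (is.null(imu_sum)) ang250 else imu_sum + ang250
  }
  nt <- length(motion)
  energy_mean <- lapply(energy_sum, function(m) m / nt)
  imu_mean <- imu_sum / nt

  segs <- ann[ann$label %in% c("relax1", "mi", "relax2"), ]
  rows <- list()
  for (j in seq_along(bandset$bands)) {
    bname <- bandset$bands[[j]]$name
    for (si in seq_len(nrow(segs))) {
      i0 <- round((segs$start_s[si] + transition_guard_s[1]) * fs) + 1L
      i1 <- round((segs$end_s[si] - transition_guard_s[2]) * fs)
      imu_seg <- imu_mean[i0:i1]
      seg_len <- i1 - i0 + 1L
      # clamp the search so the overlap never drops below 3/4 of the
      # segment; wider searches inflate boundary-lag artifacts
      ml <- min(max_lag, floor(seg_len / 4))
      # smoothing windows beyond a quarter of the segment leave too few
      # effective samples for a meaningful correlation; skip those levels
      usable <- which(plan$windows <= seg_len / 4)
      if (length(usable) == 0L) usable <- 1L
      for (ch in seq_along(montage)) {
        e_seg <- energy_mean[[j]][ch, i0:i1]
        sm <- smooth_multilevel(e_seg, plan)
        best <- NULL
        for (lev in usable) {
          xc <- xcorr_best_lag(sm[[lev]], imu_seg, ml)
          if (!is.null(xc$flag)) next
          if (is.null(best) || xc$peak_abs_r > best$peak_abs_r) {
            best <- xc
            best$level <- lev
          }
        }
        if (is.null(best)) next
        rows[[length(rows) + 1L]] <- data.frame(
          electrode = montage[ch], band = bname, segment = segs$label[si],
          transform = transform, smoothing_level = best$level,
          peak_abs_r = best$peak_abs_r, best_lag_samples = best$best_lag,
          lead_s = -best$best_lag / fs, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  aggregates <- stats::aggregate(peak_abs_r ~ band + segment, data = tab, FUN = mean)
  names(aggregates)[names(aggregates) == "peak_abs_r"] <- "mean_abs_r"
  lag_summary <- stats::aggregate(cbind(best_lag_samples, lead_s) ~ band,
                                  data = tab, FUN = mean)
  structure(list(table = tab, aggregates = aggregates,
                 lag_summary = lag_summary, transform = transform,
                 n_motion_trials = nt, fs = fs),
            class = "correlation_study")
}
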