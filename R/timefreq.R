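# The four instantaneous-energy-density estimators.
#
# Every estimator maps one signal + one frequency band to a non-negative
# energy-density series aligned to the signal's own sample grid:
#   stft      - tapered overlapping frames, |X|^2 integrated over band bins
#   stockwell - frequency-scaled Gaussian voices, |S|^2 integrated over band
#   hht       - VMD modes -> analytic |z|^2, summed over modes whose mean
#               instantaneous frequency falls in the band
#   chirplet  - Gaussian frames with a quadratic phase (chirp) term; with
#               chirp rate 0 it coincides with a Gaussian-tapered STFT.

#' Time-frequency configuration
#'
#' @param stft List: `window_len_s` (taper length, s), `hop_s` (frame shift,
#'   s), `window_shape` ("hann" or "gaussian"), `gaussian_width_s` (sd of the
#'   Gaussian taper when used), `nfft` (NULL = next power of two).
#' @param stockwell List: `f_min`, `f_max` (Hz, voices outside are never
#'   computed), `df` (target voice spacing, Hz; snapped to the signal's
#'   natural FFT grid).
#' @param chirplet List: `gaussian_width_s` (sd of the analysis Gaussian, s),
#'   `chirp_rate` (Hz/s), `window_len_s`, `hop_s`.
#' @param vmd A [vmd_config()].
#' @return Object of class `tf_config`.
#' @export
tf_config <- function(stft = list(), stockwell = list(), chirplet = list(),
                      vmd = vmd_config()) {
  s <- utils::modifyList(list(window_len_s = 1, hop_s = 0.1,
                              window_shape = "hann", gaussian_width_s = 0.15,
                              nfft = NULL), stft)
  st <- utils::modifyList(list(f_min = 0.5, f_max = 80, df = 0.5), stockwell)
  ct <- utils::modifyList(list(gaussian_width_s = 0.15, chirp_rate = 0,
                               window_len_s = 1, hop_s = 0.1), chirplet)
  if (s$window_len_s <= 0) stop_field("tf_config: stft window_len_s must be > 0")
  if (st$f_min >= st$f_max) stop_field("tf_config: stockwell f_min must be < f_max")
  if (st$df <= 0) stop_field("tf_config: stockwell df must be > 0")
  structure(list(stft = s, stockwell = st, chirplet = ct, vmd = vmd),
            class = "tf_config")
}

as_band <- function(band) {
  if (inherits(band, "band")) return(band)
  if (is.numeric(band) && length(band) == 2L) return(band("band", band[1], band[2]))
  stop_field("expected a band object or c(f_lo, f_hi)")
}

check_band_nyquist <- function(b, fs) {
  if (b$f_hi > fs / 2 + 1e-9 || b$f_lo < 0) {
    stop_field("band %g-%g Hz outside (0, Nyquist = %g Hz)", b$f_lo, b$f_hi, fs / 2)
  }
}

#' Energy-series container
#' @noRd
energy_series <- function(values, band, transform, fs, flag = NULL) {
  if (any(values < -1e-12)) stop_field("internal: negative energy values")
  values[values < 0] <- 0
  structure(list(values = values, band = band, transform = transform,
                 fs = fs, flag = flag), class = "energy_series")
}

#' @export
print.energy_series <- function(x, ...) {
  v <- x$values
  n <- if (is.matrix(v)) ncol(v) else length(v)
  ch <- if (is.matrix(v)) nrow(v) else 1L
  cat(sprintf("<energy_series %s, band %g-%g Hz, %d ch x %d samples @ %g Hz>\n",
              x$transform, x$band$f_lo, x$band$f_hi, ch, n, x$fs))
  invisible(x)
}

# band-bin membership on a frequency grid; the upper edge is inclusive only
# when it reaches Nyquist, so that contiguous bands tile without overlap
band_bins <- function(f, b, fs) {
  if (b$f_hi >= fs / 2 - 1e-9) f >= b$f_lo & f <= b$f_hi else f >= b$f_lo & f < b$f_hi
}

stft_window <- function(L, shape, sigma_samp) {
  if (shape == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  } else if (shape == "gaussian") {
    u <- seq_len(L) - (L + 1) / 2
    exp(-u^2 / (2 * sigma_samp^2))
  } else stop_field("unknown window shape '%s'", shape)
}

# frame a zero-padded signal; frames centred at samples seq(1, n, hop)
frame_signal <- function(x, L, hop) {
  n <- length(x)
  half <- L %/% 2
  xp <- c(numeric(half), x, numeric(L - half))
  centers <- seq(1L, n, by = hop)
  idx <- outer(seq_len(L), centers, function(i, c) i + c - 1L)
  list(frames = matrix(xp[idx], nrow = L), centers_s = (centers - 1))
}

#' STFT band energy
#'
#' Frames the signal with an overlapping taper, computes the one-sided power
#' spectral density of every frame, integrates it over the requested band,
#' and interpolates the frame-centred values back onto the sample grid.
#' Scaling is such that the band energies over a tiling of (0, Nyquist] sum
#' to the signal's mean power (Parseval, up to taper edge effects).
#'
#' @param x Numeric signal.
#' @param band [band()] or `c(f_lo, f_hi)` in Hz.
#' @param cfg [tf_config()].
#' @param fs Sampling rate, Hz.
#' @return An `energy_series` (values on the sample grid, units of x^2).
#' @export
stft_energy <- function(x, band, cfg = tf_config(), fs = 250) {
  b <- as_band(band)
  check_band_nyquist(b, fs)
  e <- stft_band_energies(x, list(b), cfg, fs)[[1]]
  energy_series(e, b, "stft", fs)
}

# shared multi-band STFT path: one framing + FFT pass, one integral per band
stft_band_energies <- function(x, bands, cfg, fs) {
  s <- cfg$stft
  L <- max(2L, round(s$window_len_s * fs))
  if (length(x) <= L) stop_field("signal (%d samples) not longer than one window (%d)", length(x), L)
  hop <- max(1L, round(s$hop_s * fs))
  nfft <- if (is.null(s$nfft)) next_pow2(L) else s$nfft
  w <- stft_window(L, s$window_shape, s$gaussian_width_s * fs)
  fr <- frame_signal(x, L, hop)
  fw <- fr$frames * w
  X <- stats::mvfft(rbind(fw, matrix(0, nfft - L, ncol(fw))))
  nbin <- nfft %/% 2 + 1L
  fbin <- (seq_len(nbin) - 1) * fs / nfft
  P <- Mod(X[seq_len(nbin), , drop = FALSE])^2
  scale <- 2 / (fs * sum(w^2))
  P <- P * scale
  P[1, ] <- P[1, ] / 2
  if (nfft %% 2L == 0L) P[nbin, ] <- P[nbin, ] / 2
  dfbin <- fs / nfft
  lapply(bands, function(b) {
    sel <- band_bins(fbin, b, fs)
    ie_frames <- colSums(P[sel, , drop = FALSE]) * dfbin
    frames_to_samples(ie_frames, fr$centers_s / fs, length(x), fs)
  })
}

#' Stockwell-transform band energy
#'
#' Computes the S-transform on the signal's natural FFT frequency grid
#' (voices restricted to the requested band intersected with the configured
#' `f_min`/`f_max` range), squares it, and integrates across voices. The
#' implementation shifts the signal spectrum and applies the
#' frequency-scaled Gaussian voice window in the Fourier domain (an
#' FFT-accelerated evaluation of the defining integral).
#'
#' @inheritParams stft_energy
#' @return An `energy_series` at the full sample rate.
#' @export
stockwell_energy <- function(x, band, cfg = tf_config(), fs = 250) {
  b <- as_band(band)
  check_band_nyquist(b, fs)
  S <- stockwell_transform(x, fs, max(b$f_lo, cfg$stockwell$f_min),
                           min(b$f_hi, cfg$stockwell$f_max), cfg$stockwell$df)
  if (length(S$freqs) == 0L) {
    return(energy_series(numeric(length(x)), b, "st", fs, flag = "empty_band"))
  }
  ie <- colSums(Mod(S$S)^2) * S$df
  energy_series(ie, b, "st", fs)
}

#' S-transform on the natural FFT voice grid
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param f_lo,f_hi Voice range, Hz (voices at integer multiples of `fs/N`).
#' @param df Target voice spacing, Hz; the actual spacing is the nearest
#'   multiple of the natural grid step `fs/N`.
#' @return List: `S` (voices x time complex matrix), `freqs` (Hz), `df` (Hz).
#' @export
stockwell_transform <- function(x, fs, f_lo, f_hi, df = 0.5) {
  if (df <= 0) stop_field("stockwell: df must be > 0")
  N <- length(x)
  f_nat <- fs / N
  step <- max(1L, round(df / f_nat))
  n_lo <- max(1L, ceiling(f_lo / f_nat - 1e-9))
  n_hi <- floor(f_hi / f_nat + 1e-9)
  voices <- seq(n_lo, n_hi, by = step)
  voices <- voices[voices >= 1 & voices <= N / 2]
  X <- stats::fft(x) / N
  m <- c(0:(ceiling(N / 2) - 1), -(floor(N / 2)):-1)  # DFT index -> signed freq index
  S <- matrix(complex(real = 0), nrow = length(voices), ncol = N)
  for (i in seq_along(voices)) {
    nv <- voices[i]
    G <- exp(-2 * pi^2 * m^2 / nv^2)
    idx <- ((seq_len(N) - 1 + nv) %% N) + 1
    S[i, ] <- stats::fft(X[idx] * G, inverse = TRUE)
  }
  list(S = S, freqs = voices * f_nat, df = step * f_nat)
}

#' Chirplet-transform band energy
#'
#' Gaussian-windowed frames with an extra quadratic phase (chirp) factor
#' exp(-i pi alpha u^2); the frame spectra are evaluated by explicit complex
#' projection onto the band's FFT-bin frequencies, squared, integrated over
#' the band, and interpolated to the sample grid. With `chirp_rate = 0` the
#' operator reduces exactly to a Gaussian-tapered STFT.
#'
#' @inheritParams stft_energy
#' @return An `energy_series`.
#' @export
chirplet_energy <- function(x, band, cfg = tf_config(), fs = 250) {
  b <- as_band(band)
  check_band_nyquist(b, fs)
  ct <- cfg$chirplet
  L <- max(2L, round(ct$window_len_s * fs))
  if (length(x) <= L) stop_field("signal (%d samples) not longer than one window (%d)", length(x), L)
  hop <- max(1L, round(cfg$stft$hop_s * fs))
  if (!is.null(ct$hop_s)) hop <- max(1L, round(ct$hop_s * fs))
  nfft <- next_pow2(L)
  u <- (seq_len(L) - (L + 1) / 2) / fs
  g <- exp(-u^2 / (2 * ct$gaussian_width_s^2))
  nbin <- nfft %/% 2 + 1L
  fbin <- (seq_len(nbin) - 1) * fs / nfft
  sel <- which(band_bins(fbin, b, fs))
  if (length(sel) == 0L) {
    return(energy_series(numeric(length(x)), b, "ct", fs, flag = "empty_band"))
  }
  fr <- frame_signal(x, L, hop)
  # kernel rows: g(u) * exp(-2 pi i f u) * exp(-i pi alpha u^2)
  chirp <- exp(-1i * pi * ct$chirp_rate * u^2)
  E <- exp(-2i * pi * outer(fbin[sel], u)) *
    matrix(g * chirp, nrow = length(sel), ncol = L, byrow = TRUE)
  C <- E %*% fr$frames
  scale <- 2 / (fs * sum(g^2))
  P <- Mod(C)^2 * scale
  if (1L %in% sel) P[which(sel == 1L), ] <- P[which(sel == 1L), ] / 2
  if (nbin %in% sel && nfft %% 2L == 0L) P[which(sel == nbin), ] <- P[which(sel == nbin), ] / 2
  ie_frames <- colSums(P) * fs / nfft
  ie <- frames_to_samples(ie_frames, fr$centers_s / fs, length(x), fs)
  energy_series(ie, b, "ct", fs)
}

#' Hilbert-Huang (VMD + analytic demodulation) band energy
#'
#' Decomposes the signal with [vmd_decompose()], computes each mode's
#' instantaneous energy |z_k(t)|^2, and sums the energies of the modes whose
#' mean instantaneous frequency falls inside the band. If no mode lands in
#' the band the series is all zero and carries `flag = "empty_band"`.
#'
#' @inheritParams stft_energy
#' @param imfs Optional precomputed `imf_set` (skips the decomposition).
#' @return An `energy_series`.
#' @export
hht_band_energy <- function(x, band, cfg = tf_config(), fs = 250, imfs = NULL) {
  b <- as_band(band)
  check_band_nyquist(b, fs)
  if (is.null(imfs)) imfs <- vmd_decompose(x, cfg$vmd, fs = fs)
  hht_integrate(imfs, b, fs)
}

hht_integrate <- function(imfs, b, fs) {
  K <- nrow(imfs$modes)
  n <- ncol(imfs$modes)
  ie <- numeric(n)
  assigned <- 0L
  for (k in seq_len(K)) {
    an <- hilbert_analytic(imfs$modes[k, ], fs = fs)
    mf <- imf_mean_insf(imfs$modes[k, ], fs)
    if (is.na(mf)) next
    inb <- if (b$f_hi >= fs / 2 - 1e-9) mf >= b$f_lo && mf <= b$f_hi else mf >= b$f_lo && mf < b$f_hi
    if (inb) {
      ie <- ie + an$inst_energy
      assigned <- assigned + 1L
    }
  }
  energy_series(ie, b, "hht", fs,
                flag = if (assigned == 0L) "empty_band" else NULL)
}

#' Per-channel, per-band energy for a recording
#'
#' Dispatches one of the four estimators over all EEG channels of a
#' recording and each band of a band set, reusing the per-channel heavy
#' intermediates (frame FFTs, VMD decomposition) across bands.
#'
#' @param recording A recording (see [generate_trial()]), or a plain
#'   channels-x-samples matrix (then `fs` must be given).
#' @param transform One of `"stft"`, `"st"`, `"hht"`, `"ct"`.
#' @param bandset A `bandset` (default [canonical_bands()]).
#' @param cfg [tf_config()].
#' @param fs Sampling rate when `recording` is a bare matrix.
#' @return Named list (one entry per band) of `energy_series` whose `values`
#'   are channels x samples matrices.
#' @export
band_energy <- function(recording, transform = c("stft", "st", "hht", "ct"),
                        bandset = canonical_bands(), cfg = tf_config(),
                        fs = NULL) {
  transform <- match.arg(transform)
  if (is.matrix(recording)) {
    eeg <- recording
    if (is.null(fs)) stop_field("band_energy: fs required for matrix input")
  } else {
    eeg <- recording$eeg
    fs <- recording$fs_eeg
  }
  nch <- nrow(eeg)
  n <- ncol(eeg)
  bands <- bandset$bands
  out <- lapply(bands, function(b) matrix(0, nch, n))
  flags <- vector("list", length(bands))
  for (ch in seq_len(nch)) {
    x <- eeg[ch, ]
    if (transform == "stft") {
      es <- stft_band_energies(x, bands, cfg, fs)
      for (j in seq_along(bands)) out[[j]][ch, ] <- es[[j]]
    } else if (transform == "hht") {
      imfs <- vmd_decompose(x, cfg$vmd, fs = fs)
      for (j in seq_along(bands)) {
        e <- hht_integrate(imfs, bands[[j]], fs)
        out[[j]][ch, ] <- e$values
        if (!is.null(e$flag)) flags[[j]] <- e$flag
      }
    } else {
      fun <- if (transform == "st") stockwell_energy else chirplet_energy
      for (j in seq_along(bands)) {
        e <- fun(x, bands[[j]], cfg, fs)
        out[[j]][ch, ] <- e$values
        if (!is.null(e$flag)) flags[[j]] <- e$flag
      }
    }
  }
  res <- lapply(seq_along(bands), function(j) {
    energy_series(out[[j]], bands[[j]], transform, fs, flag = flags[[j]])
  })
  names(res) <- vapply(bands, function(b) b$name, character(1))
  res
}
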