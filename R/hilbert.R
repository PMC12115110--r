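# Analytic-signal machinery used by the Hilbert-Huang energy estimator and
# by the instantaneous-frequency band derivation.

unwrap_phase <- function(ph) {
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(ph[1], ph[1] + cumsum(d))
}

#' Analytic signal, instantaneous amplitude, frequency and energy
#'
#' Computes the analytic signal z(t) = u(t) + i H\{u\}(t) via the FFT
#' one-sided spectrum method, then the instantaneous amplitude a(t) = |z|,
#' the unwrapped phase, the instantaneous frequency by central differences
#' of the phase, and the instantaneous energy |z(t)|^2.
#'
#' @param mode Numeric vector (one mode / one channel).
#' @param fs Sampling rate, Hz.
#' @return List of class `analytic_signal`: `analytic` (complex), `amplitude`,
#'   `phase` (unwrapped, rad), `inst_freq` (Hz), `inst_energy`.
#' @export
hilbert_analytic <- function(mode, fs = 1) {
  n <- length(mode)
  stopifnot(n >= 1L, fs > 0)
  if (n == 1L || stats::sd(mode) == 0) {
    # degenerate constant input: amplitude = |constant|, zero frequency
    z <- complex(real = mode, imaginary = 0)
    return(structure(list(analytic = z, amplitude = abs(mode),
                          phase = rep(0, n), inst_freq = rep(0, n),
                          inst_energy = mode^2),
                     class = "analytic_signal"))
  }
  X <- stats::fft(mode)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  amp <- Mod(z)
  ph <- unwrap_phase(Arg(z))
  instf <- numeric(n)
  if (n >= 3L) {
    instf[2:(n - 1)] <- (ph[3:n] - ph[1:(n - 2)]) * fs / (4 * pi)
  }
  instf[1] <- (ph[2] - ph[1]) * fs / (2 * pi)
  instf[n] <- (ph[n] - ph[n - 1]) * fs / (2 * pi)
  structure(list(analytic = z, amplitude = amp, phase = ph,
                 inst_freq = instf, inst_energy = amp^2),
            class = "analytic_signal")
}
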