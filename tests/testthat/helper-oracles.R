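# Independent brute-force oracles used by the transform equivalence tests.

# direct O(N^2) evaluation of the S-transform integral: periodized sampled
# Gaussian window in the time domain, explicit complex sum
stockwell_direct <- function(x, fs, voices) {
  N <- length(x)
  j <- 0:(N - 1)
  out <- matrix(complex(real = 0), length(voices), N)
  for (i in seq_along(voices)) {
    nv <- voices[i]
    f <- nv * fs / N
    for (tau in 0:(N - 1)) {
      d <- j - tau
      g <- 0
      for (k in -2:2) g <- g + exp(-((d + k * N) / fs)^2 * f^2 / 2)
      g <- g * f / (sqrt(2 * pi) * fs)
      out[i, tau + 1] <- sum(x * g * exp(-2i * pi * nv * j / N))
    }
  }
  out
}
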