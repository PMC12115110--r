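fs <- 250

test_that("zero signals give identically zero energy for all four estimators", {
  x <- numeric(3 * fs)
  for (f in list(stft_energy, stockwell_energy, chirplet_energy, hht_band_energy)) {
    expect_equal(max(abs(f(x, c(8, 20), fs = fs)$values)), 0)
  }
})

test_that("a pure tone localizes in its band for every transform (>= 10x, >= 20 dB for stft)", {
  t <- (0:(6 * fs - 1)) / fs
  x <- sin(2 * pi * 15 * t)
  mid <- (fs):(5 * fs)
  bands <- list(c(0.5, 2), c(4, 8), c(8, 20), c(25, 40), c(55, 75))
  for (tf in c("stft", "st", "ct", "hht")) {
    e <- suppressWarnings(
      band_energy(matrix(x, 1),  tf,
                  structure(list(bands = lapply(bands, function(b) band("b", b[1], b[2])),
                                 provenance = "canonical"), class = "bandset"),
                  fs = fs))
    means <- vapply(e, function(s) mean(s$values[1, mid]), numeric(1))
    expect_true(all(means[3] >= 10 * means[-3]), label = tf)
  }
  e_in <- stft_energy(sin(2 * pi * 10 * t), c(8, 20), fs = fs)$values[mid]
  e_out <- stft_energy(sin(2 * pi * 10 * t), c(25, 40), fs = fs)$values[mid]
  expect_gt(10 * log10(mean(e_in) / mean(e_out)), 20)
})

test_that("STFT band energies over a Nyquist tiling satisfy Parseval within 2%", {
  set.seed(12)
  x <- rnorm(40 * fs)
  tiles <- list(c(0, 10), c(10, 30), c(30, 60), c(60, 125))
  tot <- Reduce(`+`, lapply(tiles, function(b) stft_energy(x, b, fs = fs)$values))
  expect_lt(abs(mean(tot) / mean(x^2) - 1), 0.02)
  expect_error(stft_energy(x, c(100, 140), fs = fs), "Nyquist")
})

test_that("FFT Stockwell equals the direct integral evaluation to 1e-8", {
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(256)
    S <- stockwell_transform(x, fs, 5, 40, df = 1)
    voices <- round(S$freqs * 256 / fs)
    Sd <- stockwell_direct(x, fs, voices)
    expect_lt(max(Mod(S$S - Sd)) / max(Mod(Sd)), 1e-8)
  }
})

test_that("the Stockwell energy of a tone peaks at the tone frequency", {
  t <- (0:(4 * fs - 1)) / fs
  S <- stockwell_transform(sin(2 * pi * 15 * t), fs, 5, 40, df = 0.5)
  pk <- S$freqs[which.max(rowMeans(Mod(S$S)^2))]
  expect_lte(abs(pk - 15), S$df)
  expect_error(stockwell_transform(t, fs, 5, 40, df = 0), "df")
})

test_that("chirplet with zero chirp rate equals a Gaussian-tapered STFT", {
  set.seed(9)
  cfg <- tf_config(stft = list(window_shape = "gaussian"))
  for (rep in 1:5) {
    x <- rnorm(4 * fs)
    a <- stft_energy(x, c(8, 20), cfg, fs = fs)$values
    b <- chirplet_energy(x, c(8, 20), cfg, fs = fs)$values
    expect_lt(max(abs(a - b)) / max(a), 1e-10)
  }
})

test_that("a matched chirp rate concentrates a linear chirp's energy", {
  t <- (0:(3 * fs - 1)) / fs
  x <- sin(2 * pi * (10 * t + 5 * t^2))      # 10 -> 40 Hz over 3 s
  mid <- (1.25 * fs):(1.75 * fs)             # instantaneous frequency ~ 25 Hz
  e0 <- chirplet_energy(x, c(24, 26), tf_config(chirplet = list(chirp_rate = 0)),
                        fs = fs)$values
  em <- chirplet_energy(x, c(24, 26), tf_config(chirplet = list(chirp_rate = 10)),
                        fs = fs)$values
  expect_gt(mean(em[mid]), mean(e0[mid]))
})

test_that("VMD separates two tones and reaches the single-mode fixed point", {
  t <- (0:(5 * fs - 1)) / fs
  v <- vmd_decompose(sin(2 * pi * 2 * t) + sin(2 * pi * 40 * t),
                     vmd_config(K = 2), fs = fs)
  expect_rel_error(v$center_freqs, c(2, 40), 0.05)
  expect_lt(v$reconstruction_residual, 1e-2)
  v1 <- vmd_decompose(sin(2 * pi * 10 * t), vmd_config(K = 1, tau_update = 0),
                      fs = fs)
  expect_lt(v1$reconstruction_residual, 1e-2)
  expect_rel_error(v1$center_freqs, 10, 0.02)
  z <- vmd_decompose(numeric(1000), vmd_config(K = 3), fs = fs)
  expect_true(all(z$modes == 0))
  expect_error(vmd_decompose(rnorm(16), vmd_config(K = 5)), "too large")
  # deterministic under uniform initialization
  set.seed(1); x <- rnorm(1000)
  expect_identical(vmd_decompose(x, fs = fs)$modes,
                   vmd_decompose(x, fs = fs)$modes)
})

test_that("the analytic signal recovers tone amplitude, frequency and energy identity", {
  t <- (0:(5 * fs - 1)) / fs
  an <- hilbert_analytic(3 * sin(2 * pi * 10 * t), fs)
  mid <- (0.1 * length(t)):(0.9 * length(t))
  expect_lt(max(abs(an$amplitude[mid] / 3 - 1)), 0.02)
  expect_lt(max(abs(an$inst_freq[mid] / 10 - 1)), 0.02)
  expect_identical(an$inst_energy, an$amplitude^2)
  z <- hilbert_analytic(numeric(100), fs)
  expect_equal(max(z$inst_energy), 0)
  cst <- hilbert_analytic(rep(2, 50), fs)
  expect_equal(cst$amplitude, rep(2, 50))
  expect_equal(cst$inst_freq, rep(0, 50))
})

test_that("HHT band energy tracks a component envelope and flags empty bands", {
  set.seed(2)
  n <- 8 * fs
  t <- (0:(n - 1)) / fs
  env <- 1 + 0.5 * sin(2 * pi * 0.3 * t)
  x <- sin(2 * pi * 6 * t) + env * sin(2 * pi * 15 * t)
  e <- suppressWarnings(hht_band_energy(x, c(8, 20), fs = fs))
  mid <- (0.1 * n):(0.9 * n)
  expect_gt(stats::cor(e$values[mid], (env^2)[mid]), 0.9)
  e2 <- suppressWarnings(hht_band_energy(x, c(55, 75), fs = fs))
  expect_equal(max(e2$values), 0)
  expect_equal(e2$flag, "empty_band")
})

test_that("band_energy dispatches per channel and per band consistently", {
  set.seed(4)
  x <- matrix(rnorm(3 * 3 * fs), 3)
  x[3, ] <- x[1, ]  # identical channels in, identical series out
  es <- band_energy(x, "stft", canonical_bands(), fs = fs)
  expect_length(es, 5)
  expect_equal(dim(es[[1]]$values), c(3, 3 * fs))
  expect_equal(es[[2]]$values[3, ], es[[2]]$values[1, ])
  direct <- stft_energy(x[2, ], c(8, 20), fs = fs)$values
  expect_equal(es[["alpha_beta"]]$values[2, ], direct)
  # non-negativity across all transforms on a rough signal
  for (tf in c("stft", "st", "ct", "hht")) {
    e <- suppressWarnings(band_energy(x[1, , drop = FALSE], tf,
                                      decoding_bandset(), fs = fs))
    expect_gte(min(e[[1]]$values), 0)
  }
  expect_equal(5 * 15, length(band_energy(matrix(rnorm(15 * 3 * fs), 15), "stft",
                                          canonical_bands(), fs = fs)) * 15)
})
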