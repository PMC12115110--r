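# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, builder) {
  if (!exists(key, envir = .fx)) assign(key, builder(), envir = .fx)
  get(key, envir = .fx)
}

# one default motion trial + its preprocessed form
fx_trial <- function() fx_cached("trial", function() {
  generate_trial(trial_config(), seed = 11)
})

fx_prep <- function() fx_cached("prep", function() {
  preprocess_recording(fx_trial()$recording)
})

# a tiny mixed session for io / band-derivation tests
fx_session_small <- function() fx_cached("session_small", function() {
  generate_session(n_motion = 2, n_static = 2, seed = 1)
})

# annotations of the default protocol, without generating signals
fx_annotations <- function() {
  durs <- c(converge = 15, relax1 = 15, mi = 28, relax2 = 15, return = 5)
  edges <- cumsum(c(0, durs))
  data.frame(label = names(durs), start_s = edges[-length(edges)],
             end_s = edges[-1], stringsAsFactors = FALSE)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
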