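#' @keywords internal
#' @useDynLib eegkin, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Small shared helpers. Nothing here is exported.

stop_field <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

#' Next power of two >= n
#' @noRd
next_pow2 <- function(n) {
  2L^ceiling(log2(max(1L, n)))
}

#' Derive a stream of child seeds from one master seed.
#'
#' All randomness in the package flows from a single integer seed; children
#' are drawn once from the master-seeded RNG so that trials are independent
#' yet fully reproducible.
#' @noRd
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

#' Run an expression under a local RNG state with a given seed
#' @noRd
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Linear interpolation of frame-centred values onto a sample grid
#' @noRd
frames_to_samples <- function(values, centers_s, n, fs) {
  t_grid <- (seq_len(n) - 1L) / fs
  if (length(values) == 1L) return(rep(values, n))
  stats::approx(centers_s, values, xout = t_grid, rule = 2)$y
}

#' Centred moving average with reflection padding (same length out)
#' @noRd
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  n <- length(x)
  if (w > n) stop_field("moving-average window (%d) exceeds series length (%d)", w, n)
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  xp <- c(rev(x[seq_len(half_l) + 1L]), x, rev(x[n - seq_len(half_r)]))
  cs <- cumsum(c(0, xp))
  (cs[(w + 1L):(length(xp) + 1L)] - cs[seq_len(length(xp) - w + 1L)]) / w
}
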