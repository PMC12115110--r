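# Sliding-window epoching of energy series for motor-imagery decoding.
#
# 2 s windows shifted by 0.5 s (one prediction every 0.5 s), labeled by the
# mental task active over the window's whole extent. Windows straddling a
# task transition never occur because epochs are cut strictly inside the
# relax1 / MI / relax2 segments; converge and return segments are excluded.

#' Build labeled epochs from a per-channel energy series
#'
#' @param energy Channels x samples matrix (one band's energy on the EEG
#'   grid), or an `energy_series`.
#' @param annotations Annotation data frame (`label`, `start_s`, `end_s`).
#' @param window_s Epoch length, seconds (default 2).
#' @param shift_s Epoch shift, seconds (default 0.5).
#' @param fs Sampling rate (taken from the `energy_series` if given).
#' @param mvt Apply running MVT normalization epoch-by-epoch (in time order)?
#'   Default TRUE.
#' @param mvt_state Optional pre-initialized [new_mvt_state()]; default fresh.
#' @return Object of class `epoch_set`: `features` (epochs x channels x time
#'   array), `labels` (0 = relax, 1 = MI), `epoch_start_s`, `window_s`,
#'   `shift_s`, `fs`, `transform`, `trimmed` (FALSE), `mvt_state`.
#' @export
make_epochs <- function(energy, annotations, window_s = 2, shift_s = 0.5,
                        fs = NULL, mvt = TRUE, mvt_state = NULL) {
  transform <- NA_character_
  if (inherits(energy, "energy_series")) {
    fs <- energy$fs
    transform <- energy$transform
    energy <- energy$values
  }
  if (!is.matrix(energy)) energy <- matrix(energy, nrow = 1)
  if (is.null(fs)) stop_field("make_epochs: fs required for matrix input")
  Tn <- round(window_s * fs)
  segs <- annotations[annotations$label %in% c("relax1", "mi", "relax2"), ]
  if (any(segs$end_s - segs$start_s < window_s)) {
    stop_field("make_epochs: window (%g s) longer than a task segment", window_s)
  }
  starts <- numeric(0)
  labels <- integer(0)
  for (i in seq_len(nrow(segs))) {
    s0 <- segs$start_s[i]
    s1 <- segs$end_s[i]
    st <- seq(s0, s1 - window_s + 1e-9, by = shift_s)
    starts <- c(starts, st)
    labels <- c(labels, rep(if (segs$label[i] == "mi") 1L else 0L, length(st)))
  }
  ord <- order(starts)
  starts <- starts[ord]
  labels <- labels[ord]
  n_ep <- length(starts)
  nch <- nrow(energy)
  feats <- array(0, c(n_ep, nch, Tn))
  if (mvt && is.null(mvt_state)) mvt_state <- new_mvt_state(nch)
  for (k in seq_len(n_ep)) {
    i0 <- round(starts[k] * fs) + 1L
    win <- energy[, i0:(i0 + Tn - 1L), drop = FALSE]
    if (mvt) {
      mv <- mvt_normalize(win, mvt_state)
      win <- mv$normalized
      mvt_state <- mv$state
    }
    feats[k, , ] <- win
  }
  structure(list(features = feats, labels = labels, epoch_start_s = starts,
                 window_s = window_s, shift_s = shift_s, fs = fs,
                 transform = transform, trimmed = FALSE,
                 mvt_state = mvt_state),
            class = "epoch_set")
}

#' Trim epoch borders for the frequency-time transforms
#'
#' The Stockwell, Hilbert-Huang and chirplet estimators suffer border
#' effects on 2 s windows, so 0.5 s is removed from each border and only the
#' central second is kept as the feature. The STFT epochs are kept whole.
#' Applying the trim twice is rejected.
#'
#' @param epochs An `epoch_set` with `window_s = 2`.
#' @param transform One of `"stft"`, `"st"`, `"hht"`, `"ct"` (default: the
#'   transform recorded in the epoch set).
#' @return The (possibly) trimmed `epoch_set`; `trimmed` set accordingly.
#' @export
trim_borders <- function(epochs, transform = epochs$transform) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!transform %in% c("stft", "st", "hht", "ct")) {
    stop_field("trim_borders: unknown transform '%s'", transform)
  }
  if (isTRUE(epochs$trimmed)) {
    stop_field("trim_borders: epochs already trimmed (double trim rejected)")
  }
  if (transform == "stft") return(epochs)
  if (abs(epochs$window_s - 2) > 1e-9) {
    stop_field("trim_borders: expects 2 s epochs (got %g s)", epochs$window_s)
  }
  fs <- epochs$fs
  keep <- (round(0.5 * fs) + 1L):(round(1.5 * fs))
  epochs$features <- epochs$features[, , keep, drop = FALSE]
  epochs$trimmed <- TRUE
  epochs$effective_time_s <- 1
  epochs
}
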