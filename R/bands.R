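# Frequency-band definitions and data-driven band derivation.
#
# The analysis standardizes on five bands spanning the classical EEG rhythms,
# anchored by the mean instantaneous frequencies of the five intrinsic mode
# functions (IMFs) that variational mode decomposition extracts from
# motor-area EEG.

#' Construct a frequency band
#'
#' @param name Band label.
#' @param f_lo,f_hi Band edges in Hz, `f_lo < f_hi`.
#' @return An object of class `band` (named list).
#' @export
band <- function(name, f_lo, f_hi) {
  if (!(is.numeric(f_lo) && is.numeric(f_hi) && f_lo < f_hi)) {
    stop_field("invalid band '%s': need f_lo < f_hi (got %s, %s)", name, f_lo, f_hi)
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band")
}

#' The canonical five-band set
#'
#' Delta 0-2 Hz, theta 4-8 Hz, alpha/low-mid-beta 8-20 Hz, high beta
#' 25-40 Hz and gamma 55-75 Hz. These are the bands the whole pipeline
#' reports on; the 8-20 Hz band is the one used for motor-imagery decoding.
#'
#' @return An object of class `bandset`: list with `bands` (ordered list of
#'   [band()]) and `provenance` (`"canonical"` or `"derived"`).
#' @export
canonical_bands <- function() {
  bs <- list(
    band("delta", 0, 2),
    band("theta", 4, 8),
    band("alpha_beta", 8, 20),
    band("high_beta", 25, 40),
    band("gamma", 55, 75)
  )
  structure(list(bands = bs, provenance = "canonical"), class = "bandset")
}

#' @export
print.bandset <- function(x, ...) {
  cat(sprintf("<bandset: %s>\n", x$provenance))
  for (b in x$bands) cat(sprintf("  %-10s %g-%g Hz\n", b$name, b$f_lo, b$f_hi))
  invisible(x)
}

#' Mean instantaneous frequency of one mode
#'
#' Demodulates the mode with the Hilbert transform, differentiates the
#' unwrapped phase, and averages the resulting instantaneous-frequency
#' series. The first and last 5% of samples are excluded from the average
#' to suppress Hilbert edge artifacts.
#'
#' @param mode Numeric vector, one IMF.
#' @param fs Sampling rate in Hz.
#' @param edge_frac Fraction of samples dropped at each edge (default 0.05).
#' @return Mean instantaneous frequency in Hz, or `NA` with attribute
#'   `flag = "degenerate"` for an all-zero mode.
#' @export
imf_mean_insf <- function(mode, fs, edge_frac = 0.05) {
  stopifnot(length(mode) > 4L, fs > 0)
  if (all(mode == 0) || stats::sd(mode) == 0) {
    return(structure(NA_real_, flag = "degenerate"))
  }
  an <- hilbert_analytic(mode, fs = fs)
  n <- length(mode)
  lo <- max(1L, ceiling(n * edge_frac))
  hi <- min(n, floor(n * (1 - edge_frac)))
  mean(an$inst_freq[lo:hi])
}

#' Derive the band set from IMF mean instantaneous frequencies
#'
#' For every trial of each session and each mental-task segment (relax1, MI,
#' relax2), the signal of one electrode (CZ by default, the electrode closest
#' to the foot motor representation) is decomposed into K modes; each mode's
#' mean instantaneous frequency is computed, averaged within session
#' (= subject), then across sessions. The K resulting frequencies are mapped
#' to the nearest canonical band (by band centre).
#'
#' @details
#' Each analysis window's modes are assigned to the nearest canonical band
#' (by band centre) before averaging: a mode that splits in two contributes
#' the mean of its halves, and a window where a mode wanders into a
#' neighbouring rhythm does not contaminate that rhythm's average. The
#' decomposition runs on ocular-cleaned but *not* high-pass-filtered data,
#' so the sub-1 Hz delta component survives; the mode search starts from
#' the classical band centres (see [vmd_config()] `init_centers = "bands"`).
#'
#' @param sessions One session or a list of sessions (one per subject), as
#'   produced by [generate_session()] or [read_session()].
#' @param electrode Channel label to decompose (default "CZ").
#' @param vmd_cfg A [vmd_config()].
#' @param segments Mental-task segments included (default the three tasks).
#' @param trial_kinds Trial kinds included (default both; pass `"motion"`
#'   or `"static"` to derive one model's bands).
#' @return List with `imf_means` (K values, Hz, ordered by band),
#'   `imf_sd` (across-subject sd), `per_subject` (subjects x K matrix),
#'   `nearest_band` (indices into the canonical set), and `bandset` (a
#'   `bandset` with provenance `"derived"`).
#' @export
derive_bandset <- function(sessions, electrode = "CZ",
                           vmd_cfg = vmd_config(init_centers = "bands"),
                           segments = c("relax1", "mi", "relax2"),
                           trial_kinds = c("motion", "static")) {
  if (inherits(sessions, "tf_session")) sessions <- list(sessions)
  canon <- canonical_bands()
  centers <- vapply(canon$bands, function(b) (b$f_lo + b$f_hi) / 2, numeric(1))
  nb <- length(centers)
  per_subject <- NULL
  for (ses in sessions) {
    vals <- NULL
    for (ti in seq_along(ses$trials)) {
      if (!(ses$trial_kinds[ti] %in% trial_kinds)) next
      rec <- ses$trials[[ti]]$recording
      idx <- match(electrode, rec$channel_names)
      if (is.na(idx)) stop_field("electrode '%s' not present in recording", electrode)
      x <- hinf_clean(rec$eeg[idx, , drop = FALSE], rec$eog)$cleaned[1, ]
      fs <- rec$fs_eeg
      for (seg in segments) {
        ann <- rec$annotations[rec$annotations$label == seg, ]
        if (nrow(ann) == 0L) next
        i0 <- floor(ann$start_s[1] * fs) + 1L
        i1 <- floor(ann$end_s[1] * fs)
        imfs <- vmd_decompose(x[i0:i1], vmd_cfg, fs = fs)
        f <- vapply(seq_len(nrow(imfs$modes)), function(k) {
          v <- imf_mean_insf(imfs$modes[k, ], fs)
          if (is.na(v)) imfs$center_freqs[k] else as.numeric(v)
        }, numeric(1))
        row <- rep(NA_real_, nb)
        bucket <- vapply(f, function(fr) which.min(abs(centers - fr)), integer(1))
        for (b in unique(bucket)) row[b] <- mean(f[bucket == b])
        vals <- rbind(vals, row)
      }
    }
    if (is.null(vals)) next
    per_subject <- rbind(per_subject, colMeans(vals, na.rm = TRUE))
  }
  if (is.null(per_subject)) stop_field("derive_bandset: no trials of the requested kind")
  imf_means <- colMeans(per_subject, na.rm = TRUE)
  imf_sd <- if (nrow(per_subject) > 1L) apply(per_subject, 2, stats::sd) else
    rep(NA_real_, ncol(per_subject))
  nearest <- vapply(imf_means, function(f) {
    if (is.na(f)) NA_integer_ else which.min(abs(centers - f))
  }, integer(1))
  bs <- structure(list(bands = canon$bands[nearest[!is.na(nearest)]],
                       provenance = "derived"), class = "bandset")
  list(imf_means = imf_means, imf_sd = imf_sd, per_subject = per_subject,
       nearest_band = nearest, bandset = bs)
}
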