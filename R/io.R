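# On-disk session layout and result-table schemas.
#
# Layout: <path>/trial_01/{eeg.edf, imu.csv, meta.json}, one directory per
# trial. The EDF carries the 28 EEG + 4 EOG channels; the CSV one timestamp
# column (seconds from trial start) plus one column per IMU stream; the JSON
# sidecar the annotations, trial kind, rates and - for synthetic sessions -
# the ground truth. Time is seconds relative to trial start; sample indices
# are 0-based in all documentation.

CORRELATION_SCHEMA <- c("subject", "transform", "band", "segment",
                        "electrode", "peak_abs_r", "best_lag_samples")
DECODING_SCHEMA <- c("subject", "transform", "condition", "held_out_trial",
                     "acc_relax", "acc_mi")

#' Write a session to disk
#'
#' @param session A `tf_session`.
#' @param path Target directory (created).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "tf_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(session$trials)) {
    tdir <- file.path(path, sprintf("trial_%02d", k))
    dir.create(tdir, showWarnings = FALSE)
    rec <- session$trials[[k]]$recording
    gt <- session$trials[[k]]$ground_truth
    write_edf(file.path(tdir, "eeg.edf"),
              rbind(rec$eeg, rec$eog),
              c(rec$channel_names, rec$eog_names), rec$fs_eeg)
    imu_df <- data.frame(t_s = (seq_len(ncol(rec$imu)) - 1) / rec$fs_imu,
                         t(rec$imu))
    names(imu_df) <- c("t_s", rec$imu_names)
    utils::write.csv(imu_df, file.path(tdir, "imu.csv"), row.names = FALSE)
    meta <- list(subject_id = rec$subject_id, trial_kind = rec$trial_kind,
                 fs_eeg = rec$fs_eeg, fs_imu = rec$fs_imu,
                 annotations = rec$annotations,
                 ground_truth = list(
                   injected_lag_samples = gt$injected_lag_samples,
                   erd_depth = gt$erd_depth,
                   component_freqs = gt$component_freqs,
                   seed = gt$seed))
    jsonlite::write_json(meta, file.path(tdir, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  ses_meta <- list(subject_id = session$subject_id, seed = session$seed,
                   trial_kinds = session$trial_kinds,
                   n_trials = length(session$trials))
  jsonlite::write_json(ses_meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session from disk
#'
#' Expects the layout documented in [write_session()]. Sampling rates and
#' channel labels are taken from the file headers; EEG/EOG channels are
#' partitioned by the documented EOG label list (VU, VD, HL, HR).
#'
#' @param path Session directory.
#' @return A `tf_session` (ground truth restored from the sidecars).
#' @export
read_session <- function(path) {
  sj <- file.path(path, "session.json")
  if (!file.exists(sj)) stop_field("read_session: %s is not a session directory (no session.json)", path)
  ses_meta <- jsonlite::read_json(sj, simplifyVector = TRUE)
  tdirs <- file.path(path, sprintf("trial_%02d", seq_len(ses_meta$n_trials)))
  trials <- vector("list", length(tdirs))
  for (k in seq_along(tdirs)) {
    tdir <- tdirs[k]
    for (f in c("eeg.edf", "imu.csv", "meta.json")) {
      if (!file.exists(file.path(tdir, f))) {
        stop_field("read_session: trial_%02d is missing %s", k, f)
      }
    }
    meta <- jsonlite::read_json(file.path(tdir, "meta.json"),
                                simplifyVector = TRUE)
    edf <- read_edf(file.path(tdir, "eeg.edf"))
    is_eog <- edf$labels %in% EOG_CHANNELS
    if (sum(is_eog) != 4L) {
      stop_field("read_session: trial_%02d EDF labels do not contain the EOG montage (VU, VD, HL, HR)", k)
    }
    imu_df <- utils::read.csv(file.path(tdir, "imu.csv"))
    imu <- t(as.matrix(imu_df[, -1, drop = FALSE]))
    rownames(imu) <- names(imu_df)[-1]
    ann <- as.data.frame(meta$annotations)
    rec <- structure(list(eeg = edf$signals[!is_eog, , drop = FALSE],
                          channel_names = edf$labels[!is_eog],
                          eog = edf$signals[is_eog, , drop = FALSE][match(EOG_CHANNELS, edf$labels[is_eog]), ],
                          eog_names = EOG_CHANNELS,
                          imu = imu, imu_names = rownames(imu),
                          fs_eeg = edf$fs, fs_imu = meta$fs_imu,
                          annotations = ann,
                          trial_kind = meta$trial_kind,
                          subject_id = meta$subject_id),
                     class = "tf_recording")
    dur_edf <- ncol(rec$eeg) / rec$fs_eeg
    if (abs(dur_edf - max(ann$end_s)) > 1 / rec$fs_eeg) {
      stop_field("read_session: trial_%02d EDF duration (%g s) inconsistent with annotations (%g s)",
                 k, dur_edf, max(ann$end_s))
    }
    gt <- structure(list(injected_lag_samples = meta$ground_truth$injected_lag_samples,
                         erd_depth = meta$ground_truth$erd_depth,
                         component_freqs = meta$ground_truth$component_freqs,
                         seed = meta$ground_truth$seed),
                    class = "synth_ground_truth")
    trials[[k]] <- list(recording = rec, ground_truth = gt)
  }
  structure(list(trials = trials, trial_kinds = ses_meta$trial_kinds,
                 config = NULL, seed = ses_meta$seed,
                 subject_id = ses_meta$subject_id),
            class = "tf_session")
}

check_schema <- function(tab, schema, what) {
  missing_cols <- setdiff(schema, names(tab))
  if (length(missing_cols) > 0) {
    stop_field("%s table violates schema; missing columns: %s", what,
               paste(missing_cols, collapse = ", "))
  }
  tab[, schema, drop = FALSE]
}

#' Write result tables (fixed column order) plus a JSON manifest
#'
#' @param tables Named list; recognized names are `correlation` (columns
#'   subject, transform, band, segment, electrode, peak_abs_r,
#'   best_lag_samples) and `decoding` (subject, transform, condition,
#'   held_out_trial, acc_relax, acc_mi).
#' @param path Output directory (created).
#' @param run_config List stored in the manifest (e.g. seed, parameters).
#' @return `path`, invisibly.
#' @export
write_results <- function(tables, path, run_config = list()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in names(tables)) {
    schema <- switch(nm, correlation = CORRELATION_SCHEMA,
                     decoding = DECODING_SCHEMA,
                     stop_field("write_results: unknown table '%s'", nm))
    tab <- check_schema(tables[[nm]], schema, nm)
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(tab, f, row.names = FALSE)
    written <- c(written, basename(f))
  }
  jsonlite::write_json(list(files = written, run_config = run_config,
                            written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                       file.path(path, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read result tables written by [write_results()]
#'
#' @param path Results directory.
#' @return Named list of data frames (plus `manifest`).
#' @export
read_results <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  out <- lapply(man$files, function(f) utils::read.csv(file.path(path, f)))
  names(out) <- sub("\\.csv$", "", man$files)
  out$manifest <- man
  out
}
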