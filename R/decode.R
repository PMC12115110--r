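# Study 2: motor-imagery vs relax decoding from 8-20 Hz instantaneous
# energy with leave-one-trial-out cross-validation, separately per
# condition (motion / static) and transform.

#' Band set containing only the 8-20 Hz decoding band
#' @return A `bandset` with the single alpha/beta band.
#' @export
decoding_bandset <- function() {
  structure(list(bands = list(band("alpha_beta", 8, 20)),
                 provenance = "canonical"), class = "bandset")
}

# full feature pipeline for one trial: preprocess -> band energy -> epochs
# (with per-trial MVT state: test-trial data never touches another fold's
# normalizer or classifier) -> border trim
trial_epochs <- function(recording, transform, cfg, preprocess = TRUE,
                         montage = motor_montage()) {
  prep <- if (preprocess) preprocess_recording(recording, montage = montage)
  else select_channels(recording, montage)
  es <- band_energy(prep, transform, decoding_bandset(), cfg)[[1]]
  ep <- make_epochs(es, prep$annotations, mvt = TRUE)
  trim_borders(ep, transform)
}

bind_epochs <- function(eps) {
  feats <- do.call(abind3, lapply(eps, function(e) e$features))
  labels <- unlist(lapply(eps, function(e) e$labels))
  out <- eps[[1]]
  out$features <- feats
  out$labels <- labels
  out$epoch_start_s <- unlist(lapply(eps, function(e) e$epoch_start_s))
  out
}

abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Leave-one-trial-out evaluation of the decoding pipeline
#'
#' For every trial of the chosen condition: train the compact convolutional
#' classifier on the remaining trials' epochs and predict every epoch of the
#' held-out trial. Per-class accuracies are scored per fold; the summary
#' reports their means and standard deviations. The wall time per predicted
#' epoch is recorded so the real-time budget (one prediction per 0.5 s
#' shift) can be asserted.
#'
#' @param session A `tf_session`.
#' @param transform `"stft"`, `"st"`, `"hht"` or `"ct"`.
#' @param condition `"motion"` or `"static"`.
#' @param cfg A [classifier_config()].
#' @param tf_cfg A [tf_config()].
#' @param preprocess Run the causal preprocessing chain (default TRUE).
#' @param epochs Optional precomputed list of per-trial `epoch_set`s (skips
#'   the feature pipeline; used to share features across evaluations).
#' @return Object of class `cv_result`: `folds` (one row per held-out trial:
#'   `acc_relax`, `acc_mi`, `acc_mean`, `pred_s_per_epoch`), `summary`
#'   (means and sds), `subject`, `condition`, `transform`.
#' @export
loocv_evaluate <- function(session, transform = "stft",
                           condition = c("motion", "static"),
                           cfg = classifier_config(), tf_cfg = tf_config(),
                           preprocess = TRUE, epochs = NULL) {
  condition <- match.arg(condition)
  idx <- which(session$trial_kinds == condition)
  if (length(idx) < 2L) stop_field("loocv_evaluate: need >= 2 '%s' trials", condition)
  if (is.null(epochs)) {
    epochs <- lapply(idx, function(i) {
      trial_epochs(session$trials[[i]]$recording, transform, tf_cfg,
                   preprocess = preprocess)
    })
  }
  nf <- length(epochs)
  folds <- vector("list", nf)
  for (k in seq_len(nf)) {
    train <- bind_epochs(epochs[-k])
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + k  # distinct, reproducible init per fold
    model <- train_classifier(train, cfg_k)
    test <- epochs[[k]]
    t0 <- proc.time()[["elapsed"]]
    pred <- predict(model, test)
    dt <- (proc.time()[["elapsed"]] - t0) / length(pred)
    truth <- test$labels
    acc_relax <- mean(pred[truth == 0L] == 0L)
    acc_mi <- mean(pred[truth == 1L] == 1L)
    folds[[k]] <- data.frame(held_out_trial = k, acc_relax = acc_relax,
                             acc_mi = acc_mi,
                             acc_mean = (acc_relax + acc_mi) / 2,
                             pred_s_per_epoch = dt)
  }
  folds <- do.call(rbind, folds)
  summ <- data.frame(
    acc_relax_mean = mean(folds$acc_relax), acc_relax_sd = stats::sd(folds$acc_relax),
    acc_mi_mean = mean(folds$acc_mi), acc_mi_sd = stats::sd(folds$acc_mi),
    acc_mean = mean(folds$acc_mean), acc_sd = stats::sd(folds$acc_mean))
  structure(list(folds = folds, summary = summ,
                 subject = session$subject_id, condition = condition,
                 transform = transform), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s/%s/%s: acc %0.3f +- %0.3f (relax %0.3f, MI %0.3f)>\n",
              x$subject, x$condition, x$transform, x$summary$acc_mean,
              x$summary$acc_sd, x$summary$acc_relax_mean, x$summary$acc_mi_mean))
  invisible(x)
}
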