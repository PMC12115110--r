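# A compact convolutional classifier of the EEGNet family, written directly
# in R (matrix algebra + hand-derived backpropagation).
#
# Architecture, for an input of C channels x T time points of band energy:
#   0. average-pool the time axis to ~pool_to points (energy envelopes are
#      slow; the pooling factor scales with the input length so one
#      architecture serves the 2 s STFT epochs and the trimmed 1 s epochs)
#   1. depthwise spatial filters (F1 learned channel combinations) composed
#      with shared temporal filters of length ~T'/2  (the temporal-then-
#      depthwise-spatial convolution pair of EEGNet collapses to exactly
#      this composition when the temporal filter is shared across channels)
#   2. bias + ELU + average pool (factor 5)
#   3. separable convolution: depthwise temporal (length 3) + pointwise
#      F1 -> F2 mixing, bias + ELU, global average over time
#   4. dropout + dense softmax readout (2 classes)
# Training: Adam, cosine-annealed learning rate, class-weighted
# cross-entropy, checkpoint selection on validation F1.

#' Classifier configuration
#'
#' @param n_classes Number of classes (2).
#' @param dropout_rate Dropout on the feature vector (default 0.35).
#' @param batch_size Minibatch size (default 128).
#' @param max_train_epochs Training epochs (default 60; the cosine schedule
#'   spans this horizon).
#' @param lr_max,lr_min Cosine-annealing learning-rate bounds.
#' @param val_frac Stratified fraction of the training epochs held out for
#'   checkpoint selection by F1 (default 0.2).
#' @param f1_filters,f2_filters Widths of the spatial/temporal and separable
#'   stages.
#' @param pool_to Target time points after input pooling (default 25).
#' @param seed RNG seed: identical (data, cfg, seed) gives an identical
#'   decision function.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(n_classes = 2L, dropout_rate = 0.35,
                              batch_size = 128L, max_train_epochs = 60L,
                              lr_max = 5e-3, lr_min = 1e-4, val_frac = 0.2,
                              f1_filters = 8L, f2_filters = 8L,
                              pool_to = 25L, seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_field("classifier_config: dropout_rate must be in [0, 1)")
  }
  structure(list(n_classes = n_classes, dropout_rate = dropout_rate,
                 batch_size = batch_size, max_train_epochs = max_train_epochs,
                 lr_max = lr_max, lr_min = lr_min, val_frac = val_frac,
                 f1_filters = f1_filters, f2_filters = f2_filters,
                 pool_to = pool_to, seed = seed),
            class = "classifier_config")
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

# average-pool columns of a [T x B] matrix by integer factor p
pool_time <- function(M, p) {
  Tn <- nrow(M)
  T2 <- Tn %/% p
  M <- M[seq_len(T2 * p), , drop = FALSE]
  dim(M) <- c(p, T2, ncol(M))
  out <- colMeans(M)        # [T2 x B]
  matrix(out, nrow = T2)
}

unpool_time <- function(dM, p, Tn) {
  out <- matrix(0, Tn, ncol(dM))
  T2 <- nrow(dM)
  out[seq_len(T2 * p), ] <- apply(dM / p, 2, function(col) rep(col, each = p))
  out
}

# same-padded 1-d convolution along rows of a [T x B] matrix (shift-add)
conv_same <- function(M, w) {
  k <- length(w)
  Tn <- nrow(M)
  half <- (k - 1L) %/% 2L
  P <- rbind(matrix(0, half, ncol(M)), M, matrix(0, k - 1L - half, ncol(M)))
  out <- matrix(0, Tn, ncol(M))
  for (u in seq_len(k)) out <- out + w[u] * P[u:(u + Tn - 1L), , drop = FALSE]
  out
}

conv_same_grad_w <- function(M, dY, k) {
  Tn <- nrow(M)
  half <- (k - 1L) %/% 2L
  P <- rbind(matrix(0, half, ncol(M)), M, matrix(0, k - 1L - half, ncol(M)))
  vapply(seq_len(k), function(u) sum(P[u:(u + Tn - 1L), ] * dY), numeric(1))
}

conv_same_grad_x <- function(dY, w) {
  # transpose of conv_same: correlate with the reversed kernel, mirrored pad
  k <- length(w)
  Tn <- nrow(dY)
  half <- (k - 1L) %/% 2L
  P <- rbind(matrix(0, k - 1L - half, ncol(dY)), dY, matrix(0, half, ncol(dY)))
  out <- matrix(0, Tn, ncol(dY))
  for (u in seq_len(k)) {
    out <- out + w[k + 1L - u] * P[u:(u + Tn - 1L), , drop = FALSE]
  }
  out
}

init_eegnet <- function(C, T_in, cfg) {
  pool_in <- max(1L, round(T_in / cfg$pool_to))
  Tp <- T_in %/% pool_in
  k1 <- max(3L, 2L * (Tp %/% 4L) + 1L)   # odd, ~half the pooled length
  F1 <- cfg$f1_filters
  F2 <- cfg$f2_filters
  p1 <- 5L
  T2 <- Tp %/% p1
  k3 <- 3L
  gl <- function(n_in, n_out, ...) {
    matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / (n_in + n_out))), ...)
  }
  list(C = C, T_in = T_in, pool_in = pool_in, Tp = Tp, k1 = k1, p1 = p1,
       T2 = T2, k3 = k3, F1 = F1, F2 = F2,
       ws = gl(C, F1, nrow = F1, ncol = C),
       w1 = gl(k1, F1, nrow = F1, ncol = k1),
       b1 = numeric(F1),
       wd = gl(k3, F1, nrow = F1, ncol = k3),
       wp = gl(F1, F2, nrow = F2, ncol = F1),
       b3 = numeric(F2),
       Wo = gl(F2, cfg$n_classes, nrow = cfg$n_classes, ncol = F2),
       bo = numeric(cfg$n_classes))
}

# forward pass; X is [B, C, T_in]; returns cache when training
eegnet_forward <- function(par, X, dropout_mask = NULL, keep_cache = FALSE) {
  B <- dim(X)[1]
  C <- par$C
  # input average-pooled along time, laid out as [C, Tp, B]
  if (par$pool_in > 1L) {
    Tp <- par$Tp
    A <- X[, , seq_len(Tp * par$pool_in), drop = FALSE]
    dim(A) <- c(B, C, par$pool_in, Tp)
    Xp <- aperm(colMeans(aperm(A, c(3, 1, 2, 4))), c(2, 3, 1))
  } else {
    Xp <- aperm(X, c(2, 3, 1))
    Tp <- dim(Xp)[2]
  }
  # spatial mix: XS[f, t, b]
  Xmat <- matrix(Xp, nrow = C)                 # C x (Tp*B)
  XS <- par$ws %*% Xmat                        # F1 x (Tp*B)
  A1 <- vector("list", par$F1)                 # post-ELU pooled, [T2 x B]
  Z1 <- vector("list", par$F1)                 # pre-activation, [Tp x B]
  D <- vector("list", par$F1)
  Zs <- matrix(0, par$F2, B)
  XSl <- vector("list", par$F1)
  for (f in seq_len(par$F1)) {
    Mf <- matrix(XS[f, ], nrow = Tp)           # Tp x B
    XSl[[f]] <- Mf
    Z <- conv_same(Mf, par$w1[f, ]) + par$b1[f]
    Z1[[f]] <- Z
    A <- pool_time(elu(Z), par$p1)             # T2 x B
    A1[[f]] <- A
    D[[f]] <- conv_same(A, par$wd[f, ])        # T2 x B
  }
  Z3 <- vector("list", par$F2)
  feat <- matrix(0, par$F2, B)
  for (g in seq_len(par$F2)) {
    S <- matrix(par$b3[g], par$T2, B)
    for (f in seq_len(par$F1)) S <- S + par$wp[g, f] * D[[f]]
    Z3[[g]] <- S
    feat[g, ] <- colMeans(elu(S))
  }
  if (!is.null(dropout_mask)) feat <- feat * dropout_mask
  logits <- par$Wo %*% feat + par$bo
  out <- list(logits = logits, feat = feat)
  if (keep_cache) {
    out$cache <- list(Xp = Xp, XSl = XSl, Z1 = Z1, A1 = A1, D = D, Z3 = Z3,
                      Tp = Tp, B = B)
  }
  out
}

softmax_cols <- function(L) {
  L <- sweep(L, 2, apply(L, 2, max))
  E <- exp(L)
  sweep(E, 2, colSums(E), "/")
}

eegnet_backward <- function(par, fwd, y, w_sample, dropout_mask) {
  cache <- fwd$cache
  B <- cache$B
  P <- softmax_cols(fwd$logits)
  Y <- matrix(0, nrow(P), B)
  Y[cbind(y + 1L, seq_len(B))] <- 1
  dL <- sweep(P - Y, 2, w_sample, "*") / sum(w_sample)
  g <- list()
  g$Wo <- dL %*% t(fwd$feat)
  g$bo <- rowSums(dL)
  dfeat <- t(par$Wo) %*% dL
  if (!is.null(dropout_mask)) dfeat <- dfeat * dropout_mask
  dD <- rep(list(matrix(0, par$T2, B)), par$F1)
  g$wp <- matrix(0, par$F2, par$F1)
  g$b3 <- numeric(par$F2)
  for (gg in seq_len(par$F2)) {
    dS <- matrix(dfeat[gg, ] / par$T2, par$T2, B, byrow = TRUE) *
      elu_grad(cache$Z3[[gg]])
    g$b3[gg] <- sum(dS)
    for (f in seq_len(par$F1)) {
      g$wp[gg, f] <- sum(dS * cache$D[[f]])
      dD[[f]] <- dD[[f]] + par$wp[gg, f] * dS
    }
  }
  g$wd <- matrix(0, par$F1, par$k3)
  g$w1 <- matrix(0, par$F1, par$k1)
  g$b1 <- numeric(par$F1)
  dXS <- matrix(0, par$F1, cache$Tp * B)
  for (f in seq_len(par$F1)) {
    g$wd[f, ] <- conv_same_grad_w(cache$A1[[f]], dD[[f]], par$k3)
    dA <- conv_same_grad_x(dD[[f]], par$wd[f, ])
    dZ <- unpool_time(dA, par$p1, cache$Tp) * elu_grad(cache$Z1[[f]])
    g$b1[f] <- sum(dZ)
    g$w1[f, ] <- conv_same_grad_w(cache$XSl[[f]], dZ, par$k1)
    dXS[f, ] <- as.numeric(conv_same_grad_x(dZ, par$w1[f, ]))
  }
  Xmat <- matrix(cache$Xp, nrow = par$C)
  g$ws <- dXS %*% t(Xmat)
  g
}

adam_step <- function(par, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(par = par, state = state)
}

f1_score <- function(truth, pred, positive = 1L) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Train the compact convolutional motor-imagery classifier
#'
#' @param train An `epoch_set` (both classes must be present).
#' @param cfg A [classifier_config()].
#' @return Object of class `eegnet_model` (weights + config), usable with
#'   [predict.eegnet_model()].
#' @export
train_classifier <- function(train, cfg = classifier_config()) {
  stopifnot(inherits(train, "epoch_set"))
  y <- train$labels
  if (length(unique(y)) < 2L) {
    stop_field("train_classifier: training set contains a single class")
  }
  X <- train$features
  n <- dim(X)[1]
  C <- dim(X)[2]
  T_in <- dim(X)[3]
  with_seed(cfg$seed, {
    par <- init_eegnet(C, T_in, cfg)
    # per-feature standardization over the training set (stored in model)
    mu <- apply(X, c(2, 3), mean)
    sg <- apply(X, c(2, 3), stats::sd)
    sg[sg == 0] <- 1
    Xs <- sweep(sweep(X, c(2, 3), mu), c(2, 3), sg, "/")
    # stratified validation split for checkpoint selection
    idx0 <- which(y == 0L); idx1 <- which(y == 1L)
    v0 <- sample(idx0, max(1L, round(length(idx0) * cfg$val_frac)))
    v1 <- sample(idx1, max(1L, round(length(idx1) * cfg$val_frac)))
    val <- sort(c(v0, v1))
    tr <- setdiff(seq_len(n), val)
    cw <- length(tr) / (cfg$n_classes * tabulate(y[tr] + 1L, cfg$n_classes))
    state <- list(t = 0L,
                  m = lapply(par[c("ws", "w1", "b1", "wd", "wp", "b3", "Wo", "bo")],
                             function(x) x * 0),
                  v = lapply(par[c("ws", "w1", "b1", "wd", "wp", "b3", "Wo", "bo")],
                             function(x) x * 0))
    best <- list(f1 = -1, par = par)
    Xval <- Xs[val, , , drop = FALSE]
    for (ep in seq_len(cfg$max_train_epochs)) {
      lr <- cfg$lr_min + 0.5 * (cfg$lr_max - cfg$lr_min) *
        (1 + cos(pi * (ep - 1) / cfg$max_train_epochs))
      ord <- sample(tr)
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        Xb <- Xs[bi, , , drop = FALSE]
        yb <- y[bi]
        mask <- if (cfg$dropout_rate > 0) {
          matrix(stats::rbinom(par$F2 * length(bi), 1, 1 - cfg$dropout_rate),
                 par$F2, length(bi)) / (1 - cfg$dropout_rate)
        } else NULL
        fwd <- eegnet_forward(par, Xb, dropout_mask = mask, keep_cache = TRUE)
        gr <- eegnet_backward(par, fwd, yb, cw[yb + 1L], mask)
        st <- adam_step(par, gr, state, lr)
        par <- st$par
        state <- st$state
      }
      pv <- apply(eegnet_forward(par, Xval)$logits, 2, which.max) - 1L
      f1 <- f1_score(y[val], pv)
      if (f1 > best$f1) best <- list(f1 = f1, par = par)
    }
    structure(list(par = best$par, val_f1 = best$f1, mu = mu, sg = sg,
                   cfg = cfg), class = "eegnet_model")
  })
}

#' Predict classes for an epoch set
#'
#' @param object An `eegnet_model`.
#' @param newdata An `epoch_set` (same channels / time length as training).
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Integer class labels (0 = relax, 1 = MI) or a 2 x epochs
#'   probability matrix.
#' @export
predict.eegnet_model <- function(object, newdata, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "epoch_set")) newdata$features else newdata
  Xs <- sweep(sweep(X, c(2, 3), object$mu), c(2, 3), object$sg, "/")
  fwd <- eegnet_forward(object$par, Xs)
  if (type == "prob") return(softmax_cols(fwd$logits))
  apply(fwd$logits, 2, which.max) - 1L
}
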