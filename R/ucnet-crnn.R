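#' Semi-supervised weighted classification loss
#'
#' Sum of per-instance cross-entropy losses in which every labeled instance
#' has weight 1 and every pseudo-labeled instance weight `alpha`:
#' `sum_labeled l(f(x), y) + sum_pseudo alpha * l(f(x), y)`. With all
#' weights 1 this reduces exactly to the unweighted supervised sum; with
#' pseudo weights 0 it reduces to the labeled-only sum.
#'
#' @param predictions Matrix of class probabilities (`N x 2`, columns
#'   `wild`, `mutant`) or a numeric vector of probabilities assigned to the
#'   true class.
#' @param labels Character vector (`mutant`/`wild`) or 0/1 vector (1 =
#'   mutant); ignored when `predictions` is already the true-class
#'   probability vector.
#' @param weights Per-instance weights in `[0, 1]` (outside values are
#'   rejected).
#' @return The scalar weighted loss.
#' @export
weighted_loss <- function(predictions, labels = NULL, weights) {
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  if (is.matrix(predictions)) {
    if (is.null(labels)) stop("labels required with a probability matrix")
    y <- label_index(labels)
    p_true <- predictions[cbind(seq_len(nrow(predictions)), y)]
  } else {
    p_true <- predictions
  }
  if (length(p_true) != length(weights)) stop("lengths of predictions and weights differ")
  sum(weights * (-log(pmax(p_true, 1e-12))))
}

# labels -> column index (1 = wild, 2 = mutant)
label_index <- function(labels) {
  if (is.numeric(labels)) return(ifelse(labels > 0, 2L, 1L))
  l <- as.character(labels)
  if (!all(l %in% c("mutant", "wild"))) stop("labels must be 'mutant' or 'wild'")
  ifelse(l == "mutant", 2L, 1L)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Build the CRNN sequence classifier
#'
#' A 1-D convolution (kernel 3, same padding, LeakyReLU) over the per-slice
#' feature sequence, followed by an LSTM whose final hidden state passes
#' through dropout into a 2-class softmax head.
#'
#' @param cfg A [ucnet_config()].
#' @param feature_dim Per-slice feature dimension (defaults to the
#'   extractor bottleneck width).
#' @return Object of class `crnn_classifier` with untrained weights.
#' @export
build_crnn <- function(cfg, feature_dim = cfg$bottleneck_channels) {
  stopifnot(inherits(cfg, "ucnet_config"))
  K <- cfg$conv1d_filters; M <- cfg$lstm_hidden; F_ <- feature_dim
  with_seed(cfg$seed + 2L, {
    p <- list(
      c1_w = matrix(stats::rnorm(3 * F_ * K, sd = sqrt(2 / (3 * F_))), 3 * F_, K),
      c1_b = numeric(K),
      lstm_wx = matrix(stats::rnorm(K * 4 * M, sd = sqrt(1 / K)), K, 4 * M),
      lstm_wh = matrix(stats::rnorm(M * 4 * M, sd = sqrt(1 / M)), M, 4 * M),
      lstm_b = c(numeric(M), rep(1, M), numeric(2 * M)), # forget bias 1
      fc_w = matrix(stats::rnorm(M * 2, sd = sqrt(1 / M)), M, 2),
      fc_b = numeric(2)
    )
    structure(list(params = p, cfg = cfg, feature_dim = F_, trained = FALSE),
              class = "crnn_classifier")
  })
}

# sequences: array (S, F, N); returns forward pass with caches
crnn_forward <- function(model, X, dropout_mask = NULL) {
  p <- model$params; cfg <- model$cfg
  S <- dim(X)[1]; F_ <- dim(X)[2]; N <- dim(X)[3]
  M <- cfg$lstm_hidden
  slope <- cfg$leaky_slope
  # conv1d over the slice axis
  step_mat <- function(t) {
    if (t < 1 || t > S) matrix(0, N, F_) else {
      m <- X[t, , , drop = FALSE]
      t(matrix(m, F_, N))
    }
  }
  conv_in <- vector("list", S); conv_z <- vector("list", S)
  H <- vector("list", S)
  for (t in seq_len(S)) {
    x3 <- cbind(step_mat(t - 1), step_mat(t), step_mat(t + 1)) # N x 3F
    z <- sweep(x3 %*% p$c1_w, 2, p$c1_b, `+`)
    conv_in[[t]] <- x3; conv_z[[t]] <- z
    H[[t]] <- lrelu_fwd(z, slope)
  }
  # LSTM
  h <- matrix(0, N, M); c_ <- matrix(0, N, M)
  lstm_cache <- vector("list", S)
  for (t in seq_len(S)) {
    gates <- H[[t]] %*% p$lstm_wx + h %*% p$lstm_wh +
      matrix(p$lstm_b, N, 4 * M, byrow = TRUE)
    i <- sigmoid(gates[, 1:M, drop = FALSE])
    f <- sigmoid(gates[, M + 1:M, drop = FALSE])
    o <- sigmoid(gates[, 2 * M + 1:M, drop = FALSE])
    g <- tanh(gates[, 3 * M + 1:M, drop = FALSE])
    c_new <- f * c_ + i * g
    h_new <- o * tanh(c_new)
    lstm_cache[[t]] <- list(i = i, f = f, o = o, g = g, c_prev = c_,
                            h_prev = h, c_new = c_new)
    c_ <- c_new; h <- h_new
  }
  h_drop <- if (is.null(dropout_mask)) h else h * dropout_mask
  logits <- sweep(h_drop %*% p$fc_w, 2, p$fc_b, `+`)
  ex <- exp(logits - apply(logits, 1, max))
  probs <- ex / rowSums(ex)
  list(probs = probs, logits = logits, h = h, h_drop = h_drop,
       conv_in = conv_in, conv_z = conv_z, H = H, lstm_cache = lstm_cache,
       dropout_mask = dropout_mask, S = S, N = N)
}

crnn_backward <- function(model, fwd, dlogits) {
  p <- model$params; cfg <- model$cfg
  M <- cfg$lstm_hidden; S <- fwd$S; N <- fwd$N
  slope <- cfg$leaky_slope
  grads <- list(
    fc_w = t(fwd$h_drop) %*% dlogits,
    fc_b = colSums(dlogits)
  )
  dh <- dlogits %*% t(p$fc_w)
  if (!is.null(fwd$dropout_mask)) dh <- dh * fwd$dropout_mask
  dWx <- p$lstm_wx * 0; dWh <- p$lstm_wh * 0; db <- p$lstm_b * 0
  dH <- vector("list", S)
  dc <- matrix(0, N, M)
  for (t in rev(seq_len(S))) {
    ca <- fwd$lstm_cache[[t]]
    tanh_c <- tanh(ca$c_new)
    do_ <- dh * tanh_c
    dc <- dc + dh * ca$o * (1 - tanh_c^2)
    di <- dc * ca$g
    df <- dc * ca$c_prev
    dg <- dc * ca$i
    dgates <- cbind(
      di * ca$i * (1 - ca$i),
      df * ca$f * (1 - ca$f),
      do_ * ca$o * (1 - ca$o),
      dg * (1 - ca$g^2)
    )
    dWx <- dWx + t(fwd$H[[t]]) %*% dgates
    dWh <- dWh + t(ca$h_prev) %*% dgates
    db <- db + colSums(dgates)
    dH[[t]] <- dgates %*% t(p$lstm_wx)
    dh <- dgates %*% t(p$lstm_wh)
    dc <- dc * ca$f
  }
  grads$lstm_wx <- dWx; grads$lstm_wh <- dWh; grads$lstm_b <- db
  dc1w <- p$c1_w * 0; dc1b <- p$c1_b * 0
  for (t in seq_len(S)) {
    dz <- lrelu_bwd(fwd$conv_z[[t]], dH[[t]], slope)
    dc1w <- dc1w + t(fwd$conv_in[[t]]) %*% dz
    dc1b <- dc1b + colSums(dz)
  }
  grads$c1_w <- dc1w; grads$c1_b <- dc1b
  grads
}

# z-score feature dimensions with statistics fitted on the training set
# (stored in the model so inference applies the identical transform)
standardize_sequences <- function(model, X) {
  if (is.null(model$input_mean)) return(X)
  F_ <- dim(X)[2]
  for (k in seq_len(F_)) {
    X[, k, ] <- (X[, k, ] - model$input_mean[k]) / model$input_sd[k]
  }
  X
}

# list of (S x F) matrices -> (S, F, N) array
stack_sequences <- function(seqs) {
  if (is.array(seqs) && length(dim(seqs)) == 3) return(seqs)
  if (is.matrix(seqs)) seqs <- list(seqs)
  d <- dim(seqs[[1]])
  if (any(vapply(seqs, function(s) !identical(dim(s), d), TRUE))) {
    stop("sequences must share length and feature dimension")
  }
  array(unlist(seqs, use.names = FALSE), dim = c(d[1], d[2], length(seqs)))
}

#' Train the CRNN classifier on weighted sequences
#'
#' Minimizes the semi-supervised weighted cross-entropy (see
#' [weighted_loss()]) with Adam. Labeled instances carry weight 1 and
#' pseudo-labeled instances the supplied `alpha` weight vector entry.
#' Dropout (rate `cfg$dropout`) is applied to the final LSTM state during
#' training only. Input feature dimensions are z-scored with statistics
#' fitted on the training sequences; the same transform is applied at
#' inference.
#'
#' @param model A [build_crnn()] classifier.
#' @param sequences List of per-patient `slices x feature_dim` matrices (or
#'   a 3-D array `slices x feature_dim x patients`).
#' @param labels Class labels (`mutant`/`wild`), one per patient; a
#'   single-class training set is rejected.
#' @param weights Per-patient loss weights in `[0, 1]` (default all 1).
#' @param epochs,lr,batch_size Optional overrides of the config.
#' @param validation Optional list with `sequences` and `labels` scored
#'   after each epoch.
#' @param verbose Print per-epoch metrics.
#' @return The trained model with `$history` (epoch, loss, accuracy and,
#'   when validation data are given, val_loss, val_accuracy).
#' @export
train_classifier <- function(model, sequences, labels, weights = NULL,
                             epochs = NULL, lr = NULL, batch_size = NULL,
                             validation = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "crnn_classifier"))
  cfg <- model$cfg
  X <- stack_sequences(sequences)
  y <- label_index(labels)
  if (length(unique(y)) < 2) stop("training set contains a single class")
  N <- dim(X)[3]
  weights <- weights %||% rep(1, N)
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  epochs <- epochs %||% cfg$epochs_classifier
  lr <- lr %||% cfg$lr_classifier
  batch_size <- batch_size %||% cfg$batch_classifier
  # fit the input standardization on the training sequences
  model$input_mean <- apply(X, 2, mean)
  sds <- apply(X, 2, stats::sd)
  model$input_sd <- ifelse(sds > 0, sds, 1)
  X <- standardize_sequences(model, X)
  state <- adam_init(model$params)
  hist <- list()
  with_seed(cfg$seed + 3L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(N)
      ep_loss <- 0; correct <- 0
      for (start in seq(1, N, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, N)]
        Xb <- X[, , idx, drop = FALSE]
        yb <- y[idx]; wb <- weights[idx]
        nb <- length(idx)
        mask <- if (cfg$dropout > 0) {
          matrix(stats::rbinom(nb * cfg$lstm_hidden, 1, 1 - cfg$dropout) /
                   (1 - cfg$dropout), nb, cfg$lstm_hidden)
        } else NULL
        fwd <- crnn_forward(model, Xb, dropout_mask = mask)
        p_true <- fwd$probs[cbind(seq_len(nb), yb)]
        loss <- sum(wb * (-log(pmax(p_true, 1e-12)))) / nb
        if (!is.finite(loss)) stop("non-finite classifier loss at epoch ", ep)
        onehot <- matrix(0, nb, 2); onehot[cbind(seq_len(nb), yb)] <- 1
        dlogits <- (fwd$probs - onehot) * wb / nb
        grads <- crnn_backward(model, fwd, dlogits)
        upd <- adam_step(model$params, grads, state, lr)
        model$params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss * nb
        correct <- correct + sum(max.col(fwd$probs, ties.method = "first") == yb)
      }
      row <- data.frame(epoch = ep, loss = ep_loss / N, accuracy = correct / N)
      if (!is.null(validation)) {
        vm <- classifier_metrics(model, validation$sequences, validation$labels)
        row$val_loss <- vm$loss; row$val_accuracy <- vm$accuracy
      }
      hist[[ep]] <- row
      if (verbose) message(sprintf("epoch %d: loss %.4f acc %.3f", ep,
                                   row$loss, row$accuracy))
    }
  })
  model$trained <- TRUE
  model$history <- do.call(rbind, hist)
  model
}

#' Deterministic loss and accuracy of a classifier on a labeled set
#'
#' Scores a trained CRNN with dropout disabled.
#'
#' @param model A trained `crnn_classifier`.
#' @param sequences Feature sequences (see [train_classifier()]).
#' @param labels True labels.
#' @param weights Optional per-instance loss weights.
#' @return List with `loss`, `accuracy` and the probability matrix `probs`.
#' @export
classifier_metrics <- function(model, sequences, labels, weights = NULL) {
  X <- standardize_sequences(model, stack_sequences(sequences))
  y <- label_index(labels)
  N <- dim(X)[3]
  weights <- weights %||% rep(1, N)
  fwd <- crnn_forward(model, X, dropout_mask = NULL)
  p_true <- fwd$probs[cbind(seq_len(N), y)]
  list(loss = sum(weights * (-log(pmax(p_true, 1e-12)))) / N,
       accuracy = mean(max.col(fwd$probs, ties.method = "first") == y),
       probs = fwd$probs)
}

#' Predict IDH1 mutation status
#'
#' Deterministic inference (dropout disabled). Accepts a feature-sequence
#' matrix, a list of them, a 3-D array, or a [volume_sequence()] together
#' with a trained extractor.
#'
#' @param object A trained `crnn_classifier`.
#' @param newdata Input patient(s); see description.
#' @param extractor A trained [ucnet_extractor] (required when `newdata`
#'   is a volume).
#' @param ... Unused.
#' @return data.frame with `class`, `prob_mutant`, `prob_wild` per patient.
#' @export
predict.crnn_classifier <- function(object, newdata, extractor = NULL, ...) {
  if (!isTRUE(object$trained)) stop("classifier has not been trained")
  if (inherits(newdata, "volume_sequence")) {
    if (is.null(extractor)) stop("an extractor is required to predict from a volume")
    newdata <- extract_feature_sequence(extractor, newdata)
  }
  X <- standardize_sequences(object, stack_sequences(newdata))
  fwd <- crnn_forward(object, X, dropout_mask = NULL)
  data.frame(
    class = c("wild", "mutant")[max.col(fwd$probs, ties.method = "first")],
    prob_mutant = fwd$probs[, 2],
    prob_wild = fwd$probs[, 1],
    stringsAsFactors = FALSE
  )
}
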