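#' UCNet configuration
#'
#' Hyperparameters of the UCNet pair: the U-Net-style autoencoder feature
#' extractor (dense-block encoder, residual-block decoder, skip
#' connections) and the CRNN sequence classifier. Full-scale defaults are
#' 256 x 256 x 16 volumes with channel plan `c(64, 64, 128, 128)`; the
#' desk-scale preset used by the test suite shrinks the spatial dims and
#' scales the channel plan down so the whole pipeline runs in minutes on
#' one CPU.
#'
#' @param height,width,slices Input volume dimensions. Height and width must
#'   be divisible by 4 (two 2x2 average-pooling stages).
#' @param sequences Character vector of MRI sequences used as input
#'   channels (e.g. `c("T2", "FLAIR")`).
#' @param dense_plan,res_plan Channel plans of the 4 conv layers in each
#'   dense (encoder) and residual (decoder) block.
#' @param first_kernel,last_kernel Kernel sizes of the first and last conv
#'   layer of each block (the two inner layers are 3x3).
#' @param leaky_slope LeakyReLU negative slope.
#' @param bottleneck_channels Channels at the bottleneck; also the per-slice
#'   feature dimension after global average pooling.
#' @param conv1d_filters,lstm_hidden CRNN stage sizes.
#' @param dropout Dropout rate before the CRNN output layer (default 0.5).
#' @param lr_extractor,lr_classifier Adam learning rates (full-scale defaults
#'   1e-5 and 1e-4).
#' @param batch_extractor,batch_classifier Batch sizes (full-scale defaults 4
#'   patients for the extractor; 40 for supervised-only and 30 for
#'   semi-supervised classifier training).
#' @param epochs_extractor,epochs_classifier Training epoch budgets.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param seed Seed for weight initialization, shuffling and dropout.
#' @return Object of class `ucnet_config`.
#' @export
ucnet_config <- function(height = 64, width = 64, slices = 8,
                         sequences = c("T2", "FLAIR"),
                         dense_plan = c(16, 16, 32, 32),
                         res_plan = dense_plan,
                         first_kernel = 5, last_kernel = 1,
                         leaky_slope = 0.1,
                         bottleneck_channels = dense_plan[4],
                         conv1d_filters = 16, lstm_hidden = 16,
                         dropout = 0.5,
                         lr_extractor = 1e-5, lr_classifier = 1e-4,
                         batch_extractor = 4, batch_classifier = 40,
                         epochs_extractor = 30, epochs_classifier = 50,
                         patience = 8, seed = 1L) {
  if (height %% 4 != 0 || width %% 4 != 0) {
    stop(sprintf(
      "height and width must be divisible by 4; pad to %d x %d",
      4 * ceiling(height / 4), 4 * ceiling(width / 4)
    ))
  }
  stopifnot(length(dense_plan) == 4, length(res_plan) == 4)
  structure(
    list(height = as.integer(height), width = as.integer(width),
         slices = as.integer(slices), sequences = sequences,
         dense_plan = as.integer(dense_plan), res_plan = as.integer(res_plan),
         first_kernel = as.integer(first_kernel),
         last_kernel = as.integer(last_kernel),
         leaky_slope = leaky_slope,
         bottleneck_channels = as.integer(bottleneck_channels),
         conv1d_filters = as.integer(conv1d_filters),
         lstm_hidden = as.integer(lstm_hidden), dropout = dropout,
         lr_extractor = lr_extractor, lr_classifier = lr_classifier,
         batch_extractor = as.integer(batch_extractor),
         batch_classifier = as.integer(batch_classifier),
         epochs_extractor = as.integer(epochs_extractor),
         epochs_classifier = as.integer(epochs_classifier),
         patience = as.integer(patience), seed = as.integer(seed)),
    class = "ucnet_config"
  )
}

#' Full-scale UCNet preset
#'
#' The full-scale configuration (256 x 256 x 16 inputs, channel plan
#' 64/64/128/128, 300 extractor epochs); provided as a preset but not
#' exercised by the test suite, which uses desk-scale configurations.
#'
#' @param ... Overrides passed to [ucnet_config()].
#' @return A `ucnet_config`.
#' @export
ucnet_config_full <- function(...) {
  args <- list(height = 256, width = 256, slices = 16,
               dense_plan = c(64, 64, 128, 128),
               conv1d_filters = 64, lstm_hidden = 64,
               epochs_extractor = 300, epochs_classifier = 300)
  utils::modifyList(do.call(ucnet_config, args), list(...))
}

block_kernels <- function(cfg) c(cfg$first_kernel, 3L, 3L, cfg$last_kernel)

#' Build the autoencoder feature extractor
#'
#' Encoder: two dense blocks (4 conv layers each, DenseNet-style
#' concatenation, LeakyReLU) joined by 1x1-conv + 2x2-average-pool
#' transitions. Decoder: two residual blocks with nearest-neighbour
#' upsampling and skip concatenation from the matching encoder stage,
#' followed by a linear 1x1 output head that reconstructs the input. The
#' per-slice feature vector is the globally average-pooled bottleneck
#' (`bottleneck_channels` dimensions).
#'
#' @param cfg A [ucnet_config()].
#' @return Object of class `ucnet_extractor` with untrained weights.
#' @export
build_feature_extractor <- function(cfg) {
  stopifnot(inherits(cfg, "ucnet_config"))
  C0 <- length(cfg$sequences)
  kern <- block_kernels(cfg)
  plan <- cfg$dense_plan; rplan <- cfg$res_plan
  Cb <- cfg$bottleneck_channels
  with_seed(cfg$seed, {
    p <- list()
    add <- function(name, k, cin, cout) {
      p[[paste0(name, "_w")]] <<- conv_init(k, k, cin, cout)
      p[[paste0(name, "_b")]] <<- numeric(cout)
    }
    # encoder dense block 1: layer k input = block input + previous outputs
    cin <- C0
    for (k in 1:4) {
      add(sprintf("e1_conv%d", k), kern[k], cin, plan[k])
      cin <- cin + plan[k]
    }
    add("t1", 1L, C0 + sum(plan), plan[1])
    cin <- plan[1]
    for (k in 1:4) {
      add(sprintf("e2_conv%d", k), kern[k], cin, plan[k])
      cin <- cin + plan[k]
    }
    add("t2", 1L, plan[1] + sum(plan), Cb)
    # decoder residual block 1 operates on upsampled bottleneck + skipB
    cin <- 2L * Cb
    for (k in 1:4) {
      add(sprintf("d1_conv%d", k), kern[k], if (k == 1) cin else rplan[k - 1], rplan[k])
    }
    add("d1_proj", 1L, cin, rplan[4])
    cin <- rplan[4] + plan[1] # upsampled block-1 output + skipA
    for (k in 1:4) {
      add(sprintf("d2_conv%d", k), kern[k], if (k == 1) cin else rplan[k - 1], rplan[k])
    }
    add("d2_proj", 1L, cin, rplan[4])
    add("out", 1L, rplan[4], C0)
    structure(list(params = p, cfg = cfg, trained = FALSE),
              class = "ucnet_extractor")
  })
}

# rename dense-block layer params to the prefix scheme used by
# dense_block_fwd/bwd (prefix_w1..4)
block_params <- function(params, from_prefix) {
  out <- list()
  for (k in 1:4) {
    out[[sprintf("%s_w%d", from_prefix, k)]] <-
      params[[sprintf("%s_conv%d_w", from_prefix, k)]]
    out[[sprintf("%s_b%d", from_prefix, k)]] <-
      params[[sprintf("%s_conv%d_b", from_prefix, k)]]
  }
  pw <- params[[paste0(from_prefix, "_proj_w")]]
  if (!is.null(pw)) {
    out[[paste0(from_prefix, "_projw")]] <- pw
    out[[paste0(from_prefix, "_projb")]] <- params[[paste0(from_prefix, "_proj_b")]]
  }
  out
}

# map block-local gradient names back to the flat parameter names
unblock_grads <- function(grads, prefix) {
  out <- list()
  for (nm in names(grads)) {
    nm2 <- nm
    nm2 <- sub(sprintf("^(%s)_w(\\d)$", prefix), "\\1_conv\\2_w", nm2)
    nm2 <- sub(sprintf("^(%s)_b(\\d)$", prefix), "\\1_conv\\2_b", nm2)
    nm2 <- sub(sprintf("^(%s)_projw$", prefix), "\\1_proj_w", nm2)
    nm2 <- sub(sprintf("^(%s)_projb$", prefix), "\\1_proj_b", nm2)
    out[[nm2]] <- grads[[nm]]
  }
  out
}

ae_forward <- function(model, x, want_cache = TRUE) {
  cfg <- model$cfg; p <- model$params
  slope <- cfg$leaky_slope; kern <- block_kernels(cfg)
  b1 <- dense_block_fwd(x, block_params(p, "e1"), "e1", slope, kern, cfg$dense_plan)
  t1z <- conv2d_forward(b1$out, p$t1_w, p$t1_b)
  t1a <- lrelu_fwd(t1z, slope)                 # skip A (H x W)
  p1 <- avgpool2_fwd(t1a)
  b2 <- dense_block_fwd(p1, block_params(p, "e2"), "e2", slope, kern, cfg$dense_plan)
  t2z <- conv2d_forward(b2$out, p$t2_w, p$t2_b)
  t2a <- lrelu_fwd(t2z, slope)                 # skip B (H/2 x W/2)
  bott <- avgpool2_fwd(t2a)                    # bottleneck (H/4 x W/4)
  u1 <- upsample2_fwd(bott)
  c1 <- cat_ch(list(u1, t2a))
  r1 <- res_block_fwd(c1, block_params(p, "d1"), "d1", slope, kern, cfg$res_plan)
  u2 <- upsample2_fwd(r1$out)
  c2 <- cat_ch(list(u2, t1a))
  r2 <- res_block_fwd(c2, block_params(p, "d2"), "d2", slope, kern, cfg$res_plan)
  rec <- conv2d_forward(r2$out, p$out_w, p$out_b)
  out <- list(rec = rec, bottleneck = bott)
  if (want_cache) {
    out$cache <- list(x = x, b1 = b1, t1z = t1z, t1a = t1a, p1 = p1, b2 = b2,
                      t2z = t2z, t2a = t2a, bott = bott, u1 = u1, c1 = c1,
                      r1 = r1, u2 = u2, c2 = c2, r2 = r2)
  }
  out
}

ae_backward <- function(model, fwd, drec) {
  cfg <- model$cfg; p <- model$params
  slope <- cfg$leaky_slope; kern <- block_kernels(cfg)
  ca <- fwd$cache
  grads <- list()
  g <- conv2d_backward(ca$r2$out, p$out_w, drec)
  grads$out_w <- g$dw; grads$out_b <- g$db
  r2b <- res_block_bwd(ca$r2, block_params(p, "d2"), "d2", slope, g$dx)
  grads <- accumulate_grads(grads, unblock_grads(r2b$grads, "d2"))
  dc2 <- split_ch(r2b$dx, c(cfg$res_plan[4], cfg$dense_plan[1]))
  dr1out <- upsample2_bwd(dc2[[1]])
  dt1a_skip <- dc2[[2]]
  r1b <- res_block_bwd(ca$r1, block_params(p, "d1"), "d1", slope, dr1out)
  grads <- accumulate_grads(grads, unblock_grads(r1b$grads, "d1"))
  Cb <- cfg$bottleneck_channels
  dc1 <- split_ch(r1b$dx, c(Cb, Cb))
  dbott <- upsample2_bwd(dc1[[1]])
  dt2a_skip <- dc1[[2]]
  dt2a <- avgpool2_bwd(dbott, dim(ca$t2a)) + dt2a_skip
  dt2z <- lrelu_bwd(ca$t2z, dt2a, slope)
  g <- conv2d_backward(ca$b2$out, p$t2_w, dt2z)
  grads$t2_w <- g$dw; grads$t2_b <- g$db
  b2b <- dense_block_bwd(ca$b2, block_params(p, "e2"), "e2", slope, g$dx)
  grads <- accumulate_grads(grads, unblock_grads(b2b$grads, "e2"))
  dt1a <- avgpool2_bwd(b2b$dx, dim(ca$t1a)) + dt1a_skip
  dt1z <- lrelu_bwd(ca$t1z, dt1a, slope)
  g <- conv2d_backward(ca$b1$out, p$t1_w, dt1z)
  grads$t1_w <- g$dw; grads$t1_b <- g$db
  b1b <- dense_block_bwd(ca$b1, block_params(p, "e1"), "e1", slope, g$dx)
  grads <- accumulate_grads(grads, unblock_grads(b1b$grads, "e1"))
  grads
}

# stack the configured sequences of one patient into (H, W, C, S) slices,
# intensities scaled to [0, 1]
volume_to_slices <- function(vol, cfg) {
  missing <- setdiff(cfg$sequences, seq_names(vol))
  if (length(missing)) {
    stop("volume lacks configured sequence(s): ", paste(missing, collapse = ", "))
  }
  d <- dim(vol)
  if (d[1] != cfg$slices || d[2] != cfg$height || d[3] != cfg$width) {
    stop(sprintf("volume is %dx%dx%d but the extractor expects %dx%dx%d slices x H x W",
                 d[1], d[2], d[3], cfg$slices, cfg$height, cfg$width))
  }
  x <- array(0, dim = c(cfg$height, cfg$width, length(cfg$sequences), cfg$slices))
  for (ci in seq_along(cfg$sequences)) {
    a <- vol$sequences[[cfg$sequences[ci]]]
    rng <- range(a)
    if (rng[2] > rng[1]) a <- (a - rng[1]) / (rng[2] - rng[1])
    for (s in seq_len(cfg$slices)) x[, , ci, s] <- a[s, , ]
  }
  x
}

#' Train the autoencoder feature extractor
#'
#' Minimizes the mean-squared reconstruction error with Adam, processing
#' all slices of each mini-batch of patients jointly. Training stops early
#' once the epoch loss has not improved for `patience` epochs ("stop when
#' the loss curve reaches its lowest point"). Aborts on a non-finite loss.
#'
#' @param model An untrained [build_feature_extractor()] model.
#' @param volumes List of [volume_sequence()] objects (>= 1).
#' @param epochs,lr,batch_size,patience Optional overrides of the config.
#' @param verbose Print per-epoch losses.
#' @return The trained model, with `$history` (per-epoch mean loss).
#' @export
train_autoencoder <- function(model, volumes, epochs = NULL, lr = NULL,
                              batch_size = NULL, patience = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(model, "ucnet_extractor"), length(volumes) >= 1)
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs_extractor
  lr <- lr %||% cfg$lr_extractor
  batch_size <- batch_size %||% cfg$batch_extractor
  patience <- patience %||% cfg$patience
  xs <- lapply(volumes, volume_to_slices, cfg = cfg)
  state <- adam_init(model$params)
  history <- numeric(0)
  best <- Inf; stall <- 0L
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(xs))
      ep_loss <- 0; nb <- 0L
      for (start in seq(1, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, length(ord))]
        xb <- do.call(cat_n, list(xs[idx]))
        fwd <- ae_forward(model, xb)
        resid <- fwd$rec - xb
        loss <- mean(resid^2)
        if (!is.finite(loss)) stop("non-finite reconstruction loss at epoch ", ep)
        drec <- 2 * resid / length(resid)
        grads <- ae_backward(model, fwd, drec)
        upd <- adam_step(model$params, grads, state, lr)
        model$params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      history <- c(history, ep_loss / nb)
      if (verbose) message(sprintf("epoch %d: loss %.6g", ep, ep_loss / nb))
      if (ep_loss / nb < best - 1e-10) {
        best <- ep_loss / nb; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  })
  model$trained <- TRUE
  model$history <- history
  model
}

# concatenate (H, W, C, S) arrays along the 4th (sample) dimension
cat_n <- function(xs) {
  d <- dim(xs[[1]])
  ns <- vapply(xs, function(x) dim(x)[4], 1L)
  out <- array(0, dim = c(d[1], d[2], d[3], sum(ns)))
  at <- 0L
  for (x in xs) {
    out[, , , at + seq_len(dim(x)[4])] <- x
    at <- at + dim(x)[4]
  }
  out
}

#' Extract the per-slice feature sequence of a patient
#'
#' Runs the encoder and returns the globally average-pooled bottleneck
#' activations, one vector per slice in slice order.
#'
#' @param model A trained [ucnet_extractor] (see [train_autoencoder()]).
#' @param vol A [volume_sequence()] matching the extractor's configured
#'   dimensions.
#' @return Numeric matrix `slices x bottleneck_channels`.
#' @export
extract_feature_sequence <- function(model, vol) {
  stopifnot(inherits(model, "ucnet_extractor"))
  if (!isTRUE(model$trained)) {
    warning("extractor has not been trained; features come from random weights")
  }
  x <- volume_to_slices(vol, model$cfg)
  fwd <- ae_forward(model, x, want_cache = FALSE)
  t(gap_fwd(fwd$bottleneck)) # slices x channels
}
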