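# Low-level neural-network primitives shared by the autoencoder feature
# extractor and the CRNN classifier. Images are (H, W, C, N) arrays, conv
# weights (KH, KW, Cin, Cout); all convolutions are stride-1 "same".

lrelu_fwd <- function(x, slope) ifelse(x > 0, x, slope * x)
lrelu_bwd <- function(x, dy, slope) dy * ifelse(x > 0, 1, slope)

conv_init <- function(kh, kw, cin, cout) {
  # He-style init for leaky-ReLU layers
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

n_channels <- function(x) dim(x)[3]

cat_ch <- function(xs) {
  # concatenate 4-D arrays along the channel dimension
  d <- dim(xs[[1]])
  cs <- vapply(xs, n_channels, 1L)
  out <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    out[, , at + seq_len(n_channels(x)), ] <- x
    at <- at + n_channels(x)
  }
  out
}

split_ch <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(s) {
    out <- x[, , at + seq_len(s), , drop = FALSE]
    at <<- at + s
    out
  })
}

avgpool2_fwd <- function(x) {
  d <- dim(x)
  io <- seq(1, d[1], by = 2); jo <- seq(1, d[2], by = 2)
  (x[io, jo, , , drop = FALSE] + x[io + 1, jo, , , drop = FALSE] +
     x[io, jo + 1, , , drop = FALSE] + x[io + 1, jo + 1, , , drop = FALSE]) / 4
}

avgpool2_bwd <- function(dy, in_dim) {
  dx <- array(0, dim = in_dim)
  io <- seq(1, in_dim[1], by = 2); jo <- seq(1, in_dim[2], by = 2)
  g <- dy / 4
  dx[io, jo, , ] <- g
  dx[io + 1, jo, , ] <- g
  dx[io, jo + 1, , ] <- g
  dx[io + 1, jo + 1, , ] <- g
  dx
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  io <- seq(1, d[1], by = 2); jo <- seq(1, d[2], by = 2)
  dy[io, jo, , , drop = FALSE] + dy[io + 1, jo, , , drop = FALSE] +
    dy[io, jo + 1, , , drop = FALSE] + dy[io + 1, jo + 1, , , drop = FALSE]
}

gap_fwd <- function(x) {
  # global average pool -> C x N matrix of per-slice feature vectors
  d <- dim(x)
  m <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
  matrix(m, d[3], d[4])
}

# --- dense block: each conv layer sees the concatenation of the block input
# --- and all previous layer outputs (DenseNet-style connectivity)
dense_block_fwd <- function(x, params, prefix, slope, kernels, plan) {
  feats <- list(x)
  caches <- vector("list", length(plan))
  for (k in seq_along(plan)) {
    xin <- if (k == 1) x else cat_ch(feats)
    w <- params[[sprintf("%s_w%d", prefix, k)]]
    b <- params[[sprintf("%s_b%d", prefix, k)]]
    z <- conv2d_forward(xin, w, b)
    caches[[k]] <- list(xin = xin, z = z)
    feats[[k + 1]] <- lrelu_fwd(z, slope)
  }
  list(out = cat_ch(feats), feats_ch = vapply(feats, n_channels, 1L),
       caches = caches)
}

dense_block_bwd <- function(fwd, params, prefix, slope, dout) {
  sizes <- fwd$feats_ch
  dfeats <- split_ch(dout, sizes)
  grads <- list()
  for (k in rev(seq_along(fwd$caches))) {
    cache <- fwd$caches[[k]]
    dz <- lrelu_bwd(cache$z, dfeats[[k + 1]], slope)
    w <- params[[sprintf("%s_w%d", prefix, k)]]
    g <- conv2d_backward(cache$xin, w, dz)
    grads[[sprintf("%s_w%d", prefix, k)]] <- g$dw
    grads[[sprintf("%s_b%d", prefix, k)]] <- g$db
    din_parts <- split_ch(g$dx, sizes[seq_len(k)])
    for (m in seq_len(k)) dfeats[[m]] <- dfeats[[m]] + din_parts[[m]]
  }
  list(dx = dfeats[[1]], grads = grads)
}

# --- residual block: 4 conv layers plus a 1x1 projection shortcut added to
# --- the final pre-activation
res_block_fwd <- function(x, params, prefix, slope, kernels, plan) {
  caches <- vector("list", length(plan))
  a <- x
  for (k in seq_along(plan)) {
    w <- params[[sprintf("%s_w%d", prefix, k)]]
    b <- params[[sprintf("%s_b%d", prefix, k)]]
    z <- conv2d_forward(a, w, b)
    caches[[k]] <- list(xin = a, z = z)
    if (k < length(plan)) a <- lrelu_fwd(z, slope)
  }
  zp <- conv2d_forward(x, params[[paste0(prefix, "_projw")]],
                       params[[paste0(prefix, "_projb")]])
  ypre <- caches[[length(plan)]]$z + zp
  list(out = lrelu_fwd(ypre, slope), ypre = ypre, caches = caches, x = x)
}

res_block_bwd <- function(fwd, params, prefix, slope, dout) {
  plan_len <- length(fwd$caches)
  dypre <- lrelu_bwd(fwd$ypre, dout, slope)
  grads <- list()
  gp <- conv2d_backward(fwd$x, params[[paste0(prefix, "_projw")]], dypre)
  grads[[paste0(prefix, "_projw")]] <- gp$dw
  grads[[paste0(prefix, "_projb")]] <- gp$db
  dx_proj <- gp$dx
  da <- dypre
  for (k in rev(seq_len(plan_len))) {
    cache <- fwd$caches[[k]]
    dz <- if (k == plan_len) da else lrelu_bwd(cache$z, da, slope)
    w <- params[[sprintf("%s_w%d", prefix, k)]]
    g <- conv2d_backward(cache$xin, w, dz)
    grads[[sprintf("%s_w%d", prefix, k)]] <- g$dw
    grads[[sprintf("%s_b%d", prefix, k)]] <- g$db
    da <- g$dx
  }
  list(dx = da + dx_proj, grads = grads)
}

# --- Adam optimizer over a named list of parameter arrays
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

accumulate_grads <- function(total, g) {
  for (nm in names(g)) {
    total[[nm]] <- if (is.null(total[[nm]])) g[[nm]] else total[[nm]] + g[[nm]]
  }
  total
}
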