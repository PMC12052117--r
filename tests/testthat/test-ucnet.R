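tiny_ucfg <- function(...) {
  args <- utils::modifyList(
    list(height = 16, width = 16, slices = 3, sequences = "T2",
         dense_plan = c(3, 3, 4, 4), conv1d_filters = 6,
         lstm_hidden = 5, dropout = 0, lr_extractor = 1e-2,
         lr_classifier = 5e-2, batch_extractor = 2,
         batch_classifier = 8, epochs_extractor = 5,
         epochs_classifier = 30, seed = 1),
    list(...)
  )
  do.call(ucnet_config, args)
}

tiny_volume <- function(seed = 1, constant = NULL, cfg = tiny_ucfg()) {
  arr <- if (is.null(constant)) {
    set.seed(seed)
    array(runif(cfg$slices * cfg$height * cfg$width),
          c(cfg$slices, cfg$height, cfg$width))
  } else {
    array(constant, c(cfg$slices, cfg$height, cfg$width))
  }
  volume_sequence(sprintf("p%03d", seed), stats::setNames(list(arr), cfg$sequences))
}

test_that("the weighted loss reduces to its supervised limits exactly", {
  set.seed(20)
  n_lab <- 4; n_pseudo <- 3
  p_true <- runif(n_lab + n_pseudo, 0.2, 0.95)
  ell <- -log(p_true)
  # alpha = 1: the plain sum over all instances
  expect_identical(weighted_loss(p_true, weights = rep(1, 7)), sum(ell))
  # alpha = 0: the labeled-only sum
  w0 <- c(rep(1, n_lab), rep(0, n_pseudo))
  expect_identical(weighted_loss(p_true, weights = w0), sum(ell[1:n_lab]))
  # hand-computed two-sample case: 0.5 + 0.2 * 0.4 = 0.58
  preds <- exp(-c(0.5, 0.4))
  expect_equal(weighted_loss(preds, weights = c(1, 0.2)), 0.58,
               tolerance = 1e-12)
  # matrix + label interface agrees with the vector interface
  probs <- cbind(wild = 1 - p_true, mutant = p_true)
  expect_equal(weighted_loss(probs, rep("mutant", 7), rep(0.5, 7)),
               0.5 * sum(ell), tolerance = 1e-12)
  expect_error(weighted_loss(p_true, weights = rep(1.5, 7)), "\\[0, 1\\]")
})

test_that("the extractor architecture honors its shape contracts", {
  cfg <- tiny_ucfg()
  model <- build_feature_extractor(cfg)
  # dense blocks: 4 conv layers with the declared channel plan
  for (k in 1:4) {
    w <- model$params[[sprintf("e1_conv%d_w", k)]]
    expect_identical(dim(w)[4], cfg$dense_plan[k])
    expect_identical(dim(w)[1], c(cfg$first_kernel, 3L, 3L, cfg$last_kernel)[k])
  }
  # dense connectivity: layer k consumes the block input plus all previous
  # layer outputs
  expect_identical(dim(model$params$e1_conv3_w)[3],
                   1L + sum(cfg$dense_plan[1:2]))
  x <- array(runif(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  ns <- asNamespace("gliosemi")
  fwd <- ns$ae_forward(model, x, want_cache = FALSE)
  # reconstruction has the input's shape; bottleneck sits at H/4 x W/4
  expect_identical(dim(fwd$rec), dim(x))
  expect_identical(dim(fwd$bottleneck),
                   c(4L, 4L, cfg$bottleneck_channels, 2L))
  expect_error(ucnet_config(height = 18, width = 16), "divisible by 4")
  # multi-sequence input changes only the input channel count
  cfg2 <- tiny_ucfg(sequences = c("T2", "FLAIR"))
  m2 <- build_feature_extractor(cfg2)
  expect_identical(dim(m2$params$e1_conv1_w)[3], 2L)
  expect_identical(dim(m2$params$e2_conv1_w), dim(model$params$e2_conv1_w))
})

test_that("autoencoder training reduces reconstruction loss deterministically", {
  cfg <- tiny_ucfg()
  vols <- lapply(1:6, tiny_volume, cfg = cfg)
  model <- build_feature_extractor(cfg)
  trained <- train_autoencoder(model, vols)
  expect_lt(tail(trained$history, 1), trained$history[1])
  trained2 <- train_autoencoder(build_feature_extractor(cfg), vols)
  expect_identical(trained$history, trained2$history)
  expect_identical(trained$params, trained2$params)
  # constant-zero volumes are trivially learnable: loss collapses
  zvols <- lapply(1:4, function(i) tiny_volume(i, constant = 0, cfg = cfg))
  zt <- train_autoencoder(build_feature_extractor(cfg), zvols,
                          epochs = 25, lr = 5e-2)
  expect_lt(tail(zt$history, 1), 1e-4)
})

test_that("feature sequences follow slice order and bottleneck width", {
  cfg <- tiny_ucfg()
  vols <- lapply(1:4, tiny_volume, cfg = cfg)
  model <- train_autoencoder(build_feature_extractor(cfg), vols, epochs = 2)
  fs <- extract_feature_sequence(model, vols[[1]])
  expect_identical(dim(fs), c(cfg$slices, cfg$bottleneck_channels))
  expect_identical(fs, extract_feature_sequence(model, vols[[1]]))
  bad <- tiny_volume(9, cfg = tiny_ucfg(slices = 4))
  expect_error(extract_feature_sequence(model, bad), "expects")
})

test_that("the CRNN learns separable sequences and predicts deterministically", {
  cfg <- tiny_ucfg()
  set.seed(33)
  n <- 40; S <- cfg$slices; F_ <- cfg$bottleneck_channels
  labels <- rep(c("mutant", "wild"), each = n / 2)
  seqs <- lapply(seq_len(n), function(i) {
    shift <- if (labels[i] == "mutant") 1 else -1
    matrix(rnorm(S * F_, mean = shift, sd = 0.5), S, F_)
  })
  model <- build_crnn(cfg, feature_dim = F_)
  expect_error(predict(model, seqs[[1]]), "not been trained")
  expect_error(train_classifier(model, seqs, rep("mutant", n)),
               "single class")
  trained <- train_classifier(model, seqs, labels)
  expect_gte(tail(trained$history$accuracy, 1), 0.95)
  pred <- predict(trained, seqs[1:4])
  expect_equal(pred$prob_mutant + pred$prob_wild, rep(1, 4), tolerance = 1e-12)
  expect_identical(pred, predict(trained, seqs[1:4]))
  expect_identical(pred$class,
                   c("wild", "mutant")[1 + (pred$prob_mutant > 0.5)])
  # the larger supervised-only batch size is accepted from config
  cfg40 <- tiny_ucfg(batch_classifier = 40)
  t40 <- train_classifier(build_crnn(cfg40, feature_dim = F_), seqs, labels,
                          epochs = 1)
  expect_identical(nrow(t40$history), 1L)
  expect_error(
    train_classifier(build_crnn(cfg, feature_dim = F_), seqs, labels,
                     weights = rep(2, n)),
    "\\[0, 1\\]"
  )
})

test_that("dropout only affects training, not inference", {
  cfg <- tiny_ucfg(dropout = 0.5)
  set.seed(44)
  S <- cfg$slices; F_ <- cfg$bottleneck_channels
  labels <- rep(c("mutant", "wild"), 10)
  seqs <- lapply(seq_len(20), function(i) {
    matrix(rnorm(S * F_, mean = ifelse(labels[i] == "mutant", 1, -1)), S, F_)
  })
  trained <- train_classifier(build_crnn(cfg, feature_dim = F_), seqs, labels,
                              epochs = 10)
  p1 <- predict(trained, seqs)
  p2 <- predict(trained, seqs)
  expect_identical(p1, p2)
})
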