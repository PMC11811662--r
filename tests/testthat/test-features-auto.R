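test_that("closest power of two minimizes distance with downward ties", {
  expect_equal(closest_power_of_two(64), 64)
  expect_equal(closest_power_of_two(2750), 2048)  # |2750-2048| < |4096-2750|
  expect_equal(closest_power_of_two(96), 64)      # tie 32 vs 32, downward
  expect_equal(closest_power_of_two(1), 1)
  expect_equal(closest_power_of_two(55), 64)
  expect_error(closest_power_of_two(0), "positive")
})

test_that("autoencoder configs enforce the latent < cp2 invariant", {
  cfg <- ae_config(2750, 32)
  expect_equal(cfg$cp2, 2048)
  expect_error(ae_config(100, 128), "latent_dim")
})

test_that("both architectures satisfy the shape contract", {
  X <- matrix(runif(12 * 55), 12, 55)
  for (arch in c("cnn", "lstm")) {
    cfg <- ae_config(55, 8, arch = arch, seed = 3, lstm_hidden = 8)
    m <- if (arch == "cnn") build_cnn_ae(cfg) else build_lstm_ae(cfg)
    fw <- painpipe:::ae_forward(m, X)
    expect_equal(dim(fw$latent), c(12, 8))
    expect_equal(dim(fw$recon), dim(X))
  }
})

test_that("analytic gradients match numerical gradients", {
  set.seed(3)
  X <- matrix(runif(5 * 40), 5, 40)
  for (arch in c("cnn", "lstm")) {
    cfg <- ae_config(40, 5, arch = arch, seed = 2, lstm_hidden = 6)
    m <- if (arch == "cnn") build_cnn_ae(cfg) else build_lstm_ae(cfg)
    fw <- painpipe:::ae_forward(m, X)
    err <- fw$recon - X
    g <- painpipe:::ae_backward(m, fw$cache, 2 * err / length(err))
    eps <- 1e-5
    for (blk in names(m$params)) {
      W <- m$params[[blk]]$W
      for (trial in 1:3) {
        i <- sample(length(W), 1)
        m2 <- m
        m2$params[[blk]]$W[i] <- W[i] + eps
        lp <- mean((painpipe:::ae_forward(m2, X)$recon - X)^2)
        m2$params[[blk]]$W[i] <- W[i] - eps
        lm <- mean((painpipe:::ae_forward(m2, X)$recon - X)^2)
        num <- (lp - lm) / (2 * eps)
        expect_equal(g[[blk]]$W[i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training reduces reconstruction loss deterministically", {
  set.seed(5)
  tt <- seq(0, 10, length.out = 64)
  X <- t(sapply(1:40, function(i) sin(2 * pi * tt / runif(1, 3, 8)) +
                  0.1 * rnorm(64)))
  Xn <- normalize_windows(X)
  cfg <- ae_config(64, 8, arch = "cnn", epochs = 30, seed = 1)
  enc <- train_ae(build_cnn_ae(cfg), Xn)
  expect_length(enc$loss_history, 30)
  expect_lt(enc$loss_history[30], enc$loss_history[1])
  # better than the best constant predictor
  expect_lt(enc$loss_history[30], mean(apply(Xn, 2, stats::var)))
  # bitwise determinism of training and latents
  enc2 <- train_ae(build_cnn_ae(cfg), Xn)
  expect_identical(enc$loss_history, enc2$loss_history)
  expect_identical(ae_encode(enc, Xn), ae_encode(enc2, Xn))
  # too little data
  expect_error(train_ae(build_cnn_ae(cfg), Xn[1:5, ]), "batch_size")
  # wrong window length at encode time
  expect_error(ae_encode(enc, Xn[, 1:32]), "expects")
})

test_that("an LSTM autoencoder learns a trivially learnable target", {
  X <- matrix(0.5, 100, 32)
  cfg <- ae_config(32, 4, arch = "lstm", epochs = 100, seed = 2,
                   lstm_hidden = 8)
  enc <- train_ae(build_lstm_ae(cfg), X)
  expect_lt(mean((ae_reconstruct(enc, X) - X)^2), 1e-3)
  # seeded builds are identical before training
  m1 <- build_lstm_ae(cfg); m2 <- build_lstm_ae(cfg)
  expect_identical(m1$params, m2$params)
})

test_that("automatic features have the fixed per-modality cardinalities", {
  # tiny training budget: cardinality is a shape property, not a fit one
  cfg <- default_config()
  cfg$autoencoder$epochs <- 2L
  cfg$autoencoder$resample_len <- c(ecg = 64L, emg = 64L, eda = 64L,
                                    rr = 64L)
  rec <- fixture_preprocessed()
  enc <- train_modality_encoders(list(rec), window_len = 10, cfg = cfg)
  feats <- extract_auto_features(enc, rec, window_len = 10, cfg = cfg)
  expect_equal(ncol(feature_matrix(feats$ecg)), 32)
  expect_equal(ncol(feature_matrix(feats$eda)), 32)
  expect_equal(ncol(feature_matrix(feats$rr)), 32)
  expect_equal(ncol(feature_matrix(feats$emg)), 30)  # 6 x 5 channels
  total <- sum(vapply(feats, function(d) ncol(feature_matrix(d)),
                      numeric(1)))
  expect_equal(total, 126)
  expect_true(all(feats$ecg$feature_source == "auto_cnn"))
})
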