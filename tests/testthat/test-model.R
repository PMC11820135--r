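test_that("positional encoding matches the sinusoidal definition", {
  pe <- positional_encoding(44, 16)
  expect_equal(pe[1, ], rep(c(0, 1), 8))
  expect_true(all(pe >= -1 & pe <= 1))
  expect_equal(pe[6, 1], sin(5))
  expect_equal(pe[6, 2], cos(5))
  expect_equal(pe[3, 3], sin(2 / 10000^(2 / 16)))
  expect_error(positional_encoding(10, 7), "even")
})

test_that("count_params agrees across total, per-layer, and named queries", {
  dec <- build_mi_decoder(model_config(), seed = 1)
  tot <- count_params(dec)
  by_layer <- attr(tot, "by_layer")
  expect_equal(sum(by_layer), as.integer(tot))
  expect_equal(count_params(dec, "multi_head_attention"), 17168)
  expect_equal(count_params(dec, "batch_normalization"), 512)
  expect_error(count_params(dec, "dense_99"), "unknown layer")
  # symmetric mode restores the second feed-forward sub-layer
  sym <- build_mi_decoder(model_config(symmetric_blocks = TRUE), seed = 1)
  expect_equal(as.integer(count_params(sym)) - as.integer(tot),
               2176 + 2064 + 32 + 32)
})

test_that("focal loss reduces to cross-entropy and matches direct evaluation", {
  expect_equal(focal_loss(c(0, 1), 2), 0, tolerance = 1e-9)
  p <- c(0.3, 0.7)
  expect_equal(focal_loss(p, 2, focal_loss_params(gamma = 0)), -log(0.7))
  expect_equal(focal_loss(c(0.1, 0.9), 2, focal_loss_params(gamma = 2)),
               0.01 * -log(0.9), tolerance = 1e-9)
  expect_equal(0.01 * -log(0.9), 1.0536e-3, tolerance = 1e-4)
  # batch form averages
  pm <- rbind(c(0.2, 0.8), c(0.6, 0.4))
  expect_equal(focal_loss(pm, c(2L, 1L), focal_loss_params(gamma = 0)),
               mean(-log(c(0.8, 0.6))))
  # strictly decreasing in p_true
  ps <- seq(0.05, 0.95, by = 0.05)
  ls <- vapply(ps, function(p) focal_loss(c(1 - p, p), 2), 0)
  expect_true(all(diff(ls) < 0))
  expect_error(focal_loss(c(0.5, 0.2), 1), "probability")
  expect_error(focal_loss_params(gamma = -1), "gamma")
})

test_that("analytic gradients match finite differences on a small model", {
  cfg <- model_config(seq_len = 6, embed_dim = 4, n_heads = 2,
                      head_size = 3, ffn_units = 5, head_units = c(7, 6),
                      dropout_attention = 0, dropout_ffn = 0)
  set.seed(11)
  w <- mibci:::init_weights(cfg, 42)
  n <- 4
  X <- array(stats::rnorm(n * 6 * 4), c(n, 6, 4))
  y <- c(1L, 2L, 1L, 2L)
  gamma <- 2; alpha <- c(1.2, 0.8)
  lossfun <- function(w) {
    fw <- mibci:::model_forward(w, cfg, X, train = TRUE)
    focal_loss(fw$probs, y, focal_loss_params(gamma, alpha))
  }
  fw <- mibci:::model_forward(w, cfg, X, train = TRUE, collect = TRUE)
  dZ <- mibci:::focal_loss_grad_logits(fw$probs, y, gamma, alpha)
  g <- mibci:::model_backward(w, cfg, fw$cache, dZ, n)
  eps <- 1e-6
  for (nm in mibci:::trainable_names(w)) {
    idx <- sample(length(w[[nm]]), min(2, length(w[[nm]])))
    for (i in idx) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (lossfun(wp) - lossfun(wm)) / (2 * eps)
      # absolute comparison: near-zero gradients (e.g. key biases, where
      # the softmax is shift-invariant) carry finite-difference noise
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("softmax outputs are valid probabilities for random inputs", {
  dec <- build_mi_decoder(model_config(), seed = 3)
  set.seed(4)
  X <- array(stats::rnorm(8 * 44 * 16), c(8, 44, 16))
  probs <- mibci:::model_forward(dec$weights, dec$config, X)$probs
  expect_equal(rowSums(probs), rep(1, 8), tolerance = 1e-6)
  expect_true(all(probs >= 0))
})

test_that("training is seed-deterministic and rejects single-class data", {
  batch <- generate_epoch_batch(subject_profile(effect_size = 0.9,
                                                seed = 51),
                                n_per_class = 40)
  parts <- split_by_group(batch, "trial", 0.25, seed = 1)
  a <- mi_decoder(parts$train, val_epochs = parts$test, max_epochs = 4,
                  seed = 9)
  b <- mi_decoder(parts$train, val_epochs = parts$test, max_epochs = 4,
                  seed = 9)
  expect_identical(a$weights, b$weights)
  expect_identical(a$history, b$history)
  fist_only <- parts$train[parts$train$labels == "fist"]
  expect_error(mi_decoder(fist_only, val_epochs = parts$test,
                          max_epochs = 2, seed = 1), "both classes")
  # inverse-frequency alpha was recorded and averages to one
  expect_equal(mean(a$loss$alpha), 1, tolerance = 1e-9)
})

test_that("intent decoding applies the threshold with the documented tie-break", {
  dec <- get_trained_decoder()
  fist_feat <- class_feature_stream("fist", 1)[[1]]
  rest_feat <- class_feature_stream("rest", 1)[[1]]
  out <- decode_intent(dec, fist_feat)
  expect_equal(out$s_t, 1L)
  expect_gte(out$probabilities[["fist"]], 0.5)
  out0 <- decode_intent(dec, rest_feat)
  expect_equal(out0$s_t, 0L)
  # threshold semantics: s_t = 1 iff P(fist) >= threshold
  p <- out$probabilities[["fist"]]
  expect_equal(decode_intent(dec, fist_feat, threshold = p)$s_t, 1L)
  expect_equal(decode_intent(dec, fist_feat,
                             threshold = min(1, p + 1e-6))$s_t, 0L)
  expect_error(predict(dec, matrix(0, 10, 16)), "shape")
})

test_that("checkpoints round trip through save and load", {
  dec <- get_trained_decoder()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(dec, path)
  back <- load_checkpoint(path)
  expect_identical(back$weights, dec$weights)
  expect_identical(back$classes, dec$classes)
  saveRDS(list(format = "other"), path)
  expect_error(load_checkpoint(path), "checkpoint")
})
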