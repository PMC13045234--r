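# The reduced-dimension configuration exercises the same code paths as
# the full architecture at a fraction of the cost; the full-size model
# is trained in test-acceptance.R.

test_that("forward pass produces valid dual predictions", {
  cfg <- tiny_recognizer_config()
  model <- build_model(cfg, seed = 1L)
  set.seed(1)
  x <- array(rnorm(8 * 8 * 5), c(8L, 8L, 5L))
  pred <- predict_model(model, x)
  expect_identical(dim(pred$emotion_probs), c(5L, 6L))
  expect_identical(dim(pred$text_probs), c(5L, 5L))
  expect_true(all(pred$emotion_probs >= 0))
  expect_equal(rowSums(pred$emotion_probs), rep(1, 5), tolerance = 1e-6)
  expect_equal(rowSums(pred$text_probs), rep(1, 5), tolerance = 1e-6)
  # wrong input shape is rejected with the expected shape in the message
  expect_error(predict_model(model, array(0, c(7, 8, 2))), "8")
})

test_that("inference is deterministic and batch-order equivariant", {
  cfg <- tiny_recognizer_config()
  model <- build_model(cfg, seed = 2L)
  set.seed(9)
  x <- array(rnorm(8 * 8 * 6), c(8L, 8L, 6L))
  p1 <- predict_model(model, x)
  p2 <- predict_model(model, x)
  expect_identical(p1$emotion_probs, p2$emotion_probs)
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  p3 <- predict_model(model, x[, , perm])
  expect_equal(p3$emotion_probs, p1$emotion_probs[perm, ],
               tolerance = 1e-4)
  # single matrix input works
  p4 <- predict_model(model, x[, , 1])
  expect_equal(unname(p4$emotion_probs[1, ]),
               unname(p1$emotion_probs[1, ]), tolerance = 1e-4)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_recognizer_config()
  set.seed(42)
  x <- array(rnorm(8 * 8 * 3), c(8L, 8L, 3L))
  y_em <- c(0L, 1L, 2L); y_tx <- c(0L, 1L, 0L)
  params <- throatspeech:::init_recognizer_params(cfg, 7L)
  res <- throatspeech:::.nn_loss_grad_cpp(params, cfg, x, y_em, y_tx, 1)
  expect_equal(res$loss, res$loss_emotion + res$loss_text,
               tolerance = 1e-6)
  eps <- 1e-3   # single-precision core: coarser finite differences
  for (nm in c("conv1_w", "conv2_w", "bn1_gamma", "bn2_beta",
               "lstm1_fwd_w", "lstm2_bwd_u", "attn_wq", "attn_wo",
               "ln1_gamma", "ff1_w", "fc_w", "head_em_w", "head_tx_b")) {
    g <- res$grads[[nm]]
    for (i in sample(length(g), min(3, length(g)))) {
      p2 <- params
      p2[[nm]][i] <- p2[[nm]][i] + eps
      lp <- throatspeech:::.nn_loss_grad_cpp(p2, cfg, x, y_em, y_tx, 1)$loss
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      lm <- throatspeech:::.nn_loss_grad_cpp(p2, cfg, x, y_em, y_tx, 1)$loss
      num <- (lp - lm) / (2 * eps)
      # float forward: finite differences carry ~1e-4 absolute noise
      expect_lt(abs(num - g[i]), 1e-3 + 0.02 * (abs(num) + abs(g[i])))
    }
  }
})

test_that("training reduces loss, stops early, and is seed-reproducible", {
  cfg <- tiny_recognizer_config(max_epochs = 100L, patience = 100L,
                                batch_size = 16L, learning_rate = 0.01)
  set.seed(5)
  n <- 36L
  y_em <- rep(0:5, each = 6L)
  y_tx <- rep(0:4, length.out = n)
  # class-dependent mean patterns: separable by construction
  x <- array(rnorm(8 * 8 * n, sd = 0.3), c(8L, 8L, n))
  for (i in seq_len(n)) {
    x[(y_em[i] %% 4) + 1, , i] <- x[(y_em[i] %% 4) + 1, , i] + 2 + y_em[i]
    x[, (y_tx[i] %% 4) + 1, i] <- x[, (y_tx[i] %% 4) + 1, i] + 2 + y_tx[i]
  }
  set <- list(x = x, y_emotion = y_em, y_text = y_tx)
  m1 <- train_model(build_model(cfg, 1L), set, set, seed = 3L)
  expect_lt(utils::tail(m1$training_log$train_loss, 1),
            m1$training_log$train_loss[1])
  pred <- predict_model(m1, x)
  # the reduced-width model learns the planted structure well above
  # chance (1/6, 1/5) on both heads
  expect_gt(mean(pred$emotion == EMOTIONS[y_em + 1L]), 0.7)
  expect_gt(mean(pred$sentence_id == y_tx), 0.7)
  # identical seeds reproduce the trajectory
  m2 <- train_model(build_model(cfg, 1L), set, set, seed = 3L)
  expect_equal(m1$training_log$val_loss, m2$training_log$val_loss,
               tolerance = 1e-10)
  # conflicting labels bound validation accuracy below 1
  y_bad <- set; y_bad$y_emotion <- rev(y_em)
  m3 <- train_model(build_model(cfg, 1L), set, y_bad, seed = 3L)
  last <- utils::tail(m3$training_log, 1)
  expect_lt(last$val_acc_emotion, 1)
  # empty split is rejected
  empty <- list(x = x[, , 0, drop = FALSE], y_emotion = integer(0),
                y_text = integer(0))
  expect_error(train_model(build_model(cfg, 1L), empty, set, seed = 1L),
               "empty")
})

test_that("early stopping respects the patience setting", {
  cfg <- tiny_recognizer_config(max_epochs = 50L, patience = 3L,
                                batch_size = 8L)
  set.seed(6)
  # pure-noise labels: validation loss cannot improve for long
  x <- array(rnorm(8 * 8 * 16), c(8L, 8L, 16L))
  set <- list(x = x, y_emotion = sample(0:5, 16, TRUE),
              y_text = sample(0:4, 16, TRUE))
  xv <- array(rnorm(8 * 8 * 16), c(8L, 8L, 16L))
  val <- list(x = xv, y_emotion = sample(0:5, 16, TRUE),
              y_text = sample(0:4, 16, TRUE))
  m <- train_model(build_model(cfg, 1L), set, val, seed = 2L)
  n_ep <- nrow(m$training_log)
  expect_lt(n_ep, 50L)
  expect_gte(n_ep, m$best_epoch + 3L)
})

test_that("model checkpoints round-trip through save/load", {
  cfg <- tiny_recognizer_config()
  model <- build_model(cfg, seed = 4L)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  set.seed(3)
  x <- array(rnorm(8 * 8 * 2), c(8L, 8L, 2L))
  expect_identical(predict_model(model, x)$emotion_probs,
                   predict_model(back, x)$emotion_probs)
  unlink(path)
})
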