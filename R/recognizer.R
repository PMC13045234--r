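# Dual-head recognizer: CNN front end, bidirectional LSTM, transformer
# encoder block, shared trunk with 6-class emotion and 5-class sentence
# softmax heads. The numerical core lives in src/nnet.cpp.

#' Recognizer configuration
#'
#' Architecture and training hyperparameters: two 3x3 convolution
#' stages (32 then 64 channels, ReLU, batch normalization, 2x2 max
#' pooling), a 2-layer bidirectional LSTM (128 units per direction,
#' dropout 0.3), one transformer encoder block (8 heads, width 128,
#' feed-forward 256), global average pooling, a 128-unit fully
#' connected layer (dropout 0.5) and two softmax heads. Training uses
#' Adam (learning rate 0.001), mini-batches of 64 and early stopping
#' with patience 10.
#'
#' @param ... Overrides of the defaults listed above.
#' @return A `recognizer_config` list.
#' @export
recognizer_config <- function(...) {
  cfg <- list(
    n_feature_rows = 40L, n_frames = 128L,
    conv_channels1 = 32L, conv_channels2 = 64L,
    lstm_units = 128L, attn_dim = 128L, attn_heads = 8L,
    ff_dim = 256L, fc_units = 128L,
    n_emotions = 6L, n_texts = 5L,
    dropout_lstm = 0.3, dropout_fc = 0.5,
    bn_eps = 1e-5, bn_momentum = 0.1,
    learning_rate = 0.001, batch_size = 64L,
    max_epochs = 100L, patience = 10L,
    max_grad_norm = 5
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown recognizer option: ", nm)
    cfg[[nm]] <- over[[nm]]
  }
  if (cfg$attn_dim %% cfg$attn_heads != 0)
    stop("attn_dim must be divisible by attn_heads")
  structure(cfg, class = "recognizer_config")
}

glorot <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

# He (fan-in) initialization for layers feeding a ReLU
he_init <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)
}

# block-orthogonal initialization for LSTM recurrent matrices
orth_blocks <- function(h, blocks = 4L) {
  do.call(rbind, lapply(seq_len(blocks), function(i) {
    qr.Q(qr(matrix(stats::rnorm(h * h), h, h)))
  }))
}

init_recognizer_params <- function(config, seed = 0L) {
  cf <- config
  with_seed(seed, {
    H <- cf$lstm_units; D <- cf$attn_dim
    Ds <- cf$conv_channels2 * cf$n_feature_rows %/% 4L
    p <- list(
      conv1_w = he_init(cf$conv_channels1, 9L),
      conv1_b = numeric(cf$conv_channels1),
      bn1_gamma = rep(1, cf$conv_channels1),
      bn1_beta = numeric(cf$conv_channels1),
      bn1_run_mean = numeric(cf$conv_channels1),
      bn1_run_var = rep(1, cf$conv_channels1),
      conv2_w = he_init(cf$conv_channels2, cf$conv_channels1 * 9L),
      conv2_b = numeric(cf$conv_channels2),
      bn2_gamma = rep(1, cf$conv_channels2),
      bn2_beta = numeric(cf$conv_channels2),
      bn2_run_mean = numeric(cf$conv_channels2),
      bn2_run_var = rep(1, cf$conv_channels2)
    )
    for (l in 1:2) {
      din <- if (l == 1) Ds else 2L * H
      for (d in c("fwd", "bwd")) {
        b <- numeric(4L * H)
        b[(H + 1L):(2L * H)] <- 1   # forget-gate bias
        p[[sprintf("lstm%d_%s_w", l, d)]] <- glorot(4L * H, din)
        p[[sprintf("lstm%d_%s_u", l, d)]] <- orth_blocks(H)
        p[[sprintf("lstm%d_%s_b", l, d)]] <- b
      }
    }
    p$proj_w <- glorot(D, 2L * H); p$proj_b <- numeric(D)
    for (nm in c("wq", "wk", "wv", "wo")) {
      p[[paste0("attn_", nm)]] <- glorot(D, D)
      p[[paste0("attn_b", substr(nm, 2, 2))]] <- numeric(D)
    }
    p$ln1_gamma <- rep(1, D); p$ln1_beta <- numeric(D)
    p$ln2_gamma <- rep(1, D); p$ln2_beta <- numeric(D)
    p$ff1_w <- he_init(cf$ff_dim, D); p$ff1_b <- numeric(cf$ff_dim)
    p$ff2_w <- glorot(D, cf$ff_dim); p$ff2_b <- numeric(D)
    p$fc_w <- he_init(cf$fc_units, D); p$fc_b <- numeric(cf$fc_units)
    p$head_em_w <- glorot(cf$n_emotions, cf$fc_units)
    p$head_em_b <- numeric(cf$n_emotions)
    p$head_tx_w <- glorot(cf$n_texts, cf$fc_units)
    p$head_tx_b <- numeric(cf$n_texts)
    p
  })
}

#' Build an (untrained) dual-head recognizer
#'
#' @param config A [recognizer_config()].
#' @param seed Seed for the weight initialization.
#' @return An object of class `throat_model`.
#' @export
build_model <- function(config = recognizer_config(), seed = 0L) {
  stopifnot(inherits(config, "recognizer_config"))
  structure(list(config = config,
                 params = init_recognizer_params(config, seed),
                 norm_mean = numeric(config$n_feature_rows),
                 norm_sd = rep(1, config$n_feature_rows),
                 training_log = NULL,
                 rng_seed = as.integer(seed)),
            class = "throat_model")
}

# Coerce features (feature_matrix / matrix / list / 3-d array) into the
# (F, T, N) array the C++ core expects.
features_to_array <- function(x, config) {
  F <- config$n_feature_rows; T <- config$n_frames
  if (inherits(x, "feature_matrix")) x <- x$values
  if (is.list(x)) {
    x <- lapply(x, function(v) if (inherits(v, "feature_matrix")) v$values else v)
    bad <- which(!vapply(x, function(v) all(dim(v) == c(F, T)), logical(1)))
    if (length(bad))
      stop("feature matrix ", bad[1], " has wrong shape; expected (",
           F, ", ", T, ")")
    x <- array(unlist(x), dim = c(F, T, length(x)))
  }
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L ||
      dim(x)[1] != F || dim(x)[2] != T)
    stop("features must be (", F, ", ", T, ", N); got ",
         paste(dim(x), collapse = "x"))
  x
}

normalize_batch <- function(x, model) {
  sweep(sweep(x, 1, model$norm_mean, `-`), 1, model$norm_sd, `/`)
}

#' Predict emotion and sentence probabilities
#'
#' Deterministic inference (dropout disabled, batch-norm running
#' statistics).
#'
#' @param model A `throat_model`.
#' @param features One 40 x 128 matrix, a list of them, or an
#'   (40, 128, N) array.
#' @return A `dual_prediction`: list with `emotion_probs` (N x 6) and
#'   `text_probs` (N x 5), rows summing to 1, plus hard labels.
#' @export
predict_model <- function(model, features) {
  stopifnot(inherits(model, "throat_model"))
  x <- normalize_batch(features_to_array(features, model$config),
                       model)
  out <- .nn_forward_cpp(model$params, model$config, x, FALSE, 0)
  em <- t(out$emotion_probs); tx <- t(out$text_probs)
  colnames(em) <- EMOTIONS
  colnames(tx) <- SENTENCE_TEXTS
  structure(list(emotion_probs = em, text_probs = tx,
                 emotion = EMOTIONS[max.col(em)],
                 sentence_id = max.col(tx) - 1L),
            class = "dual_prediction")
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

as_label_index <- function(y, levels, what) {
  if (is.numeric(y)) {
    y <- as.integer(y)
    if (any(y < 0L | y >= length(levels)))
      stop(what, " labels out of range 0..", length(levels) - 1L)
    return(y)
  }
  idx <- match(as.character(y), levels)
  if (anyNA(idx)) stop("unknown ", what, " label: ",
                       as.character(y)[which(is.na(idx))[1]])
  idx - 1L
}

#' Train the dual-head recognizer
#'
#' Minimizes the sum of the two cross-entropy losses with Adam, in
#' mini-batches, with early stopping on the validation loss; the
#' best-validation parameters are returned. Feature rows are z-scored
#' with statistics of the training set (stored in the model and applied
#' at prediction time).
#'
#' @param model A `throat_model` from [build_model()].
#' @param train_set,val_set Lists with `x` (features, see
#'   [predict_model()]), `y_emotion` (labels or 0-based indices) and
#'   `y_text` (sentence ids 0..4).
#' @param seed Seed controlling shuffling, dropout and initialization.
#' @param verbose Print one line per epoch.
#' @return The trained `throat_model` with `training_log`.
#' @export
train_model <- function(model, train_set, val_set, seed = 1L,
                        verbose = FALSE) {
  stopifnot(inherits(model, "throat_model"))
  cf <- model$config
  x_tr <- features_to_array(train_set$x, cf)
  x_va <- features_to_array(val_set$x, cf)
  n_tr <- dim(x_tr)[3]; n_va <- dim(x_va)[3]
  if (n_tr == 0L || n_va == 0L) stop("empty training or validation split")
  y_em_tr <- as_label_index(train_set$y_emotion, EMOTIONS, "emotion")
  y_tx_tr <- as_label_index(train_set$y_text, as.character(0:4), "text")
  y_em_va <- as_label_index(val_set$y_emotion, EMOTIONS, "emotion")
  y_tx_va <- as_label_index(val_set$y_text, as.character(0:4), "text")

  # feature-row normalization from the training set
  model$norm_mean <- apply(x_tr, 1, mean)
  model$norm_sd <- pmax(apply(x_tr, 1, stats::sd), 1e-6)
  model$rng_seed <- as.integer(seed)
  model$params <- init_recognizer_params(cf, seed)
  x_tr <- normalize_batch(x_tr, model)
  x_va <- normalize_batch(x_va, model)

  params <- model$params
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  # running-statistic entries carry no gradient
  state$m[c("bn1_run_mean", "bn1_run_var",
            "bn2_run_mean", "bn2_run_var")] <- NULL

  best <- list(loss = Inf, params = params, epoch = 0L)
  log_rows <- list()
  wait <- 0L

  eval_split <- function(params, x, y_em, y_tx) {
    out <- .nn_forward_cpp(params, cf, x, FALSE, 0)
    p_em <- out$emotion_probs; p_tx <- out$text_probs
    n <- ncol(p_em)
    idx <- cbind(y_em + 1L, seq_len(n))
    loss <- mean(-log(pmax(p_em[idx], 1e-12))) +
      mean(-log(pmax(p_tx[cbind(y_tx + 1L, seq_len(n))], 1e-12)))
    acc_em <- mean(max.col(t(p_em)) - 1L == y_em)
    acc_tx <- mean(max.col(t(p_tx)) - 1L == y_tx)
    list(loss = loss, acc_em = acc_em, acc_tx = acc_tx)
  }

  for (epoch in seq_len(cf$max_epochs)) {
    ord <- with_seed(seed + epoch * 131L, sample.int(n_tr))
    nb <- ceiling(n_tr / cf$batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      sel <- ord[((b - 1L) * cf$batch_size + 1L):min(b * cf$batch_size, n_tr)]
      res <- .nn_loss_grad_cpp(params, cf,
                               x_tr[, , sel, drop = FALSE],
                               y_em_tr[sel], y_tx_tr[sel],
                               seed * 1e4 + epoch * 100 + b)
      grads <- res$grads
      # guard against a pathological step
      if (!is.finite(res$loss))
        stop("non-finite training loss at epoch ", epoch, ", batch ", b)
      # global gradient-norm clipping stabilizes the recurrent stack
      gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
      if (is.finite(gnorm) && gnorm > cf$max_grad_norm)
        grads <- lapply(grads, `*`, cf$max_grad_norm / gnorm)
      upd <- adam_step(params, grads, state, cf$learning_rate)
      params <- upd$params; state <- upd$state
      for (nm in names(res$bn_running)) params[[nm]] <- res$bn_running[[nm]]
      ep_loss <- ep_loss + res$loss * length(sel)
    }
    ep_loss <- ep_loss / n_tr
    va <- eval_split(params, x_va, y_em_va, y_tx_va)
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, train_loss = ep_loss, val_loss = va$loss,
      val_acc_emotion = va$acc_em, val_acc_text = va$acc_tx)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f/%.3f",
                      epoch, ep_loss, va$loss, va$acc_em, va$acc_tx))
    if (va$loss < best$loss - 1e-6) {
      best <- list(loss = va$loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cf$patience) break
    }
  }
  model$params <- best$params
  model$training_log <- do.call(rbind, log_rows)
  model$best_epoch <- best$epoch
  model
}

#' Save / load a trained model
#'
#' The checkpoint is a single RDS archive embedding the configuration,
#' weights and normalization statistics.
#'
#' @param model A `throat_model`.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "throat_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "throat_model"))
  model
}
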