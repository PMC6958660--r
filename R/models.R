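# Classifier models: GRU (proposed), LSTM, FCN, and their training regime.
#
# The recurrent cells follow the screening model's printed conventions:
# the GRU update gate z multiplies the PREVIOUS hidden state
# (h = z*h_prev + (1-z)*h_tilde), and the LSTM cell candidate is squashed by
# the sigmoid by default (a tanh variant is available via
# `lstm_candidate = "tanh"`). Training minimizes softmax cross-entropy plus
# lambda * sum of squared weight matrices (biases excluded) with Adam.

#' Numerically stable softmax
#'
#' Exponential normalization with max-subtraction, so adding a constant to
#' all scores leaves the output unchanged and large scores cannot overflow.
#' @param scores Numeric vector, or matrix with one score row per case.
#' @return Probabilities of the same shape; each vector/row sums to 1.
#' @export
softmax <- function(scores) {
  if (is.matrix(scores)) {
    z <- scores - apply(scores, 1, max)
    e <- exp(z)
    return(e / rowSums(e))
  }
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' One GRU time step
#'
#' z = sigmoid(bz + Uz x + Wz h_prev); r = sigmoid(br + Ur x + Wr h_prev);
#' h_tilde = tanh(bh + Uh x + Wh (r * h_prev));
#' h = z * h_prev + (1 - z) * h_tilde.
#'
#' @param x_t Input vector (or matrix with one column per batch case).
#' @param h_prev Previous hidden state, same column layout.
#' @param params Named list `Uz, Ur, Uh, Wz, Wr, Wh, bz, br, bh`.
#' @return Hidden state of the same shape as `h_prev`.
#' @export
gru_step <- function(x_t, h_prev, params) {
  x_t <- as.matrix(x_t); h_prev <- as.matrix(h_prev)
  check_dims(params$Uz, x_t, params$Wz, h_prev)
  drop_if_vec(gru_step_cpp(x_t, h_prev, params))
}

#' One LSTM time step
#'
#' Gates g (input), f (forget), o (output) are sigmoids of affine maps of
#' (x, h_prev); the cell state is s = f * s_prev + g * act(bc + Uc x + Wc
#' h_prev) with act = sigmoid by default; h = tanh(s) * o.
#'
#' @param x_t,h_prev,s_prev Input, previous hidden and cell state (vectors or
#'   one-column-per-case matrices).
#' @param params Named list `Ug, Uf, Uo, Uc, Wg, Wf, Wo, Wc, bg, bf, bo, bc`.
#' @param candidate `"sigmoid"` (default, the screening model's printed form)
#'   or `"tanh"` (the common variant).
#' @return List with `h` and `s`.
#' @export
lstm_step <- function(x_t, h_prev, s_prev, params, candidate = c("sigmoid", "tanh")) {
  candidate <- match.arg(candidate)
  x_t <- as.matrix(x_t); h_prev <- as.matrix(h_prev); s_prev <- as.matrix(s_prev)
  check_dims(params$Ug, x_t, params$Wg, h_prev)
  out <- lstm_step_cpp(x_t, h_prev, s_prev, params, candidate == "tanh")
  list(h = drop_if_vec(out$h), s = drop_if_vec(out$s))
}

check_dims <- function(U, x, W, h) {
  if (ncol(U) != nrow(x))
    stopf("input dimension mismatch: U has %d columns, x has %d rows",
          ncol(U), nrow(x))
  if (ncol(W) != nrow(h))
    stopf("hidden dimension mismatch: W has %d columns, h has %d rows",
          ncol(W), nrow(h))
}

drop_if_vec <- function(m) if (ncol(m) == 1) drop(m) else m

# Uniform fan-in-scaled initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
init_mat <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(nc), nr, nc)
}

init_rnn_layer <- function(type, in_dim, hidden) {
  gates <- if (type == "gru") c("z", "r", "h") else c("g", "f", "o", "c")
  p <- list()
  for (g in gates) {
    p[[paste0("U", g)]] <- init_mat(hidden, in_dim)
    p[[paste0("W", g)]] <- init_mat(hidden, hidden)
    p[[paste0("b", g)]] <- numeric(hidden)
  }
  p
}

#' Training configuration
#'
#' Defaults are the screening model's regime: Adam with learning rate 0.001,
#' softmax cross-entropy loss with L2 weight decay lambda = 0.0001, batch
#' size 64, 50 epochs; 2 layers of 64 units for the recurrent models.
#'
#' @param learning_rate,l2_lambda,batch_size,epochs Optimization settings.
#' @param n_layers Number of recurrent layers (1-3).
#' @param units Hidden units per layer (8/16/32/64/128 in the sweep grid).
#' @param input_chunk Samples consumed per timestep; 1 (default) feeds one
#'   scalar sample per step, larger values chunk the frame for speed.
#' @param lstm_candidate LSTM cell-candidate squashing, `"sigmoid"` or `"tanh"`.
#' @param rng_seed Seed for initialization and batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, l2_lambda = 1e-4,
                         batch_size = 64L, epochs = 50L, n_layers = 2L,
                         units = 64L, input_chunk = 1L,
                         lstm_candidate = "sigmoid", rng_seed = 1L) {
  stopifnot(learning_rate > 0, l2_lambda >= 0, batch_size >= 1, epochs >= 1,
            n_layers >= 1, units >= 1, input_chunk >= 1)
  structure(list(learning_rate = learning_rate, l2_lambda = l2_lambda,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 n_layers = as.integer(n_layers), units = as.integer(units),
                 input_chunk = as.integer(input_chunk),
                 lstm_candidate = lstm_candidate,
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Build a classifier model
#'
#' `"gru"` / `"lstm"`: `n_layers` stacked recurrent layers (each layer feeds
#' the next at every timestep) whose final hidden state goes through a fully
#' connected 3-unit softmax head. `"fcn"`: three convolutional blocks with
#' 128/256/128 filters and kernel sizes 8/5/3 ("same" padding, stride 1),
#' each followed by batch normalization and ReLU, then global average
#' pooling and the softmax head.
#'
#' @param name `"gru"`, `"lstm"` or `"fcn"`.
#' @param config A [train_config()].
#' @param n_class Number of output classes (3).
#' @return An untrained `pcg_model`.
#' @export
build_model <- function(name = c("gru", "lstm", "fcn"), config = train_config(),
                        n_class = 3L) {
  name <- match.arg(name)
  with_seed(config$rng_seed, {
    if (name %in% c("gru", "lstm")) {
      in_dim <- config$input_chunk
      layers <- vector("list", config$n_layers)
      for (l in seq_len(config$n_layers)) {
        layers[[l]] <- init_rnn_layer(name, if (l == 1) in_dim else config$units,
                                      config$units)
      }
      params <- list(layers = layers,
                     V = init_mat(n_class, config$units), c = numeric(n_class))
    } else {
      filters <- c(128L, 256L, 128L); kernels <- c(8L, 5L, 3L)
      blocks <- vector("list", 3)
      cin <- 1L
      for (b in 1:3) {
        blocks[[b]] <- list(W = init_mat(kernels[b] * cin, filters[b]),
                            gamma = rep(1, filters[b]), beta = numeric(filters[b]),
                            run_mean = numeric(filters[b]),
                            run_var = rep(1, filters[b]), kernel = kernels[b])
        cin <- filters[b]
      }
      params <- list(blocks = blocks, V = init_mat(n_class, 128L),
                     c = numeric(n_class))
    }
    structure(list(type = name, params = params, config = config,
                   n_class = as.integer(n_class), trained = FALSE,
                   history = NULL),
              class = c(paste0("pcg_", name), "pcg_model"))
  })
}

#' @export
print.pcg_model <- function(x, ...) {
  cat(sprintf("<pcg_model %s> %s%s\n", x$type,
              if (x$type == "fcn") "3 conv blocks 128/256/128 (k 8/5/3)"
              else sprintf("%d layer(s) x %d units", x$config$n_layers,
                           x$config$units),
              if (x$trained) ", trained" else ", untrained"))
  invisible(x)
}

# ---- Adam over nested parameter lists --------------------------------------

map2_params <- function(a, b, f) {
  if (is.list(a)) {
    nm <- names(a)
    if (!is.null(nm) && !is.null(names(b)) && all(nm %in% names(b)))
      b <- b[nm]                     # align by name; orders may differ
    return(mapply(map2_params, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE))
  }
  f(a, b)
}

zeros_like <- function(p) {
  if (is.list(p)) return(lapply(p, zeros_like))
  p * 0
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  mhat_scale <- 1 / (1 - beta1^t)
  vhat_scale <- 1 / (1 - beta2^t)
  upd <- map2_params(state$m, state$v, function(m, v)
    lr * (m * mhat_scale) / (sqrt(v * vhat_scale) + eps))
  params <- map2_params(params, upd, `-`)
  list(params = params, state = state)
}

# ---- generic loss/grad dispatch --------------------------------------------

model_loss_grad <- function(model, xb, yb, want_grads = TRUE) {
  cfg <- model$config
  if (model$type %in% c("gru", "lstm")) {
    out <- rnn_batch_cpp(xb, as.integer(yb), model$params$layers,
                         model$params$V, model$params$c, model$type,
                         cfg$input_chunk, cfg$l2_lambda,
                         identical(cfg$lstm_candidate, "tanh"), want_grads)
    if (want_grads)
      out$grads <- list(layers = out$grad_layers, V = out$grad_V,
                        c = as.numeric(out$grad_c))
    out
  } else {
    fcn_loss_grad(model, xb, yb, want_grads)
  }
}

#' Train a classifier
#'
#' Mini-batch Adam on softmax cross-entropy + lambda * sum(weights^2), with
#' seeded shuffling each epoch; per-epoch training loss and validation
#' accuracy are recorded. No early stopping: the model trains for the full
#' epoch budget and validation metrics are monitoring only.
#'
#' @param model An untrained model from [build_model()].
#' @param x_train,y_train Training frames (matrix, one frame per row) and
#'   integer labels in 1..3.
#' @param x_val,y_val Optional validation split (disjoint from training).
#' @param verbose Print per-epoch progress.
#' @return The trained model, with `$history` (per-epoch loss and accuracy).
#' @export
train_model <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                        verbose = FALSE) {
  if (!nrow(x_train)) stopf("empty training set")
  if (any(!y_train %in% seq_len(model$n_class)))
    stopf("labels must be integers in 1..%d", model$n_class)
  cfg <- model$config
  state <- list(m = zeros_like(model$params), v = zeros_like(model$params))
  n <- nrow(x_train)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_accuracy = numeric(0))
  tstep <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$rng_seed, epoch), sample.int(n))
    losses <- numeric(0)
    for (i0 in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[i0:min(i0 + cfg$batch_size - 1, n)]
      out <- model_loss_grad(model, x_train[idx, , drop = FALSE], y_train[idx])
      if (!is.null(out$updated_blocks))        # BN running statistics
        model$params$blocks <- out$updated_blocks
      tstep <- tstep + 1L
      upd <- adam_update(model$params, out$grads, state, cfg$learning_rate, tstep)
      model$params <- upd$params
      state <- upd$state
      losses <- c(losses, out$loss)
    }
    val_acc <- NA_real_
    if (!is.null(x_val) && nrow(x_val)) {
      pr <- predict_frames(model, x_val)
      val_acc <- mean(pr$labels == y_val)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = mean(losses),
                                   val_accuracy = val_acc))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f val acc %s", epoch, mean(losses),
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
  }
  model$trained <- TRUE
  model$input_len <- ncol(x_train)
  model$history <- hist
  model
}

#' Predict class probabilities and labels for frames
#'
#' Deterministic given the model weights; probability rows sum to 1.
#' @param model A `pcg_model`.
#' @param x Matrix of frames (one per row), same length as training frames.
#' @return List with `probs` (n x 3) and `labels` (argmax, ties to the
#'   lowest class index).
#' @export
predict_frames <- function(model, x) {
  if (!is.null(model$input_len) && ncol(x) != model$input_len)
    stopf("frame length mismatch: expected %d samples, got %d",
          model$input_len, ncol(x))
  if (model$type %in% c("gru", "lstm")) {
    if (ncol(x) %% model$config$input_chunk != 0)
      stopf("frame length %d is not a multiple of input chunk %d",
            ncol(x), model$config$input_chunk)
  }
  bs <- if (model$type == "fcn") 16L else 64L
  probs <- matrix(NA_real_, nrow(x), model$n_class)
  for (i0 in seq(1, nrow(x), by = bs)) {
    idx <- i0:min(i0 + bs - 1, nrow(x))
    out <- model_loss_grad(model, x[idx, , drop = FALSE],
                           rep(1L, length(idx)), want_grads = FALSE)
    probs[idx, ] <- out$probs
  }
  list(probs = probs, labels = max.col(probs, ties.method = "first"))
}

# Sum of squared weight matrices (biases and BN parameters excluded);
# the quantity penalized by the L2 term.
model_weight_norm <- function(model) {
  tot <- 0
  acc <- function(p) {
    for (nm in names(p)) {
      v <- p[[nm]]
      if (is.list(v)) acc(v)
      else if (is.matrix(v) && grepl("^[UWV]", nm)) tot <<- tot + sum(v^2)
    }
  }
  if (model$type == "fcn") {
    for (b in model$params$blocks) tot <- tot + sum(b$W^2)
    tot <- tot + sum(model$params$V^2)
  } else {
    for (l in model$params$layers) acc(l)
    tot <- tot + sum(model$params$V^2)
  }
  tot
}
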