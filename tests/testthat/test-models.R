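# GRU/LSTM cells, softmax, model building, training.

test_that("gru_step matches the equation-level reference on random instances", {
  pcgscreen:::with_seed(101, {
    worst <- 0
    for (i in 1:100) {
      p <- rand_params("gru", 2, 3)
      x <- stats::rnorm(2); h <- stats::rnorm(3)
      worst <- max(worst, max(abs(gru_step(x, h, p) - ref_gru_step(x, h, p))))
    }
    expect_lt(worst, 1e-12)
  })
})

test_that("lstm_step matches the equation-level reference, both candidates", {
  pcgscreen:::with_seed(102, {
    worst_sig <- 0; worst_tanh <- 0
    for (i in 1:100) {
      p <- rand_params("lstm", 2, 3)
      x <- stats::rnorm(2); h <- stats::rnorm(3); s <- stats::rnorm(3)
      got <- lstm_step(x, h, s, p)
      ref <- ref_lstm_step(x, h, s, p)
      worst_sig <- max(worst_sig, abs(got$h - ref$h), abs(got$s - ref$s))
      got2 <- lstm_step(x, h, s, p, candidate = "tanh")
      ref2 <- ref_lstm_step(x, h, s, p, cand = tanh)
      worst_tanh <- max(worst_tanh, abs(got2$h - ref2$h), abs(got2$s - ref2$s))
    }
    expect_lt(worst_sig, 1e-12)
    expect_lt(worst_tanh, 1e-12)
  })
})

test_that("gate limits force the printed cell identities", {
  pcgscreen:::with_seed(103, {
    p <- rand_params("gru", 2, 3)
    x <- stats::rnorm(2); h <- stats::rnorm(3)
    # z = 1 (huge bz, no input/hidden contribution): h_t = h_prev
    p1 <- p; p1$bz <- rep(50, 3); p1$Uz[] <- 0; p1$Wz[] <- 0
    expect_equal(gru_step(x, h, p1), h, tolerance = 1e-12)
    # z = 0, r = 0: h_t = tanh(bh + Uh x)
    p0 <- p; p0$bz <- rep(-50, 3); p0$Uz[] <- 0; p0$Wz[] <- 0
    p0$br <- rep(-50, 3); p0$Ur[] <- 0; p0$Wr[] <- 0
    expect_equal(gru_step(x, h, p0), as.numeric(tanh(p0$bh + p0$Uh %*% x)),
                 tolerance = 1e-12)
    # LSTM: f = 1, g = 0 keeps the cell state; o = 0 silences the output
    q <- rand_params("lstm", 2, 3)
    s <- stats::rnorm(3)
    q1 <- q; q1$bf <- rep(50, 3); q1$Uf[] <- 0; q1$Wf[] <- 0
    q1$bg <- rep(-50, 3); q1$Ug[] <- 0; q1$Wg[] <- 0
    expect_equal(lstm_step(x, h, s, q1)$s, s, tolerance = 1e-12)
    q2 <- q; q2$bo <- rep(-50, 3); q2$Uo[] <- 0; q2$Wo[] <- 0
    expect_equal(lstm_step(x, h, s, q2)$h, rep(0, 3), tolerance = 1e-12)
  })
})

test_that("softmax is normalized, shift-invariant, and overflow-safe", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  pcgscreen:::with_seed(104, {
    for (i in 1:20) {
      sc <- stats::rnorm(3, sd = 5)
      p <- softmax(sc)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_equal(softmax(sc + 123.4), p, tolerance = 1e-12)
    }
  })
  p <- softmax(c(1000, 0, 0))
  expect_true(all(is.finite(p)))
  expect_gt(p[1], 0.999)
  m <- softmax(matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE))
  expect_equal(rowSums(m), c(1, 1))
})

test_that("GRU hidden state stays in [-1, 1] from zero initialization", {
  pcgscreen:::with_seed(105, {
    p <- rand_params("gru", 1, 4)
    h <- rep(0, 4)
    for (t in 1:200) {
      h <- gru_step(stats::rnorm(1, sd = 3), h, p)
      expect_true(all(h >= -1 & h <= 1))
    }
  })
})

test_that("models build with the screening architecture and predict simplexes", {
  cfg <- train_config(n_layers = 2, units = 8, rng_seed = 1, input_chunk = 8)
  for (type in c("gru", "lstm", "fcn")) {
    m <- build_model(type, cfg)
    expect_equal(m$n_class, 3L)
    expect_equal(nrow(m$params$V), 3)          # 3-unit softmax head
    x <- matrix(stats::rnorm(4 * 96), 4, 96)
    pr <- predict_frames(m, x)
    expect_equal(rowSums(pr$probs), rep(1, 4), tolerance = 1e-6)
    # both frame lengths run without re-architecture
    x2 <- matrix(stats::rnorm(4 * 48), 4, 48)
    pr2 <- predict_frames(m, x2)
    expect_equal(dim(pr2$probs), c(4L, 3L))
  }
  # smallest sweep grid point builds and runs
  m1 <- build_model("gru", train_config(n_layers = 1, units = 8, rng_seed = 2))
  pr <- predict_frames(m1, matrix(stats::rnorm(2 * 960), 2, 960))
  expect_equal(dim(pr$probs), c(2L, 3L))
  expect_error(build_model("mlp"), "arg")
})

test_that("initial loss on balanced classes is near ln 3 and runs reproduce", {
  d <- tiny_separable_frames()
  cfg <- train_config(epochs = 1, batch_size = 64, rng_seed = 11, input_chunk = 8)
  m1 <- train_model(build_model("gru", cfg), d$x, d$y)
  m2 <- train_model(build_model("gru", cfg), d$x, d$y)
  expect_equal(m1$history$train_loss[1], log(3), tolerance = 0.2)
  expect_identical(m1$history$train_loss[1], m2$history$train_loss[1])
})

test_that("training reaches 100% on separable frames within 50 epochs", {
  d <- tiny_separable_frames()
  cfg <- train_config(epochs = 50, batch_size = 16, rng_seed = 12,
                      input_chunk = 8)
  m <- train_model(build_model("gru", cfg), d$x, d$y)
  pr <- predict_frames(m, d$x)
  expect_equal(mean(pr$labels == d$y), 1)
  # deterministic prediction
  expect_identical(pr$probs, predict_frames(m, d$x)$probs)
})

test_that("L2 decay shrinks trained weight norms", {
  d <- tiny_separable_frames()
  fit <- function(lam) {
    cfg <- train_config(epochs = 30, batch_size = 16, l2_lambda = lam,
                        rng_seed = 13, input_chunk = 8)
    pcgscreen:::model_weight_norm(train_model(build_model("gru", cfg), d$x, d$y))
  }
  expect_lt(fit(1e-2), fit(0))
})

test_that("training validates inputs", {
  d <- tiny_separable_frames(n_per_class = 2)
  cfg <- train_config(epochs = 1, rng_seed = 1)
  m <- build_model("gru", cfg)
  expect_error(train_model(m, d$x[0, , drop = FALSE], integer(0)), "empty")
  expect_error(train_model(m, d$x, rep(7L, nrow(d$x))), "labels")
  mt <- train_model(build_model("gru", train_config(epochs = 1, rng_seed = 1,
                                                    input_chunk = 8)),
                    d$x, d$y)
  expect_error(predict_frames(mt, d$x[, 1:32]), "length mismatch")
})
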