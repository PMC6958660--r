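# Cross-validation harness and metrics.

test_that("cv plans partition frames and hold out 20% for validation", {
  ds <- fixture_dataset()
  plan <- make_cv_plan(ds, k = 10, seed = 4)
  all_test <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  expect_equal(all_test, seq_len(nrow(ds$x)))
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$validation, f$test), 0)
    expect_length(intersect(f$train, f$validation), 0)
    n_train_all <- length(f$train) + length(f$validation)
    expect_equal(length(f$validation) / n_train_all, 0.2, tolerance = 0.03)
    # 90/10 split up to stratification rounding
    expect_equal(n_train_all / nrow(ds$x), 0.9, tolerance = 0.02)
  }
  expect_silent(pcgscreen:::assert_no_leakage(plan))
})

test_that("stratified plans balance class counts across test folds", {
  ds <- list(x = matrix(0, 900, 4), y = rep(1:3, each = 300),
             meta = data.frame(recording_id = rep("r", 900)))
  class(ds) <- "frame_dataset"
  plan <- make_cv_plan(ds, k = 10, seed = 1)
  for (f in plan$folds) {
    expect_length(f$test, 90)
    expect_equal(as.vector(table(ds$y[f$test])), c(30, 30, 30))
  }
  expect_error(make_cv_plan(ds, k = 1000, seed = 1), "exceeds")
})

test_that("recording-level grouping keeps recordings within one fold", {
  ds <- fixture_dataset()
  plan <- make_cv_plan(ds, k = 3, seed = 2, grouping = "recording")
  for (f in plan$folds) {
    test_ids <- unique(ds$meta$recording_id[f$test])
    other_ids <- unique(ds$meta$recording_id[c(f$train, f$validation)])
    expect_length(intersect(test_ids, other_ids), 0)
  }
})

test_that("stub predictors produce the forced confusion matrices", {
  ds <- fixture_dataset()
  plan <- make_cv_plan(ds, k = 5, seed = 3)
  oracle <- evaluate_model("stub", ds, plan,
                           predictor = function(tr, te) ds$y[te])
  expect_equal(oracle$mean_accuracy, 1)
  expect_equal(unname(diag(oracle$confusion)),
               unname(as.vector(ds$class_counts)))
  expect_equal(sum(oracle$confusion) - sum(diag(oracle$confusion)), 0)
  always1 <- evaluate_model("stub", ds, plan,
                            predictor = function(tr, te) rep(1L, length(te)))
  expect_equal(unname(always1$recall), c(1, 0, 0))
  expect_equal(always1$pooled_accuracy,
               unname(ds$class_counts[1] / sum(ds$class_counts)))
})

test_that("confusion-matrix identities hold exactly", {
  ds <- fixture_dataset()
  plan <- make_cv_plan(ds, k = 5, seed = 6)
  # a deliberately noisy stub: flips ~30% of labels deterministically
  noisy <- function(tr, te) {
    y <- ds$y[te]
    flip <- (seq_along(te) %% 3) == 0
    y[flip] <- (y[flip] %% 3) + 1L
    y
  }
  rep_ <- evaluate_model("stub", ds, plan, predictor = noisy)
  cm <- rep_$confusion
  expect_equal(unname(rowSums(cm)), unname(as.vector(ds$class_counts)))
  expect_equal(sum(diag(cm)) / sum(cm), rep_$pooled_accuracy)
  expect_equal(rep_$precision, diag(cm) / colSums(cm))
  expect_equal(rep_$recall, diag(cm) / rowSums(cm))
  expect_equal(rep_$mean_accuracy, mean(rep_$fold_accuracy), tolerance = 1e-12)
  expect_equal(rep_$sd_accuracy, stats::sd(rep_$fold_accuracy), tolerance = 1e-12)
})

test_that("a degenerate sweep grid reproduces evaluate_model's accuracy", {
  d <- tiny_separable_frames(n_per_class = 15)
  ds <- structure(list(x = d$x, y = d$y,
                       meta = data.frame(recording_id = rep("r", length(d$y))),
                       frame_length_s = NA, target_rate_hz = NA,
                       class_counts = table(d$y)), class = "frame_dataset")
  cfg <- train_config(epochs = 5, batch_size = 16, rng_seed = 7, input_chunk = 8)
  tab <- sweep_architecture("gru", ds, layer_grid = 1, unit_grid = 8,
                            config = cfg, k = 3, seed = 8)
  expect_equal(nrow(tab), 1)
  plan <- make_cv_plan(ds, k = 3, seed = 8)
  cfg$n_layers <- 1L; cfg$units <- 8L
  direct <- evaluate_model("gru", ds, plan, cfg)
  expect_equal(tab$mean_accuracy, direct$mean_accuracy)
  expect_true(all(tab$mean_accuracy >= 0 & tab$mean_accuracy <= 1))
  expect_error(sweep_architecture("gru", ds, layer_grid = integer(0)),
               "non-empty")
})

test_that("compare_frame_lengths pairs folds and zeroes out on identical inputs", {
  base <- synth_config(n_cycles = 10, snr_db = 25, rng_seed = 19)
  recs <- generate_dataset(c(normal = 3, HFpEF = 3, HFrEF = 3), base)
  cfg <- train_config(epochs = 2, batch_size = 32, rng_seed = 9, input_chunk = 16)
  cmp <- compare_frame_lengths(recs, "gru", frame_lengths_s = c(0.8, 0.8),
                               config = cfg, k = 3, seed = 10)
  expect_equal(cmp$mean_difference, 0)
  expect_equal(nrow(cmp$paired), 3)
  expect_equal(cmp$paired[[2]], cmp$paired[[3]])
})
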