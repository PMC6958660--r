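# Tenfold cross-validation harness, metrics and sweeps.
#
# Default splitting is frame-level and stratified by class (the screening
# protocol splits frames, not subjects). Frame-level splitting can leak
# recording identity between train and test; a grouping = "recording" mode
# assigns whole recordings to folds to avoid that, at the cost of less even
# fold sizes. Within each fold, a stratified 20% of the training frames is
# held out for validation monitoring.

#' Build a cross-validation plan
#'
#' @param dataset A `frame_dataset` (or plain integer count of frames when
#'   `grouping = "frame"` and `stratified = FALSE`).
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment and validation sampling.
#' @param stratified Balance class counts across folds (+/- 1 per class).
#' @param grouping `"frame"` (default) or `"recording"` (all frames of a
#'   recording share a fold).
#' @param validation_fraction Fraction of each fold's training frames held
#'   out for validation (default 0.2), sampled stratified by class.
#' @return A `cv_plan`: `fold` (per-frame assignment 1..k) and per-fold
#'   index sets `train`, `validation`, `test` (pairwise disjoint; the k test
#'   sets partition all frames).
#' @export
make_cv_plan <- function(dataset, k = 10, seed = 1L, stratified = TRUE,
                         grouping = c("frame", "recording"),
                         validation_fraction = 0.2) {
  grouping <- match.arg(grouping)
  n <- if (is.numeric(dataset) && length(dataset) == 1) as.integer(dataset)
       else nrow(dataset$x)
  if (k > n) stopf("k = %d exceeds the %d available frames", k, n)
  fold <- integer(n)
  if (grouping == "recording") {
    rid <- dataset$meta$recording_id
    ids <- unique(rid)
    if (k > length(ids)) stopf("k = %d exceeds the %d recordings", k, length(ids))
    rf <- with_seed(derive_seed(seed, "folds"), sample(rep_len(1:k, length(ids))))
    fold <- rf[match(rid, ids)]
  } else if (stratified && !is.numeric(dataset)) {
    with_seed(derive_seed(seed, "folds"), {
      for (cl in unique(dataset$y)) {
        idx <- which(dataset$y == cl)
        fold[idx] <- sample(rep_len(1:k, length(idx)))
      }
    })
  } else {
    fold <- with_seed(derive_seed(seed, "folds"), sample(rep_len(1:k, n)))
  }
  y <- if (is.numeric(dataset)) rep(1L, n) else dataset$y
  folds <- lapply(1:k, function(j) {
    test <- which(fold == j)
    train_all <- setdiff(seq_len(n), test)
    val <- integer(0)
    with_seed(derive_seed(seed, paste0("val", j)), {
      for (cl in unique(y[train_all])) {
        idx <- train_all[y[train_all] == cl]
        n_val <- round(validation_fraction * length(idx))
        if (n_val > 0) val <- c(val, sample(idx, n_val))
      }
    })
    list(train = setdiff(train_all, val), validation = sort(val), test = test)
  })
  structure(list(fold = fold, folds = folds, k = k, seed = seed,
                 stratified = stratified, grouping = grouping,
                 validation_fraction = validation_fraction),
            class = "cv_plan")
}

assert_no_leakage <- function(plan) {
  for (f in plan$folds) {
    if (length(intersect(f$train, f$test)) || length(intersect(f$validation, f$test)) ||
        length(intersect(f$train, f$validation)))
      stopf("cross-validation leakage: overlapping train/validation/test sets")
  }
  all_test <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  if (!identical(all_test, seq_along(plan$fold)))
    stopf("test sets do not partition the frames")
  invisible(TRUE)
}

new_cv_report <- function(model_name, fold_acc, confusion, manifest = list()) {
  diag_ <- diag(confusion)
  precision <- diag_ / pmax(colSums(confusion), 1)
  recall <- diag_ / pmax(rowSums(confusion), 1)
  structure(list(
    model_name = model_name, fold_accuracy = fold_acc,
    mean_accuracy = mean(fold_acc),
    sd_accuracy = stats::sd(fold_acc),        # n - 1 denominator
    confusion = confusion, precision = precision, recall = recall,
    pooled_accuracy = sum(diag_) / sum(confusion), manifest = manifest
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report %s> mean accuracy %.2f%% +/- %.2f%% over %d folds\n",
              x$model_name, 100 * x$mean_accuracy, 100 * x$sd_accuracy,
              length(x$fold_accuracy)))
  cat("pooled confusion matrix (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Cross-validated evaluation of a classifier
#'
#' Per fold: fit on the training frames (validation split for monitoring),
#' predict the test frames, and accumulate the pooled confusion matrix
#' (rows = true classes, columns = predicted). Precision is the column-wise
#' and recall the row-wise diagonal fraction; the reported mean +/- sd is
#' over per-fold accuracies.
#'
#' @param model_name `"gru"`, `"lstm"`, `"fcn"` or `"svm"`.
#' @param dataset A `frame_dataset`.
#' @param plan A [make_cv_plan()] consistent with `dataset`.
#' @param config A [train_config()] (ignored for `"svm"`).
#' @param alpha Feature-screening threshold for the SVM path.
#' @param predictor Optional function(train_idx, test_idx) -> integer labels,
#'   replacing model fitting (used for harness checks).
#' @param verbose Print per-fold progress.
#' @return A `cv_report`.
#' @export
evaluate_model <- function(model_name, dataset, plan, config = train_config(),
                           alpha = 0.001, predictor = NULL, verbose = FALSE) {
  assert_no_leakage(plan)
  if (length(plan$fold) != nrow(dataset$x))
    stopf("plan covers %d frames but dataset has %d", length(plan$fold),
          nrow(dataset$x))
  n_class <- 3L
  confusion <- matrix(0L, n_class, n_class,
                      dimnames = list(true = PCG_CLASSES, predicted = PCG_CLASSES))
  fold_acc <- numeric(plan$k)
  feats <- if (identical(model_name, "svm") && is.null(predictor))
    extract_features(dataset) else NULL
  for (j in seq_len(plan$k)) {
    f <- plan$folds[[j]]
    if (length(unique(dataset$y[f$test])) < n_class && verbose)
      message(sprintf("fold %d: some class missing from its test set", j))
    pred <- if (!is.null(predictor)) {
      predictor(c(f$train, f$validation), f$test)
    } else if (identical(model_name, "svm")) {
      tr <- feats[c(f$train, f$validation), ]     # selection on training rows only
      rep_sel <- tamhane_t2_select(tr, alpha = alpha)
      if (!length(rep_sel$selected))
        rep_sel$selected <- "energy"              # degenerate screen: fall back, logged
      svm_fit <- train_svm(tr, rep_sel$selected,
                           seed = derive_seed(plan$seed, paste0("svm", j)))
      predict_svm(svm_fit, feats[f$test, ])
    } else {
      cfg <- config
      cfg$rng_seed <- derive_seed(config$rng_seed, paste0("fold", j))
      model <- build_model(model_name, cfg)
      model <- train_model(model, dataset$x[f$train, , drop = FALSE],
                           dataset$y[f$train],
                           dataset$x[f$validation, , drop = FALSE],
                           dataset$y[f$validation])
      predict_frames(model, dataset$x[f$test, , drop = FALSE])$labels
    }
    truth <- dataset$y[f$test]
    fold_acc[j] <- mean(pred == truth)
    for (i in seq_along(truth))
      confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.3f", j, plan$k, fold_acc[j]))
  }
  new_cv_report(model_name, fold_acc, confusion,
                manifest = list(k = plan$k, seed = plan$seed,
                                grouping = plan$grouping,
                                stratified = plan$stratified,
                                epochs = config$epochs,
                                n_layers = config$n_layers,
                                units = config$units))
}

#' Hyperparameter sweep over layers and units
#'
#' One cross-validated accuracy per grid point, over the layer/unit grid of
#' the model-setting experiments ({1,2,3} layers x {8,16,32,64,128} units).
#'
#' @param model_name `"gru"` or `"lstm"`.
#' @param dataset A `frame_dataset`.
#' @param layer_grid,unit_grid Grids to sweep.
#' @param config Base [train_config()].
#' @param k Folds per grid point.
#' @param seed Seed shared across grid points.
#' @return Data frame with columns `n_layers`, `units`, `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
sweep_architecture <- function(model_name, dataset, layer_grid = 1:3,
                               unit_grid = c(8, 16, 32, 64, 128),
                               config = train_config(), k = 10, seed = 1L) {
  if (!length(layer_grid) || !length(unit_grid)) stopf("grids must be non-empty")
  plan <- make_cv_plan(dataset, k = k, seed = seed)
  out <- list()
  for (nl in layer_grid) for (u in unit_grid) {
    cfg <- config
    cfg$n_layers <- as.integer(nl)
    cfg$units <- as.integer(u)
    rep_ <- evaluate_model(model_name, dataset, plan, cfg)
    out[[length(out) + 1L]] <- data.frame(
      n_layers = nl, units = u, mean_accuracy = rep_$mean_accuracy,
      sd_accuracy = rep_$sd_accuracy)
  }
  do.call(rbind, out)
}

#' Paired comparison of two frame lengths
#'
#' Builds one dataset per frame length from the same recordings, evaluates
#' the same model with aligned fold seeds, and reports the paired per-fold
#' accuracies and the difference of means (long minus short).
#'
#' @param recordings Recordings at the working rate underlying both datasets.
#' @param model_name Classifier to compare with.
#' @param frame_lengths_s Two frame lengths, default `c(0.8, 1.6)` seconds.
#' @param config A [train_config()].
#' @param onset_source,hsmm_model Passed to [build_dataset()].
#' @param k Folds.
#' @param seed Shared fold seed.
#' @return List with the two `cv_report`s, a paired accuracy table and
#'   `mean_difference`.
#' @export
compare_frame_lengths <- function(recordings, model_name = "gru",
                                  frame_lengths_s = c(0.8, 1.6),
                                  config = train_config(),
                                  onset_source = "truth", hsmm_model = NULL,
                                  k = 10, seed = 1L) {
  reports <- lapply(frame_lengths_s, function(len) {
    ds <- build_dataset(recordings, frame_length_s = len,
                        onset_source = onset_source, hsmm_model = hsmm_model)
    plan <- make_cv_plan(ds, k = k, seed = seed)
    evaluate_model(model_name, ds, plan, config)
  })
  names(reports) <- sprintf("%.1fs", frame_lengths_s)
  tab <- data.frame(fold = seq_len(k),
                    short = reports[[1]]$fold_accuracy,
                    long = reports[[2]]$fold_accuracy)
  names(tab)[2:3] <- names(reports)
  list(reports = reports, paired = tab,
       mean_difference = reports[[2]]$mean_accuracy - reports[[1]]$mean_accuracy)
}
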