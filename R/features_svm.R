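# Hand-crafted feature bank, Tamhane's T2 feature screening across the three
# classes, and the one-vs-one RBF SVM baseline with grid search.
#
# The bank is a documented generic set of time- and frequency-domain heart
# sound descriptors (energies, band ratios, spectral shape, entropy,
# octave-band energies); which of them survive the P < 0.001 screen is
# data-driven, with an optional cap on the number kept (default 3, ranked by
# smallest adjusted P).

# Periodogram (one-sided) of a frame: list(freq, power).
frame_periodogram <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2 / n
  half <- floor(n / 2) + 1
  list(freq = (seq_len(half) - 1) * fs / n, power = P[seq_len(half)])
}

band_energy <- function(pg, band) sum(pg$power[pg$freq >= band[1] & pg$freq < band[2]])

#' Extract the hand-crafted feature table from a frame dataset
#'
#' Per-frame features: total energy; S1-band (10-200 Hz) to S2-extension
#' (200-250 Hz) energy ratio (log); zero-crossing rate (about the frame
#' mean); spectral centroid and bandwidth (Hz); spectral rolloff (95%);
#' sample entropy (m = 2, r = 0.2 sd; 0 for constant frames); energies in
#' four octave bands (10-30, 30-60, 60-120, 120-250 Hz) as fractions of
#' total band energy; and the mean and standard deviation of the frame's
#' short-time energy contour (16 sub-windows). All features are finite:
#' degenerate all-zero frames yield zeros by convention.
#'
#' @param dataset A `frame_dataset` (normalized frames).
#' @return A `feature_table`: data frame of features plus a `class` column.
#' @export
extract_features <- function(dataset) {
  fs <- dataset$target_rate_hz
  n <- nrow(dataset$x)
  feat <- matrix(NA_real_, n, 13)
  colnames(feat) <- c("energy", "log_s1_s2_ratio", "zcr", "centroid_hz",
                      "bandwidth_hz", "rolloff95_hz", "sample_entropy",
                      "oct_10_30", "oct_30_60", "oct_60_120", "oct_120_250",
                      "ste_mean", "ste_sd")
  for (i in seq_len(n)) {
    x <- dataset$x[i, ]
    xc <- x - mean(x)
    pg <- frame_periodogram(x, fs)
    tot <- sum(pg$power)
    e_s1 <- band_energy(pg, c(10, 200))
    e_hi <- band_energy(pg, c(200, 250))
    zc <- mean(diff(sign(xc + (xc == 0) * 1e-12)) != 0)
    if (tot > 0) {
      centroid <- sum(pg$freq * pg$power) / tot
      bandwidth <- sqrt(sum((pg$freq - centroid)^2 * pg$power) / tot)
      roll <- pg$freq[which(cumsum(pg$power) >= 0.95 * tot)[1]]
    } else centroid <- bandwidth <- roll <- 0
    se <- if (stats::sd(x) > 0) {
      v <- pracma::sample_entropy(x[seq(1, length(x), by = 4)], edim = 2,
                                  r = 0.2 * stats::sd(x))
      if (is.finite(v)) v else 0
    } else 0
    octs <- vapply(list(c(10, 30), c(30, 60), c(60, 120), c(120, 250)),
                   function(b) band_energy(pg, b), numeric(1))
    oct_tot <- sum(octs)
    octs <- if (oct_tot > 0) octs / oct_tot else rep(0, 4)
    nw <- 16L
    w <- floor(length(x) / nw)
    ste <- vapply(seq_len(nw), function(k) mean(x[((k - 1) * w + 1):(k * w)]^2),
                  numeric(1))
    feat[i, ] <- c(sum(x^2), log((e_s1 + 1e-12) / (e_hi + 1e-12)), zc,
                   centroid, bandwidth, roll, se, octs, mean(ste), stats::sd(ste))
  }
  out <- as.data.frame(feat)
  out$class <- factor(PCG_CLASSES[dataset$y], levels = PCG_CLASSES)
  class(out) <- c("feature_table", class(out))
  out
}

#' Tamhane's T2 feature screening across the three classes
#'
#' For every feature, all pairwise class comparisons use the Welch t
#' statistic (unequal variances, Welch-Satterthwaite degrees of freedom)
#' with Tamhane's T2 Sidak-style multiplicity adjustment
#' p_adj = 1 - (1 - p)^m over the m = 3 pairwise comparisons. A feature is
#' selected when its smallest adjusted pairwise P is below `alpha`; at most
#' `cap` features are kept, ranked by that P.
#'
#' @param table A `feature_table` from [extract_features()].
#' @param alpha Selection threshold on the adjusted P (default 0.001).
#' @param cap Maximum number of features kept (default 3); `Inf` disables
#'   the cap.
#' @return A `selection_report`: data frame `stats` (feature, pair, t, df,
#'   p, p_adj), character `selected`, `alpha`.
#' @export
tamhane_t2_select <- function(table, alpha = 0.001, cap = 3) {
  cls <- table$class
  feats <- setdiff(names(table), "class")
  counts <- table(cls)
  if (any(counts < 2))
    stopf("class %s has fewer than 2 observations",
          names(counts)[which(counts < 2)[1]])
  pairs <- utils::combn(levels(cls), 2)
  m <- ncol(pairs)
  rows <- list()
  for (f in feats) {
    for (j in seq_len(m)) {
      a <- table[[f]][cls == pairs[1, j]]
      b <- table[[f]][cls == pairs[2, j]]
      va <- stats::var(a) + 1e-24; vb <- stats::var(b) + 1e-24  # zero-variance guard
      na <- length(a); nb <- length(b)
      se2 <- va / na + vb / nb
      tt <- (mean(a) - mean(b)) / sqrt(se2)
      df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
      p <- 2 * stats::pt(-abs(tt), df)
      p_adj <- 1 - (1 - p)^m
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, pair = paste(pairs[, j], collapse = " vs "),
        t = tt, df = df, p = p, p_adj = p_adj)
    }
  }
  stats_df <- do.call(rbind, rows)
  best <- stats::aggregate(p_adj ~ feature, stats_df, min)
  best <- best[order(best$p_adj), ]
  sel <- best$feature[best$p_adj < alpha]
  if (is.finite(cap) && length(sel) > cap) sel <- sel[seq_len(cap)]
  structure(list(stats = stats_df, selected = as.character(sel),
                 alpha = alpha, cap = cap),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d feature(s) at adjusted P < %g:\n",
              length(x$selected), x$alpha))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Train the one-vs-one RBF SVM baseline
#'
#' Features are standardized with training statistics; the cost and kernel
#' width are grid-searched (C over powers 2^-5..2^15, gamma over
#' 2^-15..2^3, step 4 in the exponent) by mean accuracy over an internal
#' seeded 3-fold split of the training rows; the final model is refit on all
#' rows at the chosen point. e1071's native multiclass scheme is one-vs-one.
#'
#' @param table A `feature_table` of training rows.
#' @param selected Character vector of feature names (from
#'   [tamhane_t2_select()]); must be non-empty.
#' @param seed Seed for the internal grid-search split.
#' @param grid_c,grid_gamma Optional overrides of the search grids.
#' @return A `svm_baseline` model: e1071 fit + scaler + chosen (C, gamma).
#' @export
train_svm <- function(table, selected, seed = 1L,
                      grid_c = 2^seq(-5, 15, by = 4),
                      grid_gamma = 2^seq(-15, 3, by = 4)) {
  if (!length(selected)) stopf("no features selected; cannot train the SVM")
  missing <- setdiff(selected, names(table))
  if (length(missing)) stopf("unknown features: %s", paste(missing, collapse = ", "))
  if (length(unique(table$class[!is.na(table$class)])) < 2)
    stopf("training data contain a single class")
  X <- as.matrix(table[selected])
  y <- droplevels(table$class)
  mu <- colMeans(X); sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd_, `/`)
  folds <- with_seed(seed, sample(rep_len(1:3, nrow(Xs))))
  best <- c(acc = -1, C = NA, gamma = NA)
  for (C in grid_c) for (gam in grid_gamma) {
    accs <- vapply(1:3, function(k) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2) return(NA_real_)
      fit <- e1071::svm(Xs[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = C, gamma = gam, scale = FALSE)
      mean(stats::predict(fit, Xs[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    acc <- mean(accs, na.rm = TRUE)
    if (acc > best["acc"]) best <- c(acc = acc, C = C, gamma = gam)
  }
  fit <- e1071::svm(Xs, y, kernel = "radial", cost = best[["C"]],
                    gamma = best[["gamma"]], scale = FALSE)
  structure(list(fit = fit, mu = mu, sd = sd_, selected = selected,
                 C = best[["C"]], gamma = best[["gamma"]],
                 cv_accuracy = best[["acc"]]),
            class = "svm_baseline")
}

#' Predict classes with the SVM baseline
#' @param model A `svm_baseline`.
#' @param table A `feature_table` of rows to classify.
#' @return Integer labels (1 = normal, 2 = HFpEF, 3 = HFrEF).
#' @export
predict_svm <- function(model, table) {
  X <- as.matrix(table[model$selected])
  Xs <- sweep(sweep(X, 2, model$mu), 2, model$sd, `/`)
  pred <- stats::predict(model$fit, Xs)
  match(as.character(pred), PCG_CLASSES)
}
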