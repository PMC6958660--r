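# Feature bank, Tamhane T2 screening, SVM baseline.

fake_dataset <- function(x, y, rate = 600) {
  structure(list(x = x, y = y,
                 meta = data.frame(recording_id = rep("r", nrow(x))),
                 frame_length_s = ncol(x) / rate, target_rate_hz = rate,
                 class_counts = table(factor(pcgscreen:::PCG_CLASSES[y],
                                             levels = pcgscreen:::PCG_CLASSES))),
            class = "frame_dataset")
}

test_that("features are finite, deterministic, and match analytic cases", {
  t_ <- (0:959) / 600
  sine100 <- pcgscreen:::minmax01(sin(2 * pi * 100 * t_))
  const <- rep(0, 960)
  x <- rbind(sine100, sine100, const)
  ft <- extract_features(fake_dataset(x, c(1L, 1L, 2L)))
  expect_false(anyNA(ft[setdiff(names(ft), "class")]))
  expect_true(all(vapply(ft[setdiff(names(ft), "class")], is.finite, logical(3))))
  # a pure 100 Hz tone centres the spectrum at 100 Hz
  expect_equal(ft$centroid_hz[1], 100, tolerance = 0.03)
  # duplicated frames give identical rows
  expect_equal(unlist(ft[1, -ncol(ft)]), unlist(ft[2, -ncol(ft)]))
  # constant frame: zero crossing rate and entropy are 0 by convention
  expect_equal(ft$zcr[3], 0)
  expect_equal(ft$sample_entropy[3], 0)
})

test_that("Tamhane T2 controls type-I selection under the null", {
  n_sel <- 0
  n_tables <- 100
  pcgscreen:::with_seed(201, {
    for (i in seq_len(n_tables)) {
      tb <- data.frame(f1 = stats::rnorm(60),
                       class = factor(rep(pcgscreen:::PCG_CLASSES, each = 20),
                                      levels = pcgscreen:::PCG_CLASSES))
      class(tb) <- c("feature_table", class(tb))
      sel <- tamhane_t2_select(tb, alpha = 0.001)
      if (length(sel$selected)) n_sel <- n_sel + 1
    }
  })
  expect_lte(n_sel / n_tables, 0.05)
})

test_that("a five-sigma effect is always selected and P-values are sane", {
  pcgscreen:::with_seed(202, {
    tb <- data.frame(
      strong = c(stats::rnorm(50, 0), stats::rnorm(50, 5), stats::rnorm(50, 10)),
      null_f = stats::rnorm(150),
      class = factor(rep(pcgscreen:::PCG_CLASSES, each = 50),
                     levels = pcgscreen:::PCG_CLASSES))
    class(tb) <- c("feature_table", class(tb))
    sel <- tamhane_t2_select(tb, alpha = 0.001)
    expect_true("strong" %in% sel$selected)
    expect_false("null_f" %in% sel$selected)
    expect_true(all(sel$stats$p_adj >= 0 & sel$stats$p_adj <= 1))
    expect_true(all(sel$stats$p_adj >= sel$stats$p - 1e-12))
  })
  # identical group samples: no effect, adjusted P near 1
  tb0 <- data.frame(f = rep(c(1, 2, 3, 4), 3),
                    class = factor(rep(pcgscreen:::PCG_CLASSES, each = 4),
                                   levels = pcgscreen:::PCG_CLASSES))
  class(tb0) <- c("feature_table", class(tb0))
  sel0 <- tamhane_t2_select(tb0, alpha = 0.001)
  expect_length(sel0$selected, 0)
  expect_true(all(sel0$stats$p_adj > 0.9))
})

test_that("adjusted P decreases with the mean difference, all else fixed", {
  base <- pcgscreen:::with_seed(203, stats::rnorm(40))
  p_at <- function(delta) {
    tb <- data.frame(f = c(base, base + delta, base + 2 * delta),
                     class = factor(rep(pcgscreen:::PCG_CLASSES, each = 40),
                                    levels = pcgscreen:::PCG_CLASSES))
    class(tb) <- c("feature_table", class(tb))
    min(tamhane_t2_select(tb, alpha = 1)$stats$p_adj)
  }
  ps <- vapply(c(0.5, 1, 2, 4), p_at, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("screening errors on classes with fewer than two rows", {
  tb <- data.frame(f = stats::rnorm(5),
                   class = factor(c("normal", "normal", "HFpEF", "HFpEF", "HFrEF"),
                                  levels = pcgscreen:::PCG_CLASSES))
  class(tb) <- c("feature_table", class(tb))
  expect_error(tamhane_t2_select(tb), "HFrEF")
})

test_that("the SVM separates Gaussian blobs and is deterministic", {
  pcgscreen:::with_seed(204, {
    n <- 50
    tb <- data.frame(
      f1 = c(stats::rnorm(n, 0), stats::rnorm(n, 4), stats::rnorm(n, 8)),
      f2 = c(stats::rnorm(n, 0), stats::rnorm(n, 4), stats::rnorm(n, 0)),
      class = factor(rep(pcgscreen:::PCG_CLASSES, each = n),
                     levels = pcgscreen:::PCG_CLASSES))
    class(tb) <- c("feature_table", class(tb))
    tr <- c(1:40, 51:90, 101:140)
    te <- setdiff(seq_len(nrow(tb)), tr)
    m1 <- train_svm(tb[tr, ], c("f1", "f2"), seed = 5)
    expect_gte(mean(predict_svm(m1, tb[te, ]) == rep(1:3, each = 10)), 0.95)
    m2 <- train_svm(tb[tr, ], c("f1", "f2"), seed = 5)
    expect_equal(c(m1$C, m1$gamma), c(m2$C, m2$gamma))
    expect_error(train_svm(tb[tr, ], character(0)), "no features")
  })
})

test_that("synthetic heart-sound classes pass the screen and classify well", {
  ds <- fixture_dataset()
  ft <- extract_features(ds)
  sel <- tamhane_t2_select(ft)
  expect_gte(length(sel$selected), 1)
  expect_lte(length(sel$selected), 3)
  idx <- pcgscreen:::with_seed(205, sample(nrow(ft)))
  tr <- idx[seq_len(floor(0.7 * length(idx)))]
  te <- setdiff(idx, tr)
  m <- train_svm(ft[tr, ], sel$selected, seed = 6)
  expect_gte(mean(predict_svm(m, ft[te, ]) == ds$y[te]), 0.9)
})
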