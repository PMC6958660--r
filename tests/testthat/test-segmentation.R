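# HSMM segmentation: envelope features, emissions, heart rate, Viterbi.

test_that("envelope features are scaled, aligned, and sized by the rate", {
  rec <- clean_recording(seed = 31, n_cycles = 10)
  f <- extract_envelope_features(rec, 50)
  expect_equal(ncol(f$features), 3)
  expect_equal(nrow(f$features),
               round(length(rec$samples) / 600 * 50), tolerance = 1e-9)
  expect_true(all(f$features >= 0 & f$features <= 1))
  expect_false(anyNA(f$features))
  # constant-zero input gives all-zero envelopes
  z <- pcg_recording(numeric(1200), 600)
  expect_true(all(extract_envelope_features(z, 50)$features == 0))
  expect_error(extract_envelope_features(pcg_recording(numeric(60), 600), 50),
               "too short")
})

test_that("homomorphic envelope peaks track a 1 Hz burst train", {
  x <- numeric(6000)
  for (k in 1:9)                            # 20-sample tone bursts every 1 s
    x[600 * k + 1:20] <- sin(2 * pi * 50 * (1:20) / 600)
  rec <- pcg_recording(x, 600)
  f <- extract_envelope_features(rec, 50)
  env <- f$features[, "homomorphic"]
  pk <- which(env > 0.5)
  pk <- pk[c(TRUE, diff(pk) > 5)]           # run starts
  expect_equal(length(pk), 9)
  expect_lt(max(abs(diff(pk) - 50)), 3)     # 1 s spacing at 50 Hz, +/- ticks
})

test_that("fitted emissions classify training ticks well and normalize", {
  model <- fixture_hsmm()
  rec <- clean_recording(seed = 32, n_cycles = 10)
  f <- extract_envelope_features(rec, model$feature_rate_hz)
  post <- pcgscreen:::emission_posteriors(f$features, model)
  expect_equal(rowSums(post), rep(1, nrow(post)), tolerance = 1e-9)
  truth <- pcgscreen:::states_at_ticks(rec, model$feature_rate_hz, nrow(post))
  # tick-wise argmax must beat chance (0.25) clearly; systole and diastole
  # are both near-silent and are separated mainly by the duration model,
  # so instantaneous envelope features cannot resolve them fully
  expect_gt(mean(max.col(post) == truth), 0.55)
  # sound versus silence is the easy, near-separable part
  sound_truth <- truth %in% c(1L, 3L)
  sound_pred <- max.col(post) %in% c(1L, 3L)
  expect_gt(mean(sound_pred == sound_truth), 0.85)
  bad <- clean_recording(seed = 33, n_cycles = 4)
  bad$true_state_path <- factor(rep("S1", length(bad$samples)),
                                levels = pcgscreen:::PCG_STATES)
  expect_error(fit_hsmm(list(bad)), "absent from training labels")
})

test_that("heart-rate estimation recovers fixed cycle lengths", {
  cfg <- synth_config(cycle_duration_s = c(0.8, 0.8), n_cycles = 12,
                      snr_db = 30, rng_seed = 34)
  rec <- generate_recording(cfg, "hr")
  hr <- estimate_heart_rate(extract_envelope_features(rec, 50))
  expect_equal(hr$cycle_length_s, 0.8, tolerance = 0.025)
  expect_gt(hr$systole_fraction, 0.25)
  expect_lt(hr$systole_fraction, 0.55)
  short <- generate_recording(synth_config(n_cycles = 1, rng_seed = 35), "one")
  expect_error(estimate_heart_rate(extract_envelope_features(short, 50)),
               "2 cycles|too short")
})

test_that("Viterbi matches the exhaustive state/duration oracle on tiny instances", {
  model <- dummy_hsmm_model()
  for (seed in 1:50) {
    inst <- random_hsmm_instance(seed)
    res <- viterbi_decode(NULL, model, durations = inst$durations,
                          emissions = inst$emissions)
    oracle <- enumerate_hsmm_paths(inst$emissions, inst$durations)
    expect_equal(res$log_score, oracle$score, tolerance = 1e-9,
                 info = sprintf("instance %d score", seed))
    matches <- any(vapply(oracle$paths, function(p) identical(p, res$path),
                          logical(1)))
    expect_true(matches, info = sprintf("instance %d path", seed))
  }
})

test_that("decoded paths respect the cyclic state order", {
  model <- dummy_hsmm_model()
  nxt <- c(2L, 3L, 4L, 1L)
  for (seed in 51:60) {
    inst <- random_hsmm_instance(seed)
    res <- viterbi_decode(NULL, model, durations = inst$durations,
                          emissions = inst$emissions)
    p <- res$path
    ch <- which(diff(p) != 0)
    expect_true(all(p[ch + 1] == nxt[p[ch]]))
  }
})

test_that("S1 onsets are recovered on clean synthetic recordings", {
  model <- fixture_hsmm()
  sens <- c(); ppv <- c()
  for (seed in c(41, 42, 43)) {
    for (cls in c("normal", "HFrEF")) {
      rec <- clean_recording(seed = seed, snr_db = 30, n_cycles = 20,
                             class_label = cls)
      res <- mark_s1_onsets(rec, model)
      expect_true(!is.unsorted(res$s1_onsets_s, strictly = TRUE))
      m <- onset_metrics(res$s1_onsets_s, rec$true_s1_onsets_s, tol = 0.06)
      sens <- c(sens, m$sens); ppv <- c(ppv, m$ppv)
      expect_lte(abs(length(res$s1_onsets_s) - 20), 1)
    }
  }
  expect_gte(mean(sens), 0.95)
  expect_gte(mean(ppv), 0.95)
})

test_that("decoding is deterministic and not time-reversal symmetric", {
  model <- fixture_hsmm()
  rec <- clean_recording(seed = 44, n_cycles = 12)
  r1 <- mark_s1_onsets(rec, model)
  r2 <- mark_s1_onsets(rec, model)
  expect_identical(r1$path, r2$path)
  expect_identical(r1$s1_onsets_s, r2$s1_onsets_s)
  rev_rec <- rec
  rev_rec$samples <- rev(rec$samples)
  r3 <- mark_s1_onsets(rev_rec, model)
  expect_false(identical(r1$s1_onsets_s, r3$s1_onsets_s))
})
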