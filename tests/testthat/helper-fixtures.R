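# Shared fixture builders. Everything is generated in code at test time;
# mid-size objects are cached per session to keep the suite fast.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A clean 20-cycle normal recording at 600 Hz.
clean_recording <- function(seed = 7, snr_db = 30, n_cycles = 20,
                            class_label = "normal") {
  generate_recording(
    synth_config(n_cycles = n_cycles, snr_db = snr_db,
                 class_label = class_label, rng_seed = seed),
    recording_id = sprintf("%s-seed%d", class_label, seed))
}

# Small labelled recordings for fitting HSMM emissions.
fixture_hsmm <- function() {
  fixture("hsmm", function() {
    recs <- list(
      generate_recording(synth_config(n_cycles = 15, rng_seed = 11), "fit-a"),
      generate_recording(synth_config(n_cycles = 15, class_label = "HFpEF",
                                      rng_seed = 12), "fit-b"),
      generate_recording(synth_config(n_cycles = 15, class_label = "HFrEF",
                                      rng_seed = 13), "fit-c"))
    fit_hsmm(recs)
  })
}

# Mid-size three-class frame dataset (ground-truth onsets, 1.6 s frames).
fixture_dataset <- function() {
  fixture("dataset", function() {
    base <- synth_config(n_cycles = 12, snr_db = 25, rng_seed = 5)
    recs <- generate_dataset(c(normal = 4, HFpEF = 4, HFrEF = 4), base)
    build_dataset(recs, onset_source = "truth")
  })
}

# Tiny, trivially separable frames for fast training checks: three classes
# of short band-limited patterns with distinct shapes.
tiny_separable_frames <- function(n_per_class = 20, len = 64, seed = 3) {
  pcgscreen:::with_seed(seed, {
    t <- seq_len(len) / len
    x <- matrix(NA_real_, 3 * n_per_class, len)
    y <- rep(1:3, each = n_per_class)
    for (i in seq_len(nrow(x))) {
      shape <- switch(y[i],
                      sin(2 * pi * 2 * t),
                      sign(sin(2 * pi * 2 * t)) * 0.8,
                      2 * t - 1)
      x[i, ] <- pcgscreen:::minmax01(shape + 0.05 * rnorm(len))
    }
    list(x = x, y = y)
  })
}

# Brute-force HSMM decoding oracle: enumerates every legal state/duration
# segmentation of the tick sequence (first/last segments truncated, scored
# by the survivor function; interior segments by the pmf; uniform initial
# state) and returns the maximal score with all optimal paths.
enumerate_hsmm_paths <- function(emissions, durations, tol = 1e-9) {
  T_ <- nrow(emissions)
  log_em <- log(pmax(emissions, 1e-300))
  Dmax <- durations$max_dur
  nxt <- c(2L, 3L, 4L, 1L)
  best <- -Inf
  paths <- list()
  rec <- function(t, s, score, path) {
    for (d in seq_len(min(Dmax, T_ - t + 1))) {
      end <- t + d - 1
      dur_sc <- if (t == 1 || end == T_) durations$log_surv[s, d]
                else durations$log_pmf[s, d]
      sc <- score + dur_sc + sum(log_em[t:end, s])
      pth <- c(path, rep(s, d))
      if (end == T_) {
        if (sc > best + tol) { best <<- sc; paths <<- list(pth) }
        else if (sc > best - tol) paths[[length(paths) + 1L]] <<- pth
      } else if (sc > -Inf) {
        rec(end + 1L, nxt[s], sc, pth)
      }
    }
  }
  for (s0 in 1:4) rec(1L, s0, log(1 / 4), integer(0))
  list(score = best, paths = paths)
}

# Random small HSMM instance for oracle comparisons.
random_hsmm_instance <- function(seed, max_ticks = 12, max_dur = 4) {
  pcgscreen:::with_seed(seed, {
    T_ <- sample(6:max_ticks, 1)
    em <- matrix(stats::runif(T_ * 4, 0.05, 1), T_, 4)
    em <- em / rowSums(em)
    pmf <- matrix(stats::runif(4 * max_dur, 0.05, 1), 4, max_dur)
    pmf <- pmf / rowSums(pmf)
    surv <- t(apply(pmf, 1, function(p) rev(cumsum(rev(p)))))
    list(emissions = em,
         durations = list(log_pmf = log(pmf), log_surv = log(pmin(surv, 1)),
                          max_dur = max_dur))
  })
}

dummy_hsmm_model <- function(feature_rate_hz = 50) {
  structure(list(feature_rate_hz = feature_rate_hz), class = "hsmm_model")
}

# Onset detection metrics at a +/- tolerance (seconds).
onset_metrics <- function(detected, truth, tol = 0.06) {
  if (!length(detected)) return(list(sens = 0, ppv = NA_real_))
  d <- abs(outer(truth, detected, "-"))
  list(sens = mean(apply(d, 1, min) <= tol),
       ppv = mean(apply(d, 2, min) <= tol))
}
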