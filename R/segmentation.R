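# S1-onset localization with a duration-dependent four-state hidden
# semi-Markov model (HSMM) over the cyclic state order
# S1 -> systole -> S2 -> diastole, with logistic-regression emissions over
# envelope features. Decoding uses an extended Viterbi recursion in which
# every state visit carries an explicit duration distribution; boundary
# segments may be truncated (scored by the duration survivor function), so
# the decode can enter and leave mid-cycle.

state_next <- c(2L, 3L, 4L, 1L)   # cyclic successor of state i
state_prev <- c(4L, 1L, 2L, 3L)

analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

lowpass <- function(x, cutoff_hz, fs, order = 2) {
  bf <- signal::butter(order, min(cutoff_hz / (fs / 2), 0.99), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

bandpass <- function(x, band_hz, fs, order = 2) {
  w <- pmin(pmax(band_hz / (fs / 2), 1e-4), 0.99)
  bf <- signal::butter(order, w, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Extract per-tick envelope features for segmentation
#'
#' Three channels at the (reduced) feature rate: a homomorphic envelope
#' (low-pass on the log magnitude of the analytic signal, then
#' exponentiated), the Hilbert (analytic-signal) envelope, and the envelope
#' of a 25-120 Hz band-passed copy. Each channel is min-max scaled to
#' \[0, 1\] over the recording.
#'
#' @param recording A `pcg_recording` at the working rate.
#' @param feature_rate_hz Feature rate (ticks per second), default 50.
#' @return An `envelope_features` object: matrix `features` (ticks x 3),
#'   `feature_rate_hz`, `duration_s`.
#' @export
extract_envelope_features <- function(recording, feature_rate_hz = 50) {
  x <- recording$samples
  fs <- recording$sampling_rate_hz
  if (length(x) < fs * 0.5)
    stopf("recording too short for envelope features (< 0.5 s)")
  n_ticks <- round(length(x) / fs * feature_rate_hz)
  env <- analytic_envelope(x)
  mx <- max(env)
  if (mx == 0) {                       # silent input: all-zero channels
    f <- matrix(0, n_ticks, 3,
                dimnames = list(NULL, c("homomorphic", "hilbert", "band_25_120")))
    return(structure(list(features = f, feature_rate_hz = feature_rate_hz,
                          duration_s = length(x) / fs),
                     class = "envelope_features"))
  }
  # floor the envelope before the log so silence does not dominate the range
  homo <- exp(lowpass(log(pmax(env, 1e-4 * mx)), 8, fs, order = 1))
  hilb <- lowpass(env, 20, fs, order = 2)
  bp <- analytic_envelope(bandpass(x, c(25, 120), fs))
  bp <- lowpass(bp, 20, fs, order = 2)

  dec <- function(v) {
    r <- rational_ratio(feature_rate_hz / fs)
    y <- as.numeric(signal::resample(v, r[["p"]], r[["q"]]))
    length(y) <- n_ticks
    y[is.na(y)] <- 0
    y
  }
  scale01 <- function(v) {             # near-constant channels collapse to 0
    r <- range(v)
    if (r[2] - r[1] < 1e-8 * max(1, mx)) return(rep(0, length(v)))
    (v - r[1]) / (r[2] - r[1])
  }
  f <- cbind(homomorphic = dec(homo), hilbert = dec(hilb), band_25_120 = dec(bp))
  f <- apply(f, 2, scale01)
  structure(list(features = f, feature_rate_hz = feature_rate_hz,
                 duration_s = length(x) / fs),
            class = "envelope_features")
}

# Down-sample a per-sample state path to the feature-tick grid
# (state at the centre sample of each tick).
states_at_ticks <- function(recording, feature_rate_hz, n_ticks) {
  fs <- recording$sampling_rate_hz
  centre <- round(((seq_len(n_ticks) - 0.5) / feature_rate_hz) * fs)
  centre <- pmin(pmax(centre, 1), length(recording$true_state_path))
  as.integer(recording$true_state_path[centre])
}

#' Fit logistic-regression emission models from labelled recordings
#'
#' One one-vs-rest binomial logistic fit per state over the three envelope
#' channels; at decode time the four per-state probabilities are renormalized
#' to sum to one per tick. Training recordings must carry ground-truth state
#' paths (the synthetic generator provides them).
#'
#' @param recordings List of `pcg_recording` with `true_state_path`.
#' @param feature_rate_hz Feature rate used for training and decoding.
#' @return An `hsmm_model` with `weights` (4 x (1 + n_features)),
#'   `feature_rate_hz` and per-state duration fractions.
#' @export
fit_hsmm <- function(recordings, feature_rate_hz = 50) {
  feats <- list(); states <- list()
  for (rec in recordings) {
    if (is.null(rec$true_state_path))
      stopf("recording %s has no ground-truth state path", rec$recording_id)
    ef <- extract_envelope_features(rec, feature_rate_hz)
    feats[[length(feats) + 1L]] <- ef$features
    states[[length(states) + 1L]] <-
      states_at_ticks(rec, feature_rate_hz, nrow(ef$features))
  }
  X <- do.call(rbind, feats)
  y <- unlist(states)
  missing <- setdiff(1:4, unique(y))
  if (length(missing))
    stopf("state(s) absent from training labels: %s",
          paste(PCG_STATES[missing], collapse = ", "))
  W <- matrix(0, 4, ncol(X) + 1,
              dimnames = list(PCG_STATES, c("(Intercept)", colnames(X))))
  df <- as.data.frame(X)
  for (s in 1:4) {
    df$.y <- as.integer(y == s)
    fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    W[s, ] <- stats::coef(fit)
  }
  W[is.na(W)] <- 0
  structure(list(weights = W, feature_rate_hz = feature_rate_hz,
                 s1_duration_s = 0.122, s2_duration_s = 0.092,
                 duration_sd_frac = 0.2),
            class = "hsmm_model")
}

# Per-tick state posteriors (ticks x 4), renormalized across states.
emission_posteriors <- function(features, model) {
  X <- cbind(1, features)
  P <- sigmoid(X %*% t(model$weights))
  P / pmax(rowSums(P), 1e-300)
}

#' Estimate cycle length and systolic fraction from envelope features
#'
#' The cardiac period is taken from the highest autocorrelation peak of the
#' homomorphic envelope within a plausible lag window (0.5-1.0 s by default);
#' the S1-to-S2 spacing (hence the systolic fraction) from the strongest
#' secondary peak below 0.6 of the period. With two interleaved tempos the
#' dominant (higher-autocorrelation) one is returned.
#'
#' @param features An `envelope_features`.
#' @param lag_window_s Admissible cycle-length window (seconds).
#' @return List with `cycle_length_s` and `systole_fraction`.
#' @export
estimate_heart_rate <- function(features, lag_window_s = c(0.5, 1.0)) {
  r <- features$feature_rate_hz
  env <- features$features[, "homomorphic"]
  if (features$duration_s < 2 * lag_window_s[1])
    stopf("recording too short to estimate heart rate; need >= 2 cycles")
  a <- stats::acf(env, lag.max = min(length(env) - 1, ceiling(lag_window_s[2] * r) + 1),
                  plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lags <- seq_along(a) - 1
  win <- which(lags >= lag_window_s[1] * r & lags <= lag_window_s[2] * r)
  if (!length(win)) stopf("no admissible autocorrelation lag; record longer")
  # local maxima within the window
  cand <- win[a[win] >= a[pmax(win - 1, 1)] & a[win] >= a[pmin(win + 1, length(a))]]
  if (!length(cand)) cand <- win[which.max(a[win])]
  best <- cand[which.max(a[cand])]
  if (a[best] <= 0)
    stopf("no admissible autocorrelation peak; provide a longer recording")
  cycle_s <- lags[best] / r
  sys_win <- which(lags >= 0.15 * cycle_s * r & lags <= 0.6 * cycle_s * r)
  systole_fraction <- 0.42
  if (length(sys_win) > 2) {
    sc <- sys_win[a[sys_win] >= a[pmax(sys_win - 1, 1)] &
                  a[sys_win] >= a[pmin(sys_win + 1, length(a))]]
    if (length(sc)) {
      spacing <- lags[sc[which.max(a[sc])]] / r
      systole_fraction <- min(max(spacing / cycle_s, 0.25), 0.55)
    }
  }
  list(cycle_length_s = cycle_s, systole_fraction = systole_fraction)
}

#' Build per-state duration distributions for a given heart rate
#'
#' Truncated discretized Gaussians in feature ticks. Means: fixed S1 and S2
#' durations; systole = systolic interval minus S1; diastole = remainder of
#' the cycle. Standard deviations are `duration_sd_frac` of the mean and the
#' support is clipped to mean +/- 3 sd, at least 1 tick.
#'
#' @param model An `hsmm_model`.
#' @param cycle_length_s Estimated cardiac period (seconds).
#' @param systole_fraction Estimated systolic fraction of the cycle.
#' @return List with `log_pmf` and `log_surv` (4 x max_dur matrices; column d
#'   is duration d ticks) and `max_dur`.
#' @export
duration_model <- function(model, cycle_length_s, systole_fraction = 0.42) {
  r <- model$feature_rate_hz
  mean_s <- c(model$s1_duration_s,
              systole_fraction * cycle_length_s - model$s1_duration_s,
              model$s2_duration_s,
              (1 - systole_fraction) * cycle_length_s - model$s2_duration_s)
  mean_t <- pmax(mean_s * r, 1)
  sd_t <- pmax(model$duration_sd_frac * mean_t, 0.5)
  lo <- pmax(floor(mean_t - 3 * sd_t), 1)
  hi <- pmax(ceiling(mean_t + 3 * sd_t), lo)
  max_dur <- as.integer(max(hi))
  log_pmf <- matrix(-Inf, 4, max_dur)
  for (s in 1:4) {
    d <- lo[s]:hi[s]
    p <- stats::dnorm(d, mean_t[s], sd_t[s])
    log_pmf[s, d] <- log(p / sum(p))
  }
  pmf <- exp(log_pmf)
  # survivor: P(D >= d), for truncated boundary segments
  surv <- t(apply(pmf, 1, function(p) rev(cumsum(rev(p)))))
  list(log_pmf = log_pmf, log_surv = log(pmax(surv, 0)), max_dur = max_dur)
}

#' Duration-dependent Viterbi decoding
#'
#' Finds the maximum a-posteriori segmentation of the tick sequence into
#' state visits under the cyclic order, with each interior visit scored by
#' its duration pmf and the first and last visits allowed to be truncated
#' (scored by the survivor function P(D >= d); a single-visit path is scored
#' by the survivor function once). The initial state carries a uniform 1/4
#' prior. Ties are broken toward the shorter duration and then the earlier
#' state in cyclic order (S1 first), so decoding is reproducible.
#'
#' @param features An `envelope_features` (or bare ticks x 4 emission
#'   posterior matrix via `emissions`).
#' @param model An `hsmm_model`.
#' @param durations A [duration_model()]; computed from
#'   [estimate_heart_rate()] when `NULL`.
#' @param emissions Optional precomputed ticks x 4 emission probabilities,
#'   overriding the model's logistic emissions (used by tests).
#' @return A `segmentation_result`: integer `path` (per tick, 1..4 over
#'   S1/systole/S2/diastole), `s1_onsets_s`, `log_score`.
#' @export
viterbi_decode <- function(features, model, durations = NULL, emissions = NULL) {
  if (is.null(emissions)) {
    emissions <- emission_posteriors(features$features, model)
  }
  if (ncol(emissions) != 4) stopf("emission matrix must have 4 state columns")
  if (is.null(durations)) {
    hr <- estimate_heart_rate(features)
    durations <- duration_model(model, hr$cycle_length_s, hr$systole_fraction)
  }
  T_ <- nrow(emissions)
  Dmax <- durations$max_dur
  log_em <- log(pmax(emissions, 1e-300))
  cum <- apply(log_em, 2, cumsum)
  cum <- rbind(0, cum)                       # cum[t+1, s] = sum_{1..t}
  seg_em <- function(s, t0, t1) cum[t1 + 1, s] - cum[t0, s]

  delta <- matrix(-Inf, T_, 4)               # last segment scored by pmf
  bp_d <- matrix(0L, T_, 4)
  log_init <- log(1 / 4)
  for (t in seq_len(T_)) {
    for (s in 1:4) {
      best <- -Inf; best_d <- 0L
      for (d in seq_len(min(Dmax, t))) {
        start <- t - d + 1L
        base <- if (start == 1L) log_init + durations$log_surv[s, d]
                else delta[start - 1L, state_prev[s]] + durations$log_pmf[s, d]
        v <- base + seg_em(s, start, t)
        if (v > best) { best <- v; best_d <- d }
      }
      delta[t, s] <- best
      bp_d[t, s] <- best_d
    }
  }
  # termination: rescore the final segment with the survivor function
  final <- matrix(-Inf, 4, Dmax)
  for (s in 1:4) {
    for (d in seq_len(min(Dmax, T_))) {
      start <- T_ - d + 1L
      base <- if (start == 1L) log_init + durations$log_surv[s, d]
              else delta[start - 1L, state_prev[s]] + durations$log_surv[s, d]
      final[s, d] <- base + seg_em(s, start, T_)
    }
  }
  best_s <- 1L; best_d <- 1L; best_v <- -Inf
  for (d in seq_len(min(Dmax, T_)))          # shorter duration wins ties
    for (s in 1:4)                           # then earlier cyclic state
      if (final[s, d] > best_v) { best_v <- final[s, d]; best_s <- s; best_d <- d }

  path <- integer(T_)
  t <- T_; s <- best_s; d <- best_d
  repeat {
    path[(t - d + 1L):t] <- s
    t <- t - d
    if (t == 0L) break
    s <- state_prev[s]
    d <- bp_d[t, s]
  }
  starts <- which(path == 1L & c(TRUE, path[-T_] != 1L))
  structure(list(path = path, s1_onsets_s = (starts - 1L) / model$feature_rate_hz,
                 log_score = best_v),
            class = "segmentation_result")
}

#' Mark S1 onsets in a recording
#'
#' Composition of envelope-feature extraction, heart-rate estimation,
#' duration-model adaptation, and duration-dependent Viterbi decoding;
#' returns strictly increasing S1 onset times. Decoding is deterministic.
#'
#' @param recording A `pcg_recording` at the working rate.
#' @param model A fitted `hsmm_model`.
#' @return A `segmentation_result` (see [viterbi_decode()]).
#' @export
mark_s1_onsets <- function(recording, model) {
  feats <- extract_envelope_features(recording, model$feature_rate_hz)
  hr <- estimate_heart_rate(feats)
  dur <- duration_model(model, hr$cycle_length_s, hr$systole_fraction)
  viterbi_decode(feats, model, durations = dur)
}
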