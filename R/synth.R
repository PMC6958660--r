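# Synthetic phonocardiogram (PCG) simulator.
#
# Each cardiac cycle is modelled as two Gaussian-windowed band-limited chirp
# transients -- S1 at the cycle start (energy concentrated in 10-200 Hz) and
# S2 at the end of systole (20-250 Hz) -- separated by near-silence, with the
# four acoustic states S1 / systole / S2 / diastole labelled per sample.
# Three class-conditional profiles (normal, HFpEF, HFrEF) perturb component
# amplitudes, bandwidths, low-frequency content and systolic murmur noise;
# they are acoustic surrogates for screening experiments, not clinical claims.

#' Default class-conditional acoustic profiles
#'
#' Multipliers applied to the base cycle model. `amp_s1`/`amp_s2` scale the
#' component amplitudes, `bw_s1`/`bw_s2` widen the chirp frequency span,
#' `lowfreq` adds a slow (2-8 Hz) baseline oscillation and `murmur` adds
#' band-limited noise confined to systole. The HFpEF surrogate accentuates S2
#' and adds a soft systolic murmur; the HFrEF surrogate attenuates S1
#' (reduced contractility) and adds low-frequency content.
#'
#' @return Named list of per-class profile lists.
#' @export
default_class_profiles <- function() {
  list(
    normal = list(amp_s1 = 1.00, amp_s2 = 0.80, bw_s1 = 1.0, bw_s2 = 1.0,
                  lowfreq = 0.00, murmur = 0.00),
    HFpEF  = list(amp_s1 = 0.90, amp_s2 = 1.25, bw_s1 = 1.0, bw_s2 = 1.2,
                  lowfreq = 0.08, murmur = 0.18),
    HFrEF  = list(amp_s1 = 0.55, amp_s2 = 0.85, bw_s1 = 1.3, bw_s2 = 1.0,
                  lowfreq = 0.25, murmur = 0.08)
  )
}

#' Synthetic-recording configuration
#'
#' @param sampling_rate_hz Sampling rate of the generated waveform (Hz).
#' @param n_cycles Number of cardiac cycles.
#' @param cycle_duration_s Length-2 interval (seconds) from which each cycle
#'   duration is drawn uniformly and independently; must lie within
#'   \[0.5, 1\] s. Default \[0.6, 0.8\] s, the typical cardiac period.
#' @param s1_band_hz,s2_band_hz Frequency intervals (Hz) containing the S1 and
#'   S2 transients; defaults 10-200 Hz and 20-250 Hz.
#' @param s1_duration_s,s2_duration_s Component durations (seconds).
#' @param systole_fraction Fraction of the cycle from S1 onset to S2 onset.
#' @param class_label One of `"normal"`, `"HFpEF"`, `"HFrEF"`.
#' @param class_profile Profile list (see [default_class_profiles()]); by
#'   default looked up from `class_label`.
#' @param snr_db Additive white Gaussian noise level, as signal-to-noise
#'   ratio in dB.
#' @param rng_seed Integer seed controlling all randomness of the recording.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(sampling_rate_hz = 600, n_cycles = 20,
                         cycle_duration_s = c(0.6, 0.8),
                         s1_band_hz = c(10, 200), s2_band_hz = c(20, 250),
                         s1_duration_s = 0.12, s2_duration_s = 0.10,
                         systole_fraction = 0.42,
                         class_label = "normal", class_profile = NULL,
                         snr_db = 25, rng_seed = 1L) {
  if (sampling_rate_hz <= 0) stopf("sampling_rate_hz must be positive")
  if (n_cycles < 1) stopf("n_cycles must be >= 1")
  if (length(cycle_duration_s) == 1) cycle_duration_s <- rep(cycle_duration_s, 2)
  if (cycle_duration_s[1] > cycle_duration_s[2] ||
      cycle_duration_s[1] < 0.5 || cycle_duration_s[2] > 1.0)
    stopf("cycle_duration_s must be an interval within [0.5, 1.0] s")
  if (s1_duration_s <= 0 || s2_duration_s <= 0)
    stopf("component durations must be positive")
  if (systole_fraction <= 0 || systole_fraction >= 1)
    stopf("systole_fraction must lie in (0, 1)")
  if (s1_duration_s >= systole_fraction * cycle_duration_s[1])
    stopf("s1_duration_s must fit inside systole of the shortest cycle")
  if (systole_fraction * cycle_duration_s[1] + s2_duration_s >= cycle_duration_s[1])
    stopf("S2 must end before the shortest cycle does")
  class_label <- match.arg(class_label, PCG_CLASSES)
  profile <- class_profile %||% default_class_profiles()[[class_label]]
  structure(list(
    sampling_rate_hz = sampling_rate_hz, n_cycles = as.integer(n_cycles),
    cycle_duration_s = cycle_duration_s, s1_band_hz = s1_band_hz,
    s2_band_hz = s2_band_hz, s1_duration_s = s1_duration_s,
    s2_duration_s = s2_duration_s, systole_fraction = systole_fraction,
    class_label = class_label, class_profile = profile,
    snr_db = snr_db, rng_seed = as.integer(rng_seed)
  ), class = "synth_config")
}

# One Gaussian-windowed linear chirp transient of `n` samples at rate `fs`.
# The carrier sweeps the middle of `band_hz` (span widened by `bw_mult`);
# the Gaussian window (sd = duration/6) keeps spectral energy inside the band.
gauss_chirp <- function(n, fs, band_hz, bw_mult = 1, amp = 1) {
  t <- (seq_len(n) - 1) / fs
  dur <- n / fs
  f_lo <- band_hz[1]; f_hi <- band_hz[2]
  centre <- (f_lo + f_hi) / 2
  span <- min((f_hi - f_lo) * 0.35 * bw_mult, (f_hi - f_lo) * 0.45)
  f0 <- max(centre - span / 2, f_lo + 2)
  f1 <- min(centre + span / 2, f_hi - 2)
  phase <- 2 * pi * (f0 * t + (f1 - f0) / (2 * dur) * t^2) + stats::runif(1, 0, 2 * pi)
  win <- exp(-0.5 * ((t - dur / 2) / (dur / 6))^2)
  amp * win * sin(phase)
}

#' Generate a single cardiac cycle
#'
#' Produces one noiseless cycle: an S1 transient starting at time 0, an S2
#' transient starting at `systole_fraction * cycle_duration_s`, class-profile
#' murmur/low-frequency content, and a per-sample state labelling over
#' S1 / systole / S2 / diastole derived from the component support intervals.
#' Randomness (carrier phases, murmur noise) is drawn from the current RNG
#' stream; callers seed it ([generate_recording()] does so via `rng_seed`).
#'
#' @param config A [synth_config()].
#' @param cycle_duration_s Duration of this cycle in seconds.
#' @return List with `samples` (waveform), `s1`, `s2`, `other` (the clean
#'   components), `states` (per-sample factor over the four states),
#'   `s1_onset_s` (0) and `s2_onset_s`.
#' @export
generate_cycle <- function(config, cycle_duration_s) {
  if (cycle_duration_s <= 0) stopf("cycle_duration_s must be positive")
  if (cycle_duration_s <= config$s1_duration_s + config$s2_duration_s)
    stopf("cycle shorter than its S1 and S2 components")
  fs <- config$sampling_rate_hz
  n <- round(cycle_duration_s * fs)
  pr <- config$class_profile

  n_s1 <- round(config$s1_duration_s * fs)
  n_s2 <- round(config$s2_duration_s * fs)
  i_s2 <- round(config$systole_fraction * cycle_duration_s * fs)  # 0-based onset

  s1 <- numeric(n)
  s1[seq_len(n_s1)] <- gauss_chirp(n_s1, fs, config$s1_band_hz, pr$bw_s1, pr$amp_s1)
  s2 <- numeric(n)
  s2[i_s2 + seq_len(n_s2)] <- gauss_chirp(n_s2, fs, config$s2_band_hz, pr$bw_s2, pr$amp_s2)

  other <- numeric(n)
  if (pr$lowfreq > 0) {
    f_slow <- stats::runif(1, 2, 8)
    other <- other + pr$lowfreq * sin(2 * pi * f_slow * (seq_len(n) - 1) / fs +
                                        stats::runif(1, 0, 2 * pi))
  }
  if (pr$murmur > 0) {
    # soft systolic murmur: white noise shaped by a raised-cosine window
    # spanning the S1-end to S2-onset interval
    idx <- seq.int(n_s1 + 1, i_s2)
    w <- 0.5 - 0.5 * cos(2 * pi * seq_along(idx) / length(idx))
    other[idx] <- other[idx] + pr$murmur * w * stats::rnorm(length(idx))
  }

  states <- rep(PCG_STATES[4], n)
  states[seq_len(n_s1)] <- PCG_STATES[1]
  states[seq.int(n_s1 + 1, i_s2)] <- PCG_STATES[2]
  states[i_s2 + seq_len(n_s2)] <- PCG_STATES[3]

  list(samples = s1 + s2 + other, s1 = s1, s2 = s2, other = other,
       states = states, s1_onset_s = 0, s2_onset_s = i_s2 / fs)
}

#' Generate a labelled synthetic PCG recording
#'
#' Concatenates `n_cycles` cycles (durations drawn uniformly from
#' `cycle_duration_s`), adds white Gaussian noise at `snr_db`, and records the
#' ground-truth S1/S2 onsets and per-sample state path. All randomness flows
#' through `config$rng_seed`; the caller's RNG state is left untouched.
#'
#' @param config A [synth_config()].
#' @param recording_id Identifier stored with the recording.
#' @return A `pcg_recording`: list with `samples`, `sampling_rate_hz`,
#'   `class_label`, `true_s1_onsets_s`, `true_s2_onsets_s`, `true_state_path`,
#'   `recording_id`, and a `components` list (`s1`, `s2`, `other`, `noise`)
#'   retained for spectral bookkeeping.
#' @export
generate_recording <- function(config, recording_id = "synth-1") {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$rng_seed, {
    durs <- stats::runif(config$n_cycles, config$cycle_duration_s[1],
                         config$cycle_duration_s[2])
    cycles <- lapply(durs, function(d) generate_cycle(config, d))
    fs <- config$sampling_rate_hz
    n_per <- vapply(cycles, function(cy) length(cy$samples), integer(1))
    starts <- c(0L, cumsum(n_per))[seq_along(cycles)]  # 0-based sample offsets

    samples <- unlist(lapply(cycles, `[[`, "samples"))
    comp <- list(
      s1 = unlist(lapply(cycles, `[[`, "s1")),
      s2 = unlist(lapply(cycles, `[[`, "s2")),
      other = unlist(lapply(cycles, `[[`, "other"))
    )
    states <- unlist(lapply(cycles, `[[`, "states"))

    p_sig <- mean(samples^2)
    noise_sd <- sqrt(p_sig / 10^(config$snr_db / 10))
    comp$noise <- stats::rnorm(length(samples), sd = noise_sd)

    s1_on <- starts / fs
    s2_on <- (starts + vapply(cycles, function(cy) round(cy$s2_onset_s * fs),
                              numeric(1))) / fs
    structure(list(
      samples = samples + comp$noise, sampling_rate_hz = fs,
      class_label = config$class_label,
      true_s1_onsets_s = s1_on, true_s2_onsets_s = s2_on,
      true_state_path = factor(states, levels = PCG_STATES),
      recording_id = recording_id, components = comp
    ), class = "pcg_recording")
  })
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording %s> %s, %.2f s at %g Hz, %d labelled S1 onsets\n",
              x$recording_id, x$class_label,
              length(x$samples) / x$sampling_rate_hz, x$sampling_rate_hz,
              length(x$true_s1_onsets_s)))
  invisible(x)
}

#' Construct a pcg_recording from components
#'
#' Validates the invariants: onsets strictly increasing within the recording,
#' and (when present) a state path with one label per sample.
#' @param samples Numeric waveform.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param class_label Class label or `NA`.
#' @param s1_onsets_s,s2_onsets_s Onset times in seconds.
#' @param state_path Optional per-sample factor over the four states.
#' @param recording_id Identifier.
#' @return A `pcg_recording`.
#' @export
pcg_recording <- function(samples, sampling_rate_hz, class_label = NA,
                          s1_onsets_s = numeric(0), s2_onsets_s = numeric(0),
                          state_path = NULL, recording_id = "rec") {
  dur <- length(samples) / sampling_rate_hz
  for (nm in c("s1_onsets_s", "s2_onsets_s")) {
    on <- get(nm)
    if (length(on) && (is.unsorted(on, strictly = TRUE) || any(on < 0) ||
                       any(on >= dur)))
      stopf("%s must be strictly increasing within [0, duration)", nm)
  }
  if (!is.null(state_path) && length(state_path) != length(samples))
    stopf("state_path must have one label per sample")
  structure(list(samples = samples, sampling_rate_hz = sampling_rate_hz,
                 class_label = class_label, true_s1_onsets_s = s1_onsets_s,
                 true_s2_onsets_s = s2_onsets_s, true_state_path = state_path,
                 recording_id = recording_id, components = NULL),
            class = "pcg_recording")
}

#' Generate a class-balanced synthetic dataset
#'
#' @param per_class_counts Named integer vector/list, e.g.
#'   `c(normal = 5, HFpEF = 5, HFrEF = 5)`.
#' @param base_config A [synth_config()] supplying everything except class
#'   label and per-recording seed; per-recording seeds are derived from
#'   `base_config$rng_seed` and the recordings are returned in a seeded
#'   random order.
#' @return List of `pcg_recording` objects.
#' @export
generate_dataset <- function(per_class_counts, base_config = synth_config()) {
  counts <- unlist(per_class_counts)
  if (any(counts < 0)) stopf("counts must be >= 0")
  counts <- counts[counts > 0]
  if (!length(counts)) return(list())
  if (!all(names(counts) %in% PCG_CLASSES))
    stopf("unknown class labels: %s",
          paste(setdiff(names(counts), PCG_CLASSES), collapse = ", "))
  specs <- do.call(rbind, lapply(names(counts), function(cl)
    data.frame(class = cl, k = seq_len(counts[[cl]]))))
  recs <- lapply(seq_len(nrow(specs)), function(i) {
    cl <- specs$class[i]
    cfg <- base_config
    cfg$class_label <- cl
    cfg$class_profile <- default_class_profiles()[[cl]]
    cfg$rng_seed <- derive_seed(base_config$rng_seed, paste0(cl, specs$k[i]))
    generate_recording(cfg, recording_id = sprintf("%s-%02d", cl, specs$k[i]))
  })
  ord <- with_seed(derive_seed(base_config$rng_seed, "order"),
                   sample.int(length(recs)))
  recs[ord]
}
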