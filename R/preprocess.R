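# Resampling to the working rate and per-frame min-max normalization.

# Best small rational approximation p/q of `ratio` (continued fractions).
rational_ratio <- function(ratio, max_den = 4096) {
  pq <- c(1, 0, 0, 1)  # convergents p_{k-1}, p_k / q_{k-1}, q_k
  x <- ratio
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  for (i in 1:64) {
    a <- floor(x)
    p <- a * p1 + p0; q <- a * q1 + q0
    if (q > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p; q1 <- q
    if (abs(x - a) < 1e-12) break
    x <- 1 / (x - a)
  }
  c(p = p1, q = q1)
}

#' Resample a recording to a target rate
#'
#' Polyphase rational-ratio resampling with an anti-aliasing low-pass
#' (via [signal::resample()]). Onset times and state labels are carried in
#' seconds, so they are unchanged; the per-sample state path does not survive
#' resampling and is re-derived from the onsets when needed.
#'
#' @param recording A `pcg_recording`.
#' @param target_rate_hz Output rate; the 600 Hz default satisfies Nyquist for
#'   the 250 Hz upper edge of the S2 band. A target at or below 500 Hz
#'   triggers an aliasing warning.
#' @return The resampled `pcg_recording`.
#' @export
resample_recording <- function(recording, target_rate_hz = 600) {
  if (target_rate_hz <= 0) stopf("target_rate_hz must be positive")
  if (!length(recording$samples)) stopf("cannot resample an empty recording")
  if (target_rate_hz <= 2 * 250)
    warnf("target rate %g Hz risks aliasing the S2 band (up to 250 Hz)",
          target_rate_hz)
  fs <- recording$sampling_rate_hz
  if (isTRUE(all.equal(fs, target_rate_hz))) return(recording)
  r <- rational_ratio(target_rate_hz / fs)
  y <- signal::resample(recording$samples, r[["p"]], r[["q"]])
  n_out <- round(length(recording$samples) * target_rate_hz / fs)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, rep(0, n_out - length(y)))
  out <- recording
  out$samples <- as.numeric(y)
  out$sampling_rate_hz <- target_rate_hz
  out$true_state_path <- NULL
  out$components <- NULL
  out
}

#' Construct a frame
#'
#' @param values Numeric vector of samples.
#' @param class_label Class label inherited from the recording.
#' @param recording_id Source recording.
#' @param anchor_onset_s S1 onset (seconds) at which the frame starts.
#' @param normalized Whether values are already min-max normalized.
#' @return An object of class `pcg_frame`.
#' @export
pcg_frame <- function(values, class_label = NA, recording_id = NA,
                      anchor_onset_s = NA, normalized = FALSE) {
  structure(list(values = values, class_label = class_label,
                 recording_id = recording_id, anchor_onset_s = anchor_onset_s,
                 normalized = normalized), class = "pcg_frame")
}

#' Min-max normalize a frame to \[0, 1\]
#'
#' Maps each sample x to (x - min) / (max - min). A constant frame (max equal
#' to min) maps to all zeros rather than dividing by zero; such frames are
#' degenerate and carry no waveform information. The map is idempotent and
#' invariant under positive affine rescaling of the input.
#'
#' @param frame A `pcg_frame` (or bare numeric vector).
#' @return The normalized frame (same type as the input).
#' @export
normalize_frame <- function(frame) {
  if (is.numeric(frame)) {
    if (!length(frame)) stopf("cannot normalize an empty frame")
    return(minmax01(frame))
  }
  stopifnot(inherits(frame, "pcg_frame"))
  if (!length(frame$values)) stopf("cannot normalize an empty frame")
  frame$values <- minmax01(frame$values)
  frame$normalized <- TRUE
  frame
}
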