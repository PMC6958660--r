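# Period-synchronous framing: fixed-length frames anchored at successive S1
# onsets. With the default 1.6 s frame and 0.6-0.8 s cycles each frame spans
# about two cardiac cycles, so consecutive frames overlap by
# frame_length - cycle_length; with 0.8 s frames the overlap vanishes.

#' Cut fixed-length frames anchored at S1 onsets
#'
#' One candidate frame per onset, starting at sample `floor(onset_s * rate)`
#' (0-based, half-open) and spanning exactly `round(frame_length_s * rate)`
#' samples. Candidates running past the end of the recording are dropped, not
#' padded: padding would distort the min-max normalization applied later.
#'
#' @param recording A `pcg_recording` at the working rate.
#' @param s1_onsets_s Ascending S1 onset times (seconds).
#' @param frame_length_s Frame length in seconds (1.6 s default protocol;
#'   0.8 s alternative).
#' @return List of un-normalized `pcg_frame` objects (possibly empty).
#' @export
segment_frames <- function(recording, s1_onsets_s, frame_length_s = 1.6) {
  if (is.unsorted(s1_onsets_s, strictly = TRUE) && length(s1_onsets_s) > 1)
    stopf("s1_onsets_s must be strictly increasing")
  fs <- recording$sampling_rate_hz
  L <- round(frame_length_s * fs)
  n <- length(recording$samples)
  frames <- list()
  for (on in s1_onsets_s) {
    start <- floor(on * fs)  # 0-based
    if (start + L > n) next
    frames[[length(frames) + 1L]] <- pcg_frame(
      recording$samples[start + seq_len(L)],
      class_label = recording$class_label,
      recording_id = recording$recording_id,
      anchor_onset_s = on)
  }
  frames
}

#' Build a normalized frame dataset from recordings
#'
#' Chains S1-onset marking (detected via the fitted segmenter, or the stored
#' ground-truth onsets), period-synchronous framing, and per-frame min-max
#' normalization. Provenance (recording id, anchor onset) is retained per
#' frame.
#'
#' @param recordings List of `pcg_recording` at the working rate.
#' @param frame_length_s Frame length in seconds.
#' @param onset_source `"truth"` uses each recording's `true_s1_onsets_s`;
#'   `"detected"` runs [mark_s1_onsets()] with `hsmm_model`.
#' @param hsmm_model A fitted [fit_hsmm()] model (required for
#'   `onset_source = "detected"`).
#' @return A `frame_dataset`: list with matrix `x` (frames in rows), integer
#'   `y` (1 = normal, 2 = HFpEF, 3 = HFrEF), `meta` data frame (provenance),
#'   `frame_length_s`, `target_rate_hz`, `class_counts`.
#' @export
build_dataset <- function(recordings, frame_length_s = 1.6,
                          onset_source = c("truth", "detected"),
                          hsmm_model = NULL) {
  onset_source <- match.arg(onset_source)
  if (!length(recordings)) stopf("recordings must be non-empty")
  fs <- recordings[[1]]$sampling_rate_hz
  L <- round(frame_length_s * fs)
  rows <- list(); labs <- character(0); meta <- list()
  for (rec in recordings) {
    ons <- if (onset_source == "truth") rec$true_s1_onsets_s else {
      if (is.null(hsmm_model)) stopf("onset_source 'detected' needs hsmm_model")
      mark_s1_onsets(rec, hsmm_model)$s1_onsets_s
    }
    if (!length(ons)) {
      message(sprintf("recording %s: no S1 onsets, no frames emitted",
                      rec$recording_id))
      next
    }
    frs <- segment_frames(rec, ons, frame_length_s)
    if (!length(frs)) {
      message(sprintf("recording %s: all candidate frames overran the end",
                      rec$recording_id))
      next
    }
    for (fr in frs) {
      rows[[length(rows) + 1L]] <- normalize_frame(fr$values)
      labs <- c(labs, as.character(fr$class_label))
      meta[[length(meta) + 1L]] <- data.frame(
        recording_id = fr$recording_id, anchor_onset_s = fr$anchor_onset_s)
    }
  }
  if (!length(rows)) stopf("no frames could be segmented from any recording")
  x <- do.call(rbind, rows)
  y <- match(labs, PCG_CLASSES)
  structure(list(
    x = x, y = y, meta = do.call(rbind, meta),
    frame_length_s = frame_length_s, target_rate_hz = fs,
    class_counts = table(factor(labs, levels = PCG_CLASSES))
  ), class = "frame_dataset")
}

#' @export
print.frame_dataset <- function(x, ...) {
  cat(sprintf("<frame_dataset> %d frames x %d samples (%.1f s at %g Hz)\n",
              nrow(x$x), ncol(x$x), x$frame_length_s, x$target_rate_hz))
  print(x$class_counts)
  invisible(x)
}
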