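# Audio and sidecar I/O, pipeline configuration, report serialization.
#
# WAV dialect: RIFF, mono, PCM-16 (default) or IEEE float-32. Sample index 0
# is time 0.0 s; onset times are seconds; state intervals are half-open.
# Onset sidecars are tab-separated text with a header row:
#   recording_id  component  onset_seconds  class_label

#' Write a recording to a mono WAV file (plus optional onset sidecar)
#'
#' @param recording A `pcg_recording`; samples are clipped to \[-1, 1\] for
#'   PCM output.
#' @param path Output WAV path.
#' @param format `"pcm16"` (default) or `"float32"`.
#' @param sidecar If `TRUE`, also write `<path>.onsets.tsv` with the
#'   recording's labelled S1/S2 onsets.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("pcm16", "float32"),
                            sidecar = FALSE) {
  format <- match.arg(format)
  x <- recording$samples
  fs <- as.integer(round(recording$sampling_rate_hz))
  con <- file(path, "wb")
  on.exit(close(con))
  bits <- if (format == "pcm16") 16L else 32L
  block <- bits / 8L
  data_len <- length(x) * block
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(round(pmin(pmax(x, -1), 1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  if (sidecar) write_onsets(recording, paste0(path, ".onsets.tsv"))
  invisible(path)
}

#' Write an onset sidecar file
#' @param recording A `pcg_recording` with labelled onsets.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_onsets <- function(recording, path) {
  df <- rbind(
    data.frame(recording_id = recording$recording_id, component = "S1",
               onset_seconds = recording$true_s1_onsets_s,
               class_label = recording$class_label),
    data.frame(recording_id = recording$recording_id, component = "S2",
               onset_seconds = recording$true_s2_onsets_s,
               class_label = recording$class_label)
  )
  df <- df[order(df$onset_seconds, df$component), ]
  utils::write.table(format(df, digits = 10, scientific = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_wav_raw <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) stopf("not a RIFF file: %s", path)
  readBin(con, "integer", size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stopf("not a WAVE file: %s", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    len <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, "integer", size = 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", size = 2, endian = "little"),
        rate = readBin(con, "integer", size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", size = 4, endian = "little"),
        block = readBin(con, "integer", size = 2, endian = "little"),
        bits = readBin(con, "integer", size = 2, endian = "little"))
      if (len > 16) readBin(con, "raw", n = len - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stopf("malformed WAV: data before fmt chunk")
      data <- readBin(con, "raw", n = len)
      break
    } else {
      readBin(con, "raw", n = len + len %% 2)
    }
  }
  if (is.null(fmt) || is.null(data)) stopf("malformed WAV: %s", path)
  fmt$data <- data
  fmt
}

#' Read a mono WAV recording, attaching onset labels when a sidecar exists
#'
#' @param path WAV file path.
#' @param sidecar Path of the onset sidecar; default `<path>.onsets.tsv`.
#'   A missing sidecar gives a recording with empty onset lists.
#' @param multichannel `"error"` (default) rejects multi-channel input;
#'   `"average"` mixes channels down to mono.
#' @return A `pcg_recording` with samples in \[-1, 1\].
#' @export
read_recording <- function(path, sidecar = paste0(path, ".onsets.tsv"),
                           multichannel = c("error", "average")) {
  multichannel <- match.arg(multichannel)
  w <- read_wav_raw(path)
  if (w$code == 1) {
    x <- readBin(w$data, "integer", n = length(w$data) / 2, size = 2,
                 endian = "little") / 32767
  } else if (w$code == 3) {
    x <- readBin(w$data, "numeric", n = length(w$data) / 4, size = 4,
                 endian = "little")
  } else stopf("unsupported WAV format code %d (PCM-16 or float-32 only)", w$code)
  if (w$channels > 1) {
    if (multichannel == "error")
      stopf("%s has %d channels; mono required (or multichannel = 'average')",
            path, w$channels)
    x <- rowMeans(matrix(x, ncol = w$channels, byrow = TRUE))
  }
  rec_id <- sub("\\.wav$", "", basename(path), ignore.case = TRUE)
  s1 <- numeric(0); s2 <- numeric(0); cls <- NA
  if (!is.null(sidecar) && file.exists(sidecar)) {
    lab <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("recording_id", "component", "onset_seconds", "class_label")
    if (!all(need %in% names(lab)))
      stopf("sidecar %s lacks columns: %s", sidecar,
            paste(setdiff(need, names(lab)), collapse = ", "))
    if (!all(lab$recording_id == lab$recording_id[1]))
      stopf("sidecar %s mixes recording ids", sidecar)
    for (comp in c("S1", "S2")) {
      on <- lab$onset_seconds[lab$component == comp]
      bad <- which(diff(on) <= 0)
      if (length(bad))
        stopf("sidecar %s: %s onsets not strictly increasing at row %d",
              sidecar, comp, bad[1] + 1L)
    }
    s1 <- lab$onset_seconds[lab$component == "S1"]
    s2 <- lab$onset_seconds[lab$component == "S2"]
    cls <- lab$class_label[1]
    rec_id <- lab$recording_id[1]
  }
  pcg_recording(x, w$rate, class_label = cls, s1_onsets_s = s1,
                s2_onsets_s = s2, recording_id = rec_id)
}

#' Default pipeline configuration
#'
#' The working sampling rate is 600 Hz (comfortably above twice the 250 Hz
#' upper edge of the S2 band), frames are 1.6 s (about two cardiac cycles;
#' 0.8 s is the supported alternative), and evaluation uses stratified
#' tenfold cross-validation with 20% of each training fold held out for
#' validation.
#'
#' @return A named list of class `pcg_config`.
#' @export
default_config <- function() {
  structure(list(
    target_rate_hz = 600, frame_length_s = 1.6, model_name = "gru",
    n_layers = 2L, units = 64L, learning_rate = 0.001, l2_lambda = 1e-4,
    batch_size = 64L, epochs = 50L, input_chunk = 1L,
    cv_folds = 10L, validation_fraction_of_train = 0.2,
    stratified = TRUE, grouping = "frame", onset_source = "detected",
    seed = 1L
  ), class = "pcg_config")
}

validate_config <- function(cfg) {
  if (cfg$target_rate_hz <= 2 * 250)
    stopf("target_rate_hz must exceed 500 Hz (Nyquist for the 250 Hz S2 band)")
  if (cfg$frame_length_s <= 0) stopf("frame_length_s must be positive")
  if (cfg$cv_folds < 2) stopf("cv_folds must be >= 2")
  if (cfg$validation_fraction_of_train <= 0 || cfg$validation_fraction_of_train >= 1)
    stopf("validation_fraction_of_train must be in (0, 1)")
  cfg
}

#' Load a pipeline configuration from a YAML key-value file
#'
#' Keys absent from the file keep their defaults; unknown keys are rejected
#' with a message listing the valid ones.
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `pcg_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("no such config file: %s", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stopf("unknown config keys: %s\nvalid keys: %s",
            paste(unknown, collapse = ", "), paste(names(cfg), collapse = ", "))
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  validate_config(cfg)
}

#' Save a pipeline configuration
#' @param cfg A `pcg_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Save a cross-validation report
#'
#' Writes `<stem>_folds.tsv` (per-fold accuracies), `<stem>_confusion.tsv`
#' (pooled confusion matrix, rows = true classes) and `<stem>_summary.json`
#' (machine-readable summary).
#' @param report A `cv_report` from [evaluate_model()].
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
save_report <- function(report, stem) {
  utils::write.table(
    data.frame(fold = seq_along(report$fold_accuracy),
               accuracy = sprintf("%.6f", report$fold_accuracy)),
    paste0(stem, "_folds.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- report$confusion
  utils::write.table(data.frame(true = rownames(cm), cm, check.names = FALSE),
                     paste0(stem, "_confusion.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(
    model = report$model_name, mean_accuracy = report$mean_accuracy,
    sd_accuracy = report$sd_accuracy, fold_accuracy = report$fold_accuracy,
    precision = as.list(report$precision), recall = as.list(report$recall),
    manifest = report$manifest
  ), paste0(stem, "_summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stem)
}
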