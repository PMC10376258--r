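#' Multi-channel surface-EMG recording
#'
#' A `recording` is a time-by-channel numeric matrix with a sampling rate,
#' a subject identifier and a per-channel anatomical role tag. The default
#' montage is five bipolar channels: four over the forearm flexor/extensor
#' bellies plus one over the thenar eminence.
#'
#' @param samples Numeric matrix, time in rows, channels in columns.
#' @param fs Sampling rate in Hz (> 0).
#' @param subject_id Subject identifier (scalar, coerced to character).
#' @param channel_roles Character vector of per-channel tags, one of
#'   `"flexor"`, `"extensor"`, `"thenar"`; recycled defaults cover the
#'   five-channel montage.
#' @return An object of class `emg_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(2000), ncol = 2), fs = 1000,
#'                  channel_roles = c("flexor", "extensor"))
#' dim(rec$samples)
#' @export
recording <- function(samples, fs, subject_id = "S01",
                      channel_roles = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (ncol(samples) < 1L) abort_config("a recording needs >= 1 channel")
  if (!all(is.finite(samples))) abort_config("recording samples must all be finite")
  fs <- check_number(fs, "fs", lo = 1e-9)
  if (is.null(channel_roles)) {
    channel_roles <- default_channel_roles(ncol(samples))
  }
  channel_roles <- match.arg(channel_roles, c("flexor", "extensor", "thenar"),
                             several.ok = TRUE)
  if (length(channel_roles) != ncol(samples))
    abort_config("channel_roles length must equal the channel count")
  structure(
    list(samples = samples, fs = fs, subject_id = as.character(subject_id)[1],
         channel_roles = channel_roles),
    class = "emg_recording")
}

default_channel_roles <- function(n_channels) {
  base <- c("flexor", "flexor", "extensor", "extensor", "thenar")
  if (n_channels <= 5L) base[seq_len(n_channels)]
  else c(base, rep_len(c("flexor", "extensor"), n_channels - 5L))
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> subject %s: %d samples x %d channels @ %g Hz (%.2f s)\n",
              x$subject_id, nrow(x$samples), ncol(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  cat("  roles:", paste(x$channel_roles, collapse = ", "), "\n")
  invisible(x)
}

gesture_classes <- function() {
  c("fist", "pinch", "wrist_flexion", "wrist_extension",
    "palm_open", "thumb", "rest")
}

#' Labelled gesture segment
#'
#' A windowed excerpt of a recording with its gesture-class label. The seven
#' classes are the six hand gestures (fist, pinch, wrist flexion/extension,
#' palm open, thumb) plus rest.
#'
#' @param window Numeric matrix (time x channels).
#' @param label One of the seven gesture classes.
#' @param subject_id Subject identifier.
#' @param onset_index Sample index of the window start in its source
#'   recording (>= 0, 0-based by convention).
#' @param channel_roles Optional per-channel role tags.
#' @param fs Sampling rate of the source recording, in Hz.
#' @return An object of class `emg_segment`.
#' @export
segment <- function(window, label, subject_id = "S01", onset_index = 0,
                    channel_roles = NULL, fs = 1000) {
  window <- as.matrix(window)
  storage.mode(window) <- "double"
  if (nrow(window) < 2L) abort_config("a segment window needs >= 2 samples")
  label <- match.arg(label, gesture_classes())
  onset_index <- check_number(onset_index, "onset_index", lo = 0)
  if (is.null(channel_roles)) channel_roles <- default_channel_roles(ncol(window))
  structure(
    list(window = window, label = label, subject_id = as.character(subject_id)[1],
         onset_index = onset_index, channel_roles = channel_roles, fs = fs),
    class = "emg_segment")
}

#' @export
print.emg_segment <- function(x, ...) {
  cat(sprintf("<emg_segment> %s (subject %s): %d samples x %d channels @ %g Hz\n",
              x$label, x$subject_id, nrow(x$window), ncol(x$window), x$fs))
  invisible(x)
}

#' Write a recording to a delimited file
#'
#' The interchange format is a UTF-8 CSV whose header row carries the channel
#' roles; the sampling rate and subject id go to a JSON sidecar
#' (`<path>.json`) so the file round-trips without loss.
#'
#' @param rec An `emg_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  df <- as.data.frame(rec$samples)
  names(df) <- make.unique(rec$channel_roles, sep = ".")
  readr::write_csv(df, path, progress = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, subject_id = rec$subject_id,
         channel_roles = rec$channel_roles),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from a delimited file
#'
#' Expects one header row of channel roles and one numeric column per
#' channel. The sampling rate comes from the JSON sidecar written by
#' [write_recording()] or from the `fs` argument.
#'
#' @param path CSV path.
#' @param fs Sampling rate in Hz; overrides the sidecar when given.
#' @param subject_id Subject id; overrides the sidecar when given.
#' @return An `emg_recording`.
#' @export
read_recording <- function(path, fs = NULL, subject_id = NULL) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  fs <- fs %||% meta$fs
  if (is.null(fs)) abort_format("sampling rate missing: no `fs` argument and no sidecar")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) abort_format("delimited recording needs a header row plus data")
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  ncol_exp <- length(header)
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  mat <- matrix(NA_real_, nrow = length(rows), ncol = ncol_exp)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != ncol_exp)
      abort_format(sprintf("ragged row %d: expected %d fields, found %d",
                           i, ncol_exp, length(r)))
    v <- suppressWarnings(as.numeric(r))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort_format(sprintf("non-numeric cell at row %d, field %d ('%s')",
                           i, bad, r[bad]))
    }
    mat[i, ] <- v
  }
  roles <- meta$channel_roles %||% sub("\\.[0-9]+$", "", header)
  recording(mat, fs = fs,
            subject_id = subject_id %||% (meta$subject_id %||% "S01"),
            channel_roles = roles)
}
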