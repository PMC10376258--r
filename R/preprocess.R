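#' Filtering specification
#'
#' Parameters of the standard surface-EMG cleaning chain: a zero-phase
#' Butterworth band-pass (default 4th order, 20-300 Hz), a Hampel despiking
#' filter (default window of 100 neighbouring samples, 2 robust standard
#' deviations), and RMS normalization to a target level.
#'
#' @param band Two-element Hz pass band (default `c(20, 300)`).
#' @param order Even Butterworth order (default 4).
#' @param hampel_window Hampel window length in samples (default 100).
#' @param hampel_nsigma Outlier threshold in robust SDs (default 2).
#' @param target_rms Target per-channel RMS after normalization (default 1).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(band = c(20, 300), order = 4, hampel_window = 100,
                        hampel_nsigma = 2, target_rms = 1) {
  order <- check_count(order, "order", min = 2L)
  if (order %% 2L != 0L) abort_config("`order` must be even")
  if (length(band) != 2L || !all(is.finite(band)) || band[1] <= 0 ||
      band[2] <= band[1])
    abort_config("`band` must satisfy 0 < low < high")
  hampel_window <- check_count(hampel_window, "hampel_window", min = 3L)
  structure(list(band = as.numeric(band), order = order,
                 hampel_window = hampel_window,
                 hampel_nsigma = check_number(hampel_nsigma, "hampel_nsigma", lo = 0),
                 target_rms = check_number(target_rms, "target_rms", lo = 1e-12)),
            class = "filter_spec")
}

#' Gesture-window detection specification
#'
#' Windows are locked to envelope power peaks: one third of the window falls
#' before the peak (the supremum border) and two thirds after (the infimum
#' border), with the window length clamped to the 30-60 ms analysis range.
#'
#' @param min_window_ms,max_window_ms Window length bounds in ms.
#' @param sup_fraction Fraction of the window before the peak (default 1/3).
#' @param inf_fraction Fraction after the peak (default 2/3).
#' @param envelope_window_ms Moving-RMS envelope window in ms (default 100).
#' @return A `detection_spec` list.
#' @export
detection_spec <- function(min_window_ms = 30, max_window_ms = 60,
                           sup_fraction = 1 / 3, inf_fraction = 2 / 3,
                           envelope_window_ms = 100) {
  if (min_window_ms <= 0 || max_window_ms < min_window_ms)
    abort_config("need 0 < min_window_ms <= max_window_ms")
  if (sup_fraction <= 0 || sup_fraction >= 1 || inf_fraction <= 0 ||
      inf_fraction >= 1)
    abort_config("fractions must lie in (0, 1)")
  structure(list(min_window_ms = min_window_ms, max_window_ms = max_window_ms,
                 sup_fraction = sup_fraction, inf_fraction = inf_fraction,
                 envelope_window_ms = envelope_window_ms),
            class = "detection_spec")
}

#' Zero-phase Butterworth band-pass
#'
#' Applies the designed band-pass forward and backward (zero phase, so burst
#' peak timing is preserved for the 30-60 ms windows) to every channel.
#'
#' @param rec An `emg_recording`.
#' @param spec A [filter_spec()].
#' @return The filtered `emg_recording` (same length).
#' @export
bandpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "emg_recording"))
  if (spec$band[2] >= rec$fs / 2)
    abort_config("band upper edge must be below Nyquist (fs/2)")
  # signal::butter follows the MATLAB convention: order n yields a 2n-order
  # band-pass, so n = order/2 gives the stated filter order.
  bf <- signal::butter(spec$order / 2, spec$band / (rec$fs / 2), type = "pass")
  out <- apply(rec$samples, 2, function(x) signal::filtfilt(bf, x))
  rec$samples <- matrix(out, nrow = nrow(rec$samples))
  rec
}

#' Hampel despiking filter
#'
#' Sliding-window outlier replacement: a sample deviating from the window
#' median by more than `nsigma` robust standard deviations (1.4826 x MAD) is
#' replaced by that median; all other samples pass unchanged.
#'
#' @inheritParams bandpass
#' @return The despiked `emg_recording`.
#' @export
hampel_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "emg_recording"))
  k <- max(1L, spec$hampel_window %/% 2L)
  rec$samples <- apply(rec$samples, 2, function(x) {
    if (length(x) <= 2L * k) return(x)
    pracma::hampel(x, k = k, t0 = spec$hampel_nsigma)$y
  })
  rec
}

#' RMS normalization
#'
#' Scales each channel so its root-mean-square equals `target_rms`.
#'
#' @inheritParams bandpass
#' @param target_rms Target RMS (default taken from `spec`).
#' @return The normalized `emg_recording`.
#' @export
rms_normalize <- function(rec, target_rms = 1) {
  stopifnot(inherits(rec, "emg_recording"))
  rms <- sqrt(colMeans(rec$samples^2))
  if (any(rms == 0)) {
    bad <- which(rms == 0)[1]
    abort_degenerate(sprintf("channel %d (%s) is all-zero; cannot RMS-normalize",
                             bad, rec$channel_roles[bad]))
  }
  rec$samples <- sweep(rec$samples, 2, rms / target_rms, "/")
  rec
}

moving_rms <- function(x, w) {
  w <- max(1L, as.integer(w))
  cs <- cumsum(c(0, x^2))
  n <- length(x)
  half <- w %/% 2L
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  sqrt((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
}

#' Detect gesture windows from the envelope
#'
#' Computes a per-sample moving-RMS envelope summed over channels, finds
#' local power peaks above an adaptive threshold (median + 3 x MAD of the
#' envelope), and emits one window per peak with `sup_fraction` of the
#' window before the peak and `inf_fraction` after, clamped to the
#' `[min_window_ms, max_window_ms]` range. Overlapping windows are resolved
#' in favour of the higher peak.
#'
#' @param rec A filtered, normalized `emg_recording`.
#' @param spec A [detection_spec()].
#' @return Tibble with columns `onset`, `length`, `peak`, `peak_value`,
#'   ordered by onset.
#' @export
detect_gestures <- function(rec, spec = detection_spec()) {
  stopifnot(inherits(rec, "emg_recording"))
  fs <- rec$fs
  env_w <- round(spec$envelope_window_ms * fs / 1000)
  n <- nrow(rec$samples)
  if (n < env_w) abort_config("recording shorter than one envelope window")
  env <- rowSums(apply(rec$samples, 2, moving_rms, w = env_w))
  thr <- stats::median(env) + 3 * stats::mad(env)
  win_n <- round(spec$max_window_ms * fs / 1000)
  win_n <- max(win_n, round(spec$min_window_ms * fs / 1000))
  min_sep <- env_w  # peaks closer than the envelope window merge
  above <- env > thr
  if (!any(above))
    return(tibble::tibble(onset = integer(), length = integer(),
                          peak = integer(), peak_value = numeric()))
  # local maxima of the envelope within supra-threshold runs
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peaks <- integer(); vals <- numeric()
  for (j in which(runs$values)) {
    seg <- starts[j]:ends[j]
    p <- seg[which.max(env[seg])]
    peaks <- c(peaks, p); vals <- c(vals, env[p])
  }
  # higher peak wins among close/overlapping candidates
  ord <- order(vals, decreasing = TRUE)
  keep <- logical(length(peaks))
  taken <- integer()
  for (j in ord) {
    if (!any(abs(peaks[j] - taken) < max(min_sep, win_n))) {
      keep[j] <- TRUE
      taken <- c(taken, peaks[j])
    }
  }
  peaks <- peaks[keep]; vals <- vals[keep]
  pre <- round(win_n * spec$sup_fraction)
  onset <- pmax(1L, pmin(peaks - pre, n - win_n + 1L))
  out <- tibble::tibble(onset = as.integer(onset),
                        length = as.integer(win_n),
                        peak = as.integer(peaks), peak_value = vals)
  dplyr::arrange(out, .data$onset)
}

#' Run the full preprocessing chain
#'
#' Fixed order: band-pass, Hampel despiking, RMS normalization, gesture
#' detection. Returns the cleaned recording together with detected windows.
#'
#' @param rec An `emg_recording`.
#' @param fspec A [filter_spec()].
#' @param dspec A [detection_spec()].
#' @return List with `recording` (cleaned) and `windows` (tibble from
#'   [detect_gestures()]).
#' @export
preprocess_recording <- function(rec, fspec = filter_spec(),
                                 dspec = detection_spec()) {
  rec <- bandpass(rec, fspec)
  rec <- hampel_filter(rec, fspec)
  rec <- rms_normalize(rec, fspec$target_rms)
  list(recording = rec, windows = detect_gestures(rec, dspec))
}
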