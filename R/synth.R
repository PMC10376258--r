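#' Synthetic hemiplegic-EMG generator configuration
#'
#' Configuration for the surrogate dataset that stands in for (non-deposited)
#' acute-stroke recordings: 19 subjects, 5 bipolar channels at 1000 Hz, six
#' hand gestures performed ten times each plus rest. Bursts are zero-mean
#' Gaussian noise band-limited to `burst_band` and amplitude-modulated by a
#' smooth envelope; each gesture class has a distinct per-channel activation
#' profile, attenuated toward the rest profile by `1 - severity`.
#'
#' @param n_subjects Number of subjects (default 19).
#' @param n_channels Number of channels (default 5: 2 flexor, 2 extensor,
#'   1 thenar).
#' @param fs Sampling rate in Hz (default 1000).
#' @param reps_per_gesture Bursts per gesture class per subject (default 10).
#' @param burst_band Two-element Hz band of burst energy (default 20-300).
#' @param subject_gain_sd SD of per-subject log-normal channel gains
#'   (default 0.15); models electrode placement / impedance variability.
#' @param crosstalk Off-diagonal channel-mixing weight in `[0, 1)`
#'   (default 0.05); models muscle-signal crosstalk.
#' @param severity Per-subject class-separability scaling in `[0, 1]`
#'   (scalar or length `n_subjects`; default 0.8). 0 collapses every gesture
#'   onto the rest profile; 1 gives fully expressed gesture profiles.
#' @param artifact_rate Spike artifacts per second (default 0).
#' @param burst_ms,gap_ms Burst duration and mean inter-burst gap in ms.
#' @param rest_amp Baseline (rest) amplitude, in the generator's arbitrary
#'   units (default 0.08).
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 19, n_channels = 5, fs = 1000,
                         reps_per_gesture = 10, burst_band = c(20, 300),
                         subject_gain_sd = 0.15, crosstalk = 0.05,
                         severity = 0.8, artifact_rate = 0,
                         burst_ms = 240, gap_ms = 320, rest_amp = 0.08,
                         seed = 1) {
  cfg <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_channels = check_count(n_channels, "n_channels"),
    fs = check_number(fs, "fs", lo = 1),
    reps_per_gesture = check_count(reps_per_gesture, "reps_per_gesture"),
    burst_band = burst_band,
    subject_gain_sd = check_number(subject_gain_sd, "subject_gain_sd", lo = 0),
    crosstalk = check_number(crosstalk, "crosstalk", lo = 0, hi = 1 - 1e-9),
    severity = severity,
    artifact_rate = check_number(artifact_rate, "artifact_rate", lo = 0),
    burst_ms = check_number(burst_ms, "burst_ms", lo = 30),
    gap_ms = check_number(gap_ms, "gap_ms", lo = 50),
    rest_amp = check_number(rest_amp, "rest_amp", lo = 1e-6),
    seed = check_count(seed, "seed", min = 0L))
  if (length(burst_band) != 2L || !all(is.finite(burst_band)) ||
      burst_band[1] <= 0 || burst_band[2] <= burst_band[1] ||
      burst_band[2] >= cfg$fs / 2)
    abort_config("burst_band must satisfy 0 < low < high < fs/2")
  sev <- rep_len(as.numeric(severity), cfg$n_subjects)
  if (!all(is.finite(sev)) || any(sev < 0) || any(sev > 1))
    abort_config("severity values must lie in [0, 1]")
  cfg$severity <- sev
  class(cfg) <- "synth_config"
  cfg
}

# Distinct per-channel activation profiles (arbitrary units). Gestures get a
# 3-bit on/off pattern cycled over channels so any >= 3-channel montage keeps
# all six gesture classes geometrically distinct from each other and rest.
class_profiles <- function(n_channels, rest_amp) {
  gestures <- setdiff(gesture_classes(), "rest")
  prof <- matrix(rest_amp, nrow = 7, ncol = n_channels,
                 dimnames = list(gesture_classes(), NULL))
  for (g in seq_along(gestures)) {
    bits <- as.integer(intToBits(g))[1:3]
    for (ch in seq_len(n_channels)) {
      b <- bits[((ch - 1L) %% 3L) + 1L]
      # mild channel taper keeps profiles non-collinear across gestures
      prof[gestures[g], ch] <- 0.30 + 0.80 * b + 0.06 * ((g * ch) %% 3)
    }
  }
  prof
}

band_limited_noise <- function(n, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  pad <- min(3 * fs, n)
  x <- stats::rnorm(n + 2 * pad)
  y <- signal::filtfilt(bf, x)
  y <- y[(pad + 1):(pad + n)]
  y / stats::sd(y)
}

#' Generate a synthetic hemiplegic-EMG dataset
#'
#' Builds one recording per subject containing `reps_per_gesture` bursts per
#' gesture class, in shuffled order, separated by rest spans, plus a
#' ground-truth annotation table (onset, duration, peak, label per burst).
#' Deterministic given the config seed.
#'
#' @param cfg A [synth_config()].
#' @return An `emg_dataset`: list with `recordings` (named list of
#'   `emg_recording`), `annotations` (tibble: subject_id, label, rep, onset,
#'   duration, peak), and the `config`.
#' @examples
#' ds <- generate_dataset(synth_config(n_subjects = 3, reps_per_gesture = 2))
#' nrow(ds$annotations)  # 3 subjects x 6 gestures x 2 reps
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    prof <- class_profiles(cfg$n_channels, cfg$rest_amp)
    gestures <- setdiff(gesture_classes(), "rest")
    burst_n <- round(cfg$burst_ms * cfg$fs / 1000)
    env <- 0.5 - 0.5 * cos(2 * pi * seq_len(burst_n) / (burst_n + 1))  # Hann
    mix <- diag(1 - cfg$crosstalk, cfg$n_channels)
    if (cfg$n_channels > 1L)
      mix[mix == 0] <- cfg$crosstalk / (cfg$n_channels - 1)
    recs <- list(); anns <- list()
    for (s in seq_len(cfg$n_subjects)) {
      sid <- sprintf("S%02d", s)
      gains <- exp(stats::rnorm(cfg$n_channels, 0, cfg$subject_gain_sd))
      sev <- cfg$severity[s]
      eff <- matrix(cfg$rest_amp, 7, cfg$n_channels,
                    dimnames = dimnames(prof))
      for (g in gestures)
        eff[g, ] <- cfg$rest_amp + sev * (prof[g, ] - cfg$rest_amp)
      order_g <- sample(rep(gestures, cfg$reps_per_gesture))
      gap_n <- function() round((cfg$gap_ms * stats::runif(1, 0.8, 1.25)) *
                                  cfg$fs / 1000)
      # plan onsets first so total length is known
      onsets <- integer(length(order_g)); pos <- gap_n()
      for (k in seq_along(order_g)) {
        onsets[k] <- pos
        pos <- pos + burst_n + gap_n()
      }
      n_total <- pos + round(cfg$gap_ms * cfg$fs / 1000)
      x <- matrix(0, n_total, cfg$n_channels)
      for (ch in seq_len(cfg$n_channels))
        x[, ch] <- band_limited_noise(n_total, cfg$fs, cfg$burst_band) *
          cfg$rest_amp * gains[ch]
      for (k in seq_along(order_g)) {
        g <- order_g[k]; i0 <- onsets[k]
        idx <- i0 + seq_len(burst_n)
        for (ch in seq_len(cfg$n_channels)) {
          amp <- (eff[g, ch] - cfg$rest_amp) * gains[ch]
          if (amp > 0)
            x[idx, ch] <- x[idx, ch] +
              env * amp * band_limited_noise(burst_n, cfg$fs, cfg$burst_band)
        }
      }
      x <- x %*% t(mix)
      if (cfg$artifact_rate > 0) {
        n_spk <- stats::rpois(1, cfg$artifact_rate * n_total / cfg$fs)
        if (n_spk > 0) {
          at <- sample(seq(51, n_total - 51), n_spk)
          for (t0 in at) {
            ch <- sample(cfg$n_channels, 1)
            loc <- sqrt(mean(x[(t0 - 50):(t0 + 50), ch]^2))
            x[t0, ch] <- x[t0, ch] + sample(c(-1, 1), 1) * 12 * max(loc, 1e-6)
          }
        }
      }
      recs[[sid]] <- recording(x, fs = cfg$fs, subject_id = sid,
                               channel_roles = default_channel_roles(cfg$n_channels))
      reps_seen <- stats::setNames(integer(length(gestures)), gestures)
      ann <- vector("list", length(order_g))
      for (k in seq_along(order_g)) {
        g <- order_g[k]
        reps_seen[g] <- reps_seen[g] + 1L
        ann[[k]] <- tibble::tibble(
          subject_id = sid, label = g, rep = reps_seen[[g]],
          onset = onsets[k], duration = burst_n,
          peak = onsets[k] + round(burst_n / 2))
      }
      anns[[sid]] <- dplyr::bind_rows(ann)
    }
    structure(list(recordings = recs,
                   annotations = dplyr::bind_rows(anns),
                   config = cfg),
              class = "emg_dataset")
  })
}

#' @export
print.emg_dataset <- function(x, ...) {
  cat(sprintf("<emg_dataset> %d subjects, %d annotated bursts, %d channels @ %g Hz\n",
              length(x$recordings), nrow(x$annotations),
              x$config$n_channels, x$config$fs))
  invisible(x)
}

#' Cut labelled segments out of a dataset
#'
#' Uses the ground-truth annotations to cut one fixed-length window per
#' burst, locked to the burst peak (one third of the window before the peak,
#' two thirds after), and samples an equal number of rest windows per subject
#' from the inter-burst spans, yielding seven balanced classes.
#'
#' @param ds An `emg_dataset` from [generate_dataset()].
#' @param window_ms Window length in ms (default 48, inside the 30-60 ms
#'   analysis range).
#' @param sup_fraction Fraction of the window placed before the peak
#'   (default 1/3).
#' @param rest_per_subject Rest windows per subject (default: one per
#'   gesture repetition, balancing the class design).
#' @return List of `emg_segment` objects.
#' @export
segment_dataset <- function(ds, window_ms = 48, sup_fraction = 1 / 3,
                            rest_per_subject = NULL) {
  stopifnot(inherits(ds, "emg_dataset"))
  fs <- ds$config$fs
  win_n <- max(2L, round(window_ms * fs / 1000))
  pre <- round(win_n * sup_fraction)
  rest_k <- rest_per_subject %||% ds$config$reps_per_gesture
  segs <- list()
  with_seed(ladder_seed(ds$config$seed, 777L), {
    for (sid in names(ds$recordings)) {
      rec <- ds$recordings[[sid]]
      ann <- ds$annotations[ds$annotations$subject_id == sid, ]
      n <- nrow(rec$samples)
      occupied <- rep(FALSE, n)
      for (i in seq_len(nrow(ann))) {
        a0 <- max(1L, ann$onset[i] - win_n)
        a1 <- min(n, ann$onset[i] + ann$duration[i] + win_n)
        occupied[a0:a1] <- TRUE
        i0 <- ann$peak[i] - pre
        i0 <- max(1L, min(i0, n - win_n + 1L))
        segs[[length(segs) + 1L]] <- segment(
          rec$samples[i0:(i0 + win_n - 1L), , drop = FALSE],
          label = ann$label[i], subject_id = sid, onset_index = i0 - 1L,
          channel_roles = rec$channel_roles, fs = fs)
      }
      free <- which(!occupied)
      free <- free[free <= n - win_n]
      # keep rest windows wholly inside quiet spans
      ok <- free[vapply(free, function(i0) !any(occupied[i0:(i0 + win_n - 1L)]),
                        logical(1))]
      if (length(ok) >= 1L) {
        starts <- sort(sample(ok, min(rest_k, length(ok))))
        for (i0 in starts)
          segs[[length(segs) + 1L]] <- segment(
            rec$samples[i0:(i0 + win_n - 1L), , drop = FALSE],
            label = "rest", subject_id = sid, onset_index = i0 - 1L,
            channel_roles = rec$channel_roles, fs = fs)
      }
    }
  })
  segs
}

#' Write / read ground-truth annotations as JSON
#'
#' @param annotations Tibble as in `emg_dataset$annotations`.
#' @param path JSON path.
#' @return `path` (write) or the annotation tibble (read).
#' @export
write_annotations <- function(annotations, path) {
  jsonlite::write_json(annotations, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
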