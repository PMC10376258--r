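#' Extract a feature matrix from labelled segments
#'
#' Applies the selected registry features to every segment: per-channel
#' features are computed on each channel and concatenated in registry order
#' times channel order; spatial (SD) features are computed once per segment
#' from the role-tagged channels. Column provenance (feature, channel,
#' domain) is recorded in the `feature_map` attribute.
#'
#' @param segments List of `emg_segment` objects sharing a channel count.
#' @param features Character vector of feature names (default: the full
#'   registry). An empty selection is an error.
#' @param registry A [feature_registry()].
#' @return A `feature_matrix` tibble: columns `segment`, `subject`, `label`
#'   followed by one numeric column per feature dimension, with attribute
#'   `feature_map` (tibble: column, feature, channel, domain).
#' @examples
#' ds <- generate_dataset(synth_config(n_subjects = 3, reps_per_gesture = 2))
#' fm <- extract_features(segment_dataset(ds), features = c("MAV", "WL"))
#' dim(fm)
#' @export
extract_features <- function(segments, features = NULL,
                             registry = feature_registry()) {
  if (length(segments) == 0L) abort_config("no segments to extract from")
  stopifnot(all(vapply(segments, inherits, logical(1), "emg_segment")))
  features <- features %||% registry$specs$name
  features <- resolve_features(features, registry)
  specs <- registry$specs[match(features, registry$specs$name), ]
  n_ch <- ncol(segments[[1]]$window)
  if (!all(vapply(segments, function(s) ncol(s$window) == n_ch, logical(1))))
    abort_config("all segments must share the same channel count")

  map <- list()
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    if (sp$kind == "spatial") {
      map[[length(map) + 1L]] <- tibble::tibble(
        column = sp$name, feature = sp$name, channel = NA_integer_,
        domain = sp$domain)
    } else {
      for (ch in seq_len(n_ch)) {
        cols <- if (sp$arity == 1L) sprintf("%s_ch%d", sp$name, ch)
                else sprintf("%s_ch%d_%d", sp$name, ch, seq_len(sp$arity))
        map[[length(map) + 1L]] <- tibble::tibble(
          column = cols, feature = sp$name, channel = ch, domain = sp$domain)
      }
    }
  }
  map <- dplyr::bind_rows(map)

  values <- matrix(NA_real_, nrow = length(segments), ncol = nrow(map),
                   dimnames = list(NULL, map$column))
  for (si in seq_along(segments)) {
    seg <- segments[[si]]
    ctxs <- lapply(seq_len(n_ch), function(ch) new.env(parent = emptyenv()))
    col <- 1L
    for (i in seq_len(nrow(specs))) {
      sp <- specs[i, ]; fn <- sp$fn[[1]]
      v <- tryCatch({
        if (sp$kind == "spatial") fn(seg$window, seg$channel_roles)
        else unlist(lapply(seq_len(n_ch), function(ch)
          fn(seg$window[, ch], seg$fs, ctxs[[ch]])))
      }, error = function(e) {
        stop(sprintf("feature %s failed on segment %d (%s, subject %s): %s",
                     sp$name, si, seg$label, seg$subject_id,
                     conditionMessage(e)), call. = FALSE)
      })
      nv <- if (sp$kind == "spatial") 1L else sp$arity * n_ch
      if (length(v) != nv || !all(is.finite(v)))
        stop(sprintf("feature %s returned a non-finite or wrong-length value on segment %d",
                     sp$name, si), call. = FALSE)
      values[si, col:(col + nv - 1L)] <- v
      col <- col + nv
    }
  }
  out <- tibble::tibble(
    segment = seq_along(segments),
    subject = vapply(segments, function(s) s$subject_id, character(1)),
    label = vapply(segments, function(s) s$label, character(1)))
  out <- dplyr::bind_cols(out, tibble::as_tibble(values))
  attr(out, "feature_map") <- map
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Column provenance of a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @return The `feature_map` tibble (column, feature, channel, domain).
#' @export
feature_map <- function(fm) {
  m <- attr(fm, "feature_map", exact = TRUE)
  if (is.null(m)) abort_config("not a feature_matrix: missing feature_map")
  m
}

# Data columns belonging to a set of feature names.
feature_columns <- function(fm, features) {
  m <- feature_map(fm)
  keep <- m$column[normalize_feature_name(m$feature) %in%
                     normalize_feature_name(features)]
  if (length(keep) == 0L)
    abort_config(sprintf("no matrix columns for features: %s",
                         paste(features, collapse = ", ")))
  keep
}

#' Persist / load a feature matrix as CSV + JSON sidecar
#'
#' The CSV holds the data columns; the sidecar records the provenance map.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV path.
#' @return `path` (write) or the restored `feature_matrix` (read).
#' @export
write_feature_matrix <- function(fm, path) {
  readr::write_csv(tibble::as_tibble(fm), path, progress = FALSE)
  jsonlite::write_json(feature_map(fm), paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  map <- tibble::as_tibble(jsonlite::read_json(paste0(path, ".json"),
                                               simplifyVector = TRUE))
  attr(out, "feature_map") <- map
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Simulate a feature matrix with planted informative features
#'
#' Bypasses signal synthesis and plants class information directly at the
#' feature level: `n_informative` features carry class-dependent means
#' designed so that every informative feature is needed to keep all seven
#' classes separable (dropping feature k collapses class k onto the
#' all-quiet class), while `n_noise` features are pure subject+measurement
#' noise. Used for search-recovery experiments.
#'
#' @param n_subjects Subjects (default 10).
#' @param reps Instances per class per subject (default 3).
#' @param n_informative Planted informative features (default 5, max 5).
#' @param n_noise Noise features (default 20).
#' @param separation Class-mean separation in noise-SD units (default 2).
#' @param noise_sd Within-instance noise SD (default 1).
#' @param subject_sd Between-subject offset SD (default 0.3).
#' @param seed Integer seed.
#' @return A `feature_matrix` tibble with features named `INF1..` and
#'   `NOISE1..` (all tagged domain TD, channel 1).
#' @export
simulate_feature_matrix <- function(n_subjects = 10, reps = 3,
                                    n_informative = 5, n_noise = 20,
                                    separation = 2, noise_sd = 1,
                                    subject_sd = 0.3, seed = 1) {
  n_informative <- check_count(n_informative, "n_informative")
  if (n_informative > 5L) abort_config("n_informative is capped at 5")
  n_noise <- check_count(n_noise, "n_noise")
  classes <- gesture_classes()
  # class k (k <= 5) expresses informative feature k; class 6 is all-quiet;
  # class 7 expresses every informative feature at 60%.
  mu <- matrix(0, length(classes), n_informative)
  for (k in seq_len(min(5L, n_informative))) mu[k, k] <- separation
  mu[7, ] <- 0.6 * separation
  feats <- c(sprintf("INF%d", seq_len(n_informative)),
             sprintf("NOISE%d", seq_len(n_noise)))
  with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      off <- stats::rnorm(length(feats), 0, subject_sd)
      for (ci in seq_along(classes)) for (r in seq_len(reps)) {
        v <- c(mu[ci, ], rep(0, n_noise)) + off +
          stats::rnorm(length(feats), 0, noise_sd)
        rows[[length(rows) + 1L]] <- c(v)
      }
    }
    values <- do.call(rbind, rows)
    colnames(values) <- feats
    out <- tibble::tibble(
      segment = seq_len(nrow(values)),
      subject = rep(sprintf("S%02d", seq_len(n_subjects)),
                    each = length(classes) * reps),
      label = rep(rep(classes, each = reps), n_subjects))
    out <- dplyr::bind_cols(out, tibble::as_tibble(values))
    attr(out, "feature_map") <- tibble::tibble(
      column = feats, feature = feats, channel = 1L, domain = "TD")
    class(out) <- c("feature_matrix", class(out))
    out
  })
}
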