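# Time-domain (TD) feature extractors. Each extractor maps one channel's
# window `x` (plus fs and a per-channel cache environment `ctx`) to a fixed
# length numeric vector. Amplitude thresholds (ZC/SSC/WAMP/MYOP) default to
# 0.01 x window RMS so they survive RMS normalization.

rel_threshold <- function(x, frac = 0.01) frac * sqrt(mean(x^2))

check_segment_length <- function(x, min_len = 2L, feature = "feature") {
  if (length(x) < min_len)
    abort_degenerate(sprintf("%s needs >= %d samples, got %d",
                             feature, min_len, length(x)))
}

log_scale <- function(v, eps_scale = 1) sign(v) * log1p(abs(v) / eps_scale)

feat_mav   <- function(x, fs, ctx) mean(abs(x))
feat_iemg  <- function(x, fs, ctx) sum(abs(x))
feat_rms   <- function(x, fs, ctx) sqrt(mean(x^2))
feat_var   <- function(x, fs, ctx) sum(x^2) / (length(x) - 1)
feat_ssi   <- function(x, fs, ctx) sum(x^2)
feat_wl    <- function(x, fs, ctx) sum(abs(diff(x)))
feat_meanv <- function(x, fs, ctx) mean(x)
feat_stdv  <- function(x, fs, ctx) stats::sd(x)
feat_medav <- function(x, fs, ctx) stats::median(abs(x))
feat_madv  <- function(x, fs, ctx) stats::mad(x)
feat_iqrv  <- function(x, fs, ctx) unname(diff(stats::quantile(x, c(.25, .75))))
feat_pkamp <- function(x, fs, ctx) max(abs(x))
feat_rng   <- function(x, fs, ctx) max(x) - min(x)
feat_covv  <- function(x, fs, ctx) stats::sd(x) / (abs(mean(x)) + 1e-12)

feat_zc <- function(x, fs, ctx, threshold = rel_threshold(x)) {
  n <- length(x)
  sum(x[-n] * x[-1] < 0 & abs(x[-n] - x[-1]) > threshold)
}

feat_ssc <- function(x, fs, ctx, threshold = rel_threshold(x)) {
  if (length(x) < 3L) return(0)
  xm <- x[2:(length(x) - 1)]
  sum((xm - x[1:(length(x) - 2)]) * (xm - x[3:length(x)]) > threshold)
}

feat_wamp <- function(x, fs, ctx, threshold = rel_threshold(x)) {
  sum(abs(diff(x)) > threshold)
}

feat_myop <- function(x, fs, ctx, threshold = rel_threshold(x, 0.5)) {
  mean(abs(x) > threshold)
}

mmav_weighted <- function(x, w) sum(w * abs(x)) / length(x)

feat_mmav1 <- function(x, fs, ctx) {
  n <- length(x); i <- seq_len(n)
  w <- ifelse(i >= 0.25 * n & i <= 0.75 * n, 1, 0.5)
  mmav_weighted(x, w)
}

feat_mmav2 <- function(x, fs, ctx) {
  n <- length(x); i <- seq_len(n)
  w <- ifelse(i < 0.25 * n, 4 * i / n,
              ifelse(i > 0.75 * n, 4 * (n - i) / n, 1))
  mmav_weighted(x, w)
}

# MMAV5: raised-cosine (Hann) weighted MAV, the smooth-window member of the
# modified-MAV family.
feat_mmav5 <- function(x, fs, ctx) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  mmav_weighted(x, w)
}

feat_ewl   <- function(x, fs, ctx) sum(abs(diff(x))^0.75)
feat_damv  <- function(x, fs, ctx) sum(abs(diff(x))) / (length(x) - 1)
feat_aac   <- function(x, fs, ctx) sum(abs(diff(x))) / length(x)
feat_dasdv <- function(x, fs, ctx) sqrt(sum(diff(x)^2) / (length(x) - 1))
feat_log   <- function(x, fs, ctx) exp(mean(log(abs(x) + 1e-12)))
feat_tm3   <- function(x, fs, ctx) abs(mean(x^3))
feat_tm4   <- function(x, fs, ctx) mean(x^4)
feat_tm5   <- function(x, fs, ctx) abs(mean(x^5))
feat_vord  <- function(x, fs, ctx) mean(abs(x)^3)^(1 / 3)
feat_msr   <- function(x, fs, ctx) sum(sqrt(abs(x))) / length(x)
feat_rsm0  <- function(x, fs, ctx) sqrt(sum(x^2))
feat_rsd1  <- function(x, fs, ctx) sqrt(sum(diff(x)^2))
feat_rsd2  <- function(x, fs, ctx) sqrt(sum(diff(diff(x))^2))
feat_rog   <- function(x, fs, ctx) sqrt(mean(diff(x)^2))
feat_mfl   <- function(x, fs, ctx) log10(sqrt(sum(diff(x)^2)) + 1e-12)

feat_mavslp <- function(x, fs, ctx) {
  n <- length(x); h <- n %/% 2L
  mean(abs(x[(h + 1L):n])) - mean(abs(x[1:h]))
}

feat_skew <- function(x, fs, ctx) {
  s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

feat_kurt <- function(x, fs, ctx) {
  s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^4) / s^4
}

# Normalized slope variability: variance of the first difference relative to
# the signal variance; scale-free roughness descriptor.
feat_nsv <- function(x, fs, ctx) {
  v <- stats::var(x)
  if (v == 0) abort_degenerate("NSV undefined for a constant segment")
  stats::var(diff(x)) / v
}

quantize_card <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  round(x / (0.05 * s))
}

feat_card  <- function(x, fs, ctx) length(unique(quantize_card(x)))
feat_crd   <- function(x, fs, ctx) length(unique(quantize_card(diff(x))))

feat_hist <- function(x, fs, ctx) {
  s <- stats::sd(x)
  if (s == 0) return(c(1, 0, 0))
  br <- c(-Inf, -s, s, Inf)
  as.numeric(table(cut(x, br))) / length(x)
}

# Hjorth descriptors: activity (variance), mobility, complexity.
feat_hja <- function(x, fs, ctx) stats::var(x)
feat_hjm <- function(x, fs, ctx) {
  v <- stats::var(x)
  if (v == 0) abort_degenerate("Hjorth mobility undefined for a constant segment")
  sqrt(stats::var(diff(x)) / v)
}
feat_hjc <- function(x, fs, ctx) {
  m0 <- feat_hjm(x, fs, ctx)
  if (m0 == 0) return(0)
  vd <- stats::var(diff(x))
  if (vd == 0) return(0)
  sqrt(stats::var(diff(diff(x))) / vd) / m0
}

window_energy <- function(x, w) sum((x * w)^2)

# Multiple Hamming / trapezoidal windows: total energy under three
# half-overlapping windows spanning the segment.
multi_window_energy <- function(x, shape = c("hamming", "trapezoid")) {
  shape <- match.arg(shape)
  n <- length(x)
  L <- max(4L, ceiling(n / 2))
  starts <- unique(round(seq(1, n - L + 1, length.out = 3)))
  w <- if (shape == "hamming") {
    0.54 - 0.46 * cos(2 * pi * seq_len(L) / (L + 1))
  } else {
    r <- ceiling(L / 4)
    c(seq(0, 1, length.out = r), rep(1, L - 2 * r), seq(1, 0, length.out = r))
  }
  sum(vapply(starts, function(s) window_energy(x[s:(s + L - 1)], w), numeric(1)))
}

feat_mhw <- function(x, fs, ctx) multi_window_energy(x, "hamming")
feat_mtw <- function(x, fs, ctx) multi_window_energy(x, "trapezoid")

#' Autoregressive coefficients (Burg method)
#'
#' Burg-method AR coefficients of one channel window; the short 30-60 ms
#' windows favour Burg over Yule-Walker for stability.
#'
#' @param x Numeric vector, length > 2 * `order`.
#' @param order Model order, 2 to 6.
#' @return Numeric vector of `order` coefficients (prediction convention:
#'   `x_t = sum a_k x_{t-k} + e_t`).
#' @export
ar_coefficients <- function(x, order) {
  order <- check_count(order, "order", min = 1L)
  check_segment_length(x, 2L * order + 1L, sprintf("AR%d", order))
  if (stats::sd(x) == 0)
    abort_degenerate(sprintf("AR%d undefined for a constant segment", order))
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  as.numeric(fit$ar)
}

#' Cepstral coefficients from an AR fit
#'
#' Standard LPC-to-cepstrum recursion applied to Burg AR coefficients.
#'
#' @param x Numeric vector.
#' @param order AR model order (default 4); also the number of cepstral
#'   coefficients returned.
#' @return Numeric vector of `order` cepstral coefficients.
#' @export
cepstral_coefficients <- function(x, order = 4) {
  a <- ar_coefficients(x, order)
  cc <- numeric(order)
  cc[1] <- a[1]
  if (order > 1) {
    for (m in 2:order) {
      s <- 0
      for (k in 1:(m - 1)) s <- s + (1 - k / m) * a[k] * cc[m - k]
      cc[m] <- a[m] + s
    }
  }
  cc
}

feat_ar <- function(order) {
  force(order)
  function(x, fs, ctx) ar_coefficients(x, order)
}
feat_cc <- function(x, fs, ctx) cepstral_coefficients(x, 4)
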