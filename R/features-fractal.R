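# Fractal / complexity (FRD) features.

#' Higuchi fractal dimension
#'
#' Estimates the curve's fractal dimension from the mean normalized length
#' of k-decimated sub-curves, via the slope of log L(k) against log(1/k).
#' Smooth curves approach 1, white noise approaches 2.
#'
#' @param x Numeric vector, length >= 10.
#' @param kmax Maximum decimation factor (default 8).
#' @return Fractal dimension estimate.
#' @export
higuchi_fd <- function(x, kmax = 8L) {
  check_segment_length(x, 10L, "HFD")
  n <- length(x)
  kmax <- min(kmax, n %/% 4L)
  lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2L) { lm[m] <- NA; next }
      nm <- length(idx) - 1L
      lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (nm * k) / k
    }
    lk[k] <- mean(lm, na.rm = TRUE)
  }
  ok <- lk > 0
  if (sum(ok) < 2L)
    abort_degenerate("HFD undefined: degenerate curve lengths")
  stats::coef(stats::lm(log(lk[ok]) ~ log(1 / seq_len(kmax)[ok])))[[2]]
}

#' Detrended fluctuation analysis exponent
#'
#' First-order DFA: the scaling exponent alpha of the RMS fluctuation of the
#' linearly detrended integrated profile against box size. White noise gives
#' alpha near 0.5.
#'
#' @param x Numeric vector, length >= 30.
#' @param n_scales Number of log-spaced box sizes (default 10).
#' @return The scaling exponent alpha.
#' @export
dfa_exponent <- function(x, n_scales = 10L) {
  check_segment_length(x, 30L, "DFA")
  if (stats::sd(x) == 0) abort_degenerate("DFA undefined for a constant segment")
  n <- length(x)
  y <- cumsum(x - mean(x))
  sizes <- unique(round(exp(seq(log(4), log(n %/% 4), length.out = n_scales))))
  sizes <- sizes[sizes >= 4]
  fl <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    s <- sizes[i]
    nb <- n %/% s
    res <- 0
    t <- seq_len(s)
    for (b in seq_len(nb)) {
      seg <- y[((b - 1) * s + 1):(b * s)]
      fit <- stats::lm.fit(cbind(1, t), seg)
      res <- res + sum(fit$residuals^2)
    }
    fl[i] <- sqrt(res / (nb * s))
  }
  ok <- fl > 0
  if (sum(ok) < 2L) abort_degenerate("DFA undefined: zero fluctuations")
  stats::coef(stats::lm(log(fl[ok]) ~ log(sizes[ok])))[[2]]
}

#' Approximate and sample entropy
#'
#' Standard template-matching entropies with embedding dimension `m` and
#' tolerance `r` expressed as a multiple of the window SD.
#'
#' @param x Numeric vector.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance as a fraction of `sd(x)` (default 0.2).
#' @return Entropy value.
#' @export
approx_entropy <- function(x, m = 2L, r = 0.2) {
  check_segment_length(x, 2L * m + 2L, "AEN")
  s <- stats::sd(x)
  if (s == 0) abort_degenerate("AEN undefined for a constant segment")
  tol <- r * s
  phi <- function(mm) {
    cnt <- template_match_counts(x, mm, tol)
    mean(log(cnt / length(cnt)))
  }
  phi(m) - phi(m + 1L)
}

# Chebyshev-distance template match counts (self-matches included), via one
# pairwise matrix per embedding lag.
template_match_counts <- function(x, mm, tol) {
  n <- length(x) - mm + 1L
  within <- matrix(TRUE, n, n)
  for (j in seq_len(mm)) {
    xj <- x[j:(j + n - 1L)]
    within <- within & abs(outer(xj, xj, "-")) <= tol
  }
  rowSums(within)
}

#' @rdname approx_entropy
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2) {
  check_segment_length(x, 2L * m + 2L, "SAEN")
  s <- stats::sd(x)
  if (s == 0) abort_degenerate("SAEN undefined for a constant segment")
  tol <- r * s
  count_pairs <- function(mm) {
    cnt <- template_match_counts(x, mm, tol)
    (sum(cnt) - length(cnt)) / 2  # distinct pairs, self-matches excluded
  }
  a <- count_pairs(m + 1L); b <- count_pairs(m)
  if (a == 0 || b == 0) return(log(length(x)))  # capped, finite
  -log(a / b)
}

# Variogram-scaling fractal dimension family FRk: slope of log variogram
# V(tau) = mean (x_{t+tau} - x_t)^2 over lags 1..k+1 gives the Hurst-like
# exponent beta/2; FD = 2 - beta/2. A straight line gives 1, white noise 2.
variogram_fd <- function(x, k) {
  lags <- seq_len(k + 1L)
  check_segment_length(x, max(lags) + 2L, sprintf("FR%d", k))
  v <- vapply(lags, function(l) mean(diff(x, lag = l)^2), numeric(1))
  ok <- v > 0
  if (sum(ok) < 2L)
    abort_degenerate(sprintf("FR%d undefined for a constant segment", k))
  beta <- stats::coef(stats::lm(log(v[ok]) ~ log(lags[ok])))[[2]]
  2 - beta / 2
}

feat_fr <- function(k) {
  force(k)
  function(x, fs, ctx) variogram_fd(x, k)
}

# Katz fractal dimension.
feat_kfd <- function(x, fs, ctx) {
  L <- sum(sqrt(1 + diff(x)^2))
  d <- max(sqrt((seq_along(x) - 1)^2 + (x - x[1])^2))
  a <- L / (length(x) - 1)
  if (a == 0 || d == 0) abort_degenerate("KFD undefined for a constant segment")
  n <- L / a
  log10(n) / (log10(n) + log10(d / L))
}

# Petrosian fractal dimension.
feat_pfd <- function(x, fs, ctx) {
  n <- length(x)
  nd <- sum(diff(sign(diff(x))) != 0)
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

feat_hfd  <- function(x, fs, ctx) higuchi_fd(x)
feat_dfa  <- function(x, fs, ctx) dfa_exponent(x)
feat_aen  <- function(x, fs, ctx) approx_entropy(x)
feat_saen <- function(x, fs, ctx) sample_entropy(x)
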