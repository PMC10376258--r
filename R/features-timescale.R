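# Time-frequency domain (TFD) features. Windows shorter than 64 samples are
# extended by symmetric (mirror) padding before any decomposition, so the
# 30-60 ms gesture windows remain usable. No wavelet/EMD package ships the
# required primitives here, so small, tested implementations are provided:
# a db4 pyramid DWT, an a-trous SWT, a sifting EMD for the Hilbert-Huang
# marginal spectrum, and a support-adaptive 10-band empirical band split.

pad_symmetric <- function(x, min_len = 64L) {
  while (length(x) < min_len) {
    need <- min_len - length(x)
    take <- min(need, length(x))
    x <- c(x, rev(x)[seq_len(take)])
  }
  x
}

# db4 (4 vanishing moments, 8 taps) scaling filter.
DB4_LO <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
            -0.027983769416984, -0.187034811718881, 0.030841381835987,
            0.032883011666983, -0.010597401784997)
DB4_HI <- rev(DB4_LO) * c(1, -1, 1, -1, 1, -1, 1, -1)

conv_periodic <- function(x, h) {
  n <- length(x); L <- length(h)
  idx <- outer(seq_len(n) - 1L, seq_len(L) - 1L, function(i, k) (i - k) %% n) + 1L
  drop(matrix(x[idx], n, L) %*% h)
}

# Pyramid (decimated) DWT detail energies, 3 levels.
dwt_detail_energies <- function(x, levels = 3L) {
  x <- pad_symmetric(x)
  energies <- numeric(levels)
  a <- x
  for (l in seq_len(levels)) {
    d <- conv_periodic(a, DB4_HI)[seq(1, length(a), by = 2)]
    a <- conv_periodic(a, DB4_LO)[seq(1, length(a), by = 2)]
    energies[l] <- sum(d^2)
  }
  attr(energies, "approx_energy") <- sum(a^2)
  energies
}

# Stationary (a-trous, undecimated) wavelet detail energies, normalized by
# the redundancy so levels are comparable to the decimated transform.
swt_detail_energies <- function(x, levels = 3L) {
  x <- pad_symmetric(x)
  energies <- numeric(levels)
  a <- x
  lo <- DB4_LO; hi <- DB4_HI
  for (l in seq_len(levels)) {
    d <- conv_periodic(a, hi)
    a <- conv_periodic(a, lo)
    energies[l] <- sum(d^2) / 2^l
    # upsample filters (insert zeros) for the next scale
    lo <- as.vector(rbind(lo, 0))[seq_len(2 * length(lo) - 1)]
    hi <- as.vector(rbind(hi, 0))[seq_len(2 * length(hi) - 1)]
  }
  attr(energies, "approx_energy") <- sum(a^2) / 2^levels
  energies
}

feat_dwt <- function(x, fs, ctx) {
  if (is.null(ctx$dwt_e)) ctx$dwt_e <- dwt_detail_energies(x)
  sum(log1p(ctx$dwt_e))
}

feat_swt <- function(x, fs, ctx) {
  if (is.null(ctx$swt_e)) ctx$swt_e <- swt_detail_energies(x)
  sum(log1p(ctx$swt_e))
}

# Wavelet entropy over the DWT sub-band energy distribution.
feat_went <- function(x, fs, ctx) {
  if (is.null(ctx$dwt_e)) ctx$dwt_e <- dwt_detail_energies(x)
  e <- c(ctx$dwt_e, attr(ctx$dwt_e, "approx_energy"))
  tot <- sum(e)
  if (tot <= 0) return(0)
  pr <- e / tot
  pr <- pr[pr > 0]
  -sum(pr * log(pr))
}

# Short-time Fourier summary: mean log frame power over Hann-windowed
# 16-sample frames with 50% overlap.
feat_stft <- function(x, fs, ctx) {
  x <- pad_symmetric(x)
  L <- 16L; hop <- 8L
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  pw <- vapply(starts, function(s) sum(abs(stats::fft(x[s:(s + L - 1)] * w))^2) / L,
               numeric(1))
  mean(log1p(pw))
}

# --- Empirical mode decomposition (sifting) and Hilbert-Huang summary -----

local_extrema <- function(x) {
  n <- length(x)
  dx <- diff(x)
  s <- sign(dx)
  # flat runs inherit the preceding slope so plateaus count once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  chg <- diff(s)
  list(max = which(chg < 0) + 1L, min = which(chg > 0) + 1L)
}

envelope_mean <- function(x) {
  ext <- local_extrema(x)
  if (length(ext$max) < 2L || length(ext$min) < 2L) return(NULL)
  n <- length(x)
  up <- stats::spline(c(1, ext$max, n), c(x[1], x[ext$max], x[n]),
                      xout = seq_len(n))$y
  dn <- stats::spline(c(1, ext$min, n), c(x[1], x[ext$min], x[n]),
                      xout = seq_len(n))$y
  (up + dn) / 2
}

emd_decompose <- function(x, max_imf = 4L, max_sift = 10L) {
  imfs <- list()
  r <- x
  for (k in seq_len(max_imf)) {
    h <- r
    for (s in seq_len(max_sift)) {
      m <- envelope_mean(h)
      if (is.null(m)) break
      h_new <- h - m
      if (sum(m^2) < 1e-10 * sum(h^2)) { h <- h_new; break }
      h <- h_new
    }
    if (is.null(envelope_mean(h)) && k == 1L && sum(h^2) < 1e-12 * sum(x^2))
      break
    imfs[[k]] <- h
    r <- r - h
    if (is.null(envelope_mean(r))) break
  }
  imfs
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Hilbert-Huang summary: amplitude-squared-weighted mean instantaneous
# frequency (Hz) over the marginal spectrum of the empirical modes.
feat_hht <- function(x, fs, ctx) {
  x <- pad_symmetric(x)
  if (stats::sd(x) == 0)
    abort_degenerate("HHT undefined for a constant segment")
  imfs <- emd_decompose(x)
  if (length(imfs) == 0L) return(0)
  num <- 0; den <- 0
  for (imf in imfs) {
    z <- analytic_signal(imf)
    amp <- Mod(z)
    ph <- Arg(z)
    instf <- diff(ph)
    instf <- (instf + pi) %% (2 * pi) - pi  # unwrap steps
    instf <- abs(instf) * fs / (2 * pi)
    w <- amp[-1]^2
    num <- num + sum(w * instf)
    den <- den + sum(w)
  }
  if (den == 0) return(0)
  num / den
}

# --- Empirical 10-band split -----------------------------------------------

# Support-adaptive band segmentation: band 1 is everything below the 2nd
# power percentile frequency, band 10 everything above the 98th, and the
# eight interior bands split the occupied support uniformly. Returns the
# per-band absolute energies and relative powers (summing to 1).
ewt_bands <- function(x, fs, ctx, n_bands = 10L) {
  if (!is.null(ctx$ewt)) return(ctx$ewt)
  xp <- pad_symmetric(x)
  n <- length(xp)
  xd <- xp - mean(xp)
  sp <- abs(stats::fft(xd))^2 / n
  half <- floor(n / 2)
  p <- sp[1:(half + 1)]
  f <- (0:half) * fs / n
  tot <- sum(p)
  if (tot <= 0) abort_degenerate("all-zero spectrum: empirical bands undefined")
  cp <- cumsum(p) / tot
  lo <- f[which(cp >= 0.02)[1]]
  hi <- f[which(cp >= 0.98)[1]]
  if (hi <= lo) { lo <- 0; hi <- fs / 2 }
  edges <- c(0, seq(lo, hi, length.out = n_bands - 1L), fs / 2 + 1)
  band <- cut(f, edges, include.lowest = TRUE, labels = FALSE)
  energy <- vapply(seq_len(n_bands), function(b) sum(p[band == b]), numeric(1))
  ctx$ewt <- list(energy = energy, power = energy / tot)
  ctx$ewt
}

feat_ewt <- function(k) {
  force(k)
  function(x, fs, ctx) ewt_bands(x, fs, ctx)$energy[k]
}

feat_ewp <- function(k) {
  force(k)
  function(x, fs, ctx) ewt_bands(x, fs, ctx)$power[k]
}
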