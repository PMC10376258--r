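# Frequency-domain (FD) features, all computed from the one-sided
# periodogram of the demeaned window. The periodogram is cached per channel
# window in `ctx` so the whole FD group costs one FFT.

psd_ctx <- function(x, fs, ctx) {
  if (!is.null(ctx$psd)) return(ctx$psd)
  check_segment_length(x, 16L, "spectral features")
  n <- length(x)
  xd <- x - mean(x)
  sp <- abs(stats::fft(xd))^2 / n
  half <- floor(n / 2)
  p <- sp[1:(half + 1)]
  f <- (0:half) * fs / n
  if (sum(p) <= 0)
    abort_degenerate("all-zero spectrum: spectral features undefined")
  ctx$psd <- list(f = f, p = p, total = sum(p))
  ctx$psd
}

spectral_moment <- function(psd, k) sum(psd$p * psd$f^k)

feat_mnf <- function(x, fs, ctx) {
  s <- psd_ctx(x, fs, ctx)
  spectral_moment(s, 1) / s$total
}

cumulative_power_freq <- function(psd, frac) {
  cp <- cumsum(psd$p) / psd$total
  psd$f[which(cp >= frac)[1]]
}

feat_mdf   <- function(x, fs, ctx) cumulative_power_freq(psd_ctx(x, fs, ctx), 0.5)
feat_perc2 <- function(x, fs, ctx) cumulative_power_freq(psd_ctx(x, fs, ctx), 0.02)
feat_mnp   <- function(x, fs, ctx) mean(psd_ctx(x, fs, ctx)$p)
feat_ttp   <- function(x, fs, ctx) psd_ctx(x, fs, ctx)$total
feat_psp   <- function(x, fs, ctx) max(psd_ctx(x, fs, ctx)$p)

feat_pkf <- function(x, fs, ctx) {
  s <- psd_ctx(x, fs, ctx)
  s$f[which.max(s$p)]
}

# Power spectrum ratio: power within +-10 Hz (or +-2 bins if wider) of the
# spectral peak, relative to total power.
feat_psr <- function(x, fs, ctx) {
  s <- psd_ctx(x, fs, ctx)
  f0 <- s$f[which.max(s$p)]
  halfwidth <- max(10, 2 * (s$f[2] - s$f[1]))
  sum(s$p[abs(s$f - f0) <= halfwidth]) / s$total
}

feat_sm1 <- function(x, fs, ctx) spectral_moment(psd_ctx(x, fs, ctx), 1)
feat_sm2 <- function(x, fs, ctx) spectral_moment(psd_ctx(x, fs, ctx), 2)

# Normalized spectral-moment shape ratio SM2*SM0/SM1^2: dimensionless in
# both power and frequency, 1 for a line spectrum.
feat_smn <- function(x, fs, ctx) {
  s <- psd_ctx(x, fs, ctx)
  m1 <- spectral_moment(s, 1)
  if (m1 == 0) abort_degenerate("SMN undefined: zero first spectral moment")
  spectral_moment(s, 2) * s$total / m1^2
}

feat_vcf <- function(x, fs, ctx) {
  s <- psd_ctx(x, fs, ctx)
  mu <- spectral_moment(s, 1) / s$total
  spectral_moment(s, 2) / s$total - mu^2
}

# Frequency dispersion descriptor: power-weighted SD of frequency.
feat_fdd <- function(x, fs, ctx) sqrt(max(0, feat_vcf(x, fs, ctx)))

feat_masp <- function(x, fs, ctx) mean(sqrt(psd_ctx(x, fs, ctx)$p))

# Log-ratio of adjacent spectral moments.
feat_asm <- function(x, fs, ctx) {
  s <- psd_ctx(x, fs, ctx)
  m1 <- spectral_moment(s, 1)
  if (m1 <= 0) abort_degenerate("ASM undefined: zero first spectral moment")
  log(spectral_moment(s, 2) / m1 + 1e-12)
}

# Low-band energy ratio: fraction of power below fs/8.
feat_er <- function(x, fs, ctx) {
  s <- psd_ctx(x, fs, ctx)
  sum(s$p[s$f < fs / 8]) / s$total
}

# Mean-normalized power deviation: SD of the PSD relative to its mean.
feat_mnpd <- function(x, fs, ctx) {
  s <- psd_ctx(x, fs, ctx)
  stats::sd(s$p) / mean(s$p)
}

# Normalized spectral entropy.
feat_sen <- function(x, fs, ctx) {
  s <- psd_ctx(x, fs, ctx)
  pr <- s$p / s$total
  pr <- pr[pr > 0]
  if (length(pr) <= 1L) return(0)
  -sum(pr * log(pr)) / log(length(s$p))
}
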