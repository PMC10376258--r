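# Independent direct-summation oracles for the closed-form features, written
# as explicit loops so they share no code with the package implementations.

oracle_env <- new.env()

oracle_env$MAV <- function(x) { s <- 0; for (v in x) s <- s + abs(v); s / length(x) }
oracle_env$IEMG <- function(x) { s <- 0; for (v in x) s <- s + abs(v); s }
oracle_env$RMS <- function(x) { s <- 0; for (v in x) s <- s + v * v; sqrt(s / length(x)) }
oracle_env$VAR <- function(x) { s <- 0; for (v in x) s <- s + v * v; s / (length(x) - 1) }
oracle_env$SSI <- function(x) { s <- 0; for (v in x) s <- s + v * v; s }
oracle_env$WL <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + abs(x[i] - x[i - 1])
  s
}
oracle_env$DAMV <- function(x) oracle_env$WL(x) / (length(x) - 1)
oracle_env$AAC <- function(x) oracle_env$WL(x) / length(x)
oracle_env$DASDV <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1])^2
  sqrt(s / (length(x) - 1))
}
oracle_env$EWL <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + abs(x[i] - x[i - 1])^0.75
  s
}
oracle_env$MSR <- function(x) { s <- 0; for (v in x) s <- s + sqrt(abs(v)); s / length(x) }
oracle_env$RSM0 <- function(x) { s <- 0; for (v in x) s <- s + v * v; sqrt(s) }
oracle_env$RSD1 <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1])^2
  sqrt(s)
}
oracle_env$RSD2 <- function(x) {
  d <- numeric(length(x) - 1)
  for (i in 2:length(x)) d[i - 1] <- x[i] - x[i - 1]
  s <- 0
  for (i in 2:length(d)) s <- s + (d[i] - d[i - 1])^2
  sqrt(s)
}
oracle_env$ROG <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1])^2
  sqrt(s / (length(x) - 1))
}
oracle_env$TM3 <- function(x) { s <- 0; for (v in x) s <- s + v^3; abs(s / length(x)) }
oracle_env$TM4 <- function(x) { s <- 0; for (v in x) s <- s + v^4; s / length(x) }
oracle_env$TM5 <- function(x) { s <- 0; for (v in x) s <- s + v^5; abs(s / length(x)) }
oracle_env$VORD <- function(x) { s <- 0; for (v in x) s <- s + abs(v)^3; (s / length(x))^(1 / 3) }
oracle_env$LOG <- function(x) {
  s <- 0
  for (v in x) s <- s + log(abs(v) + 1e-12)
  exp(s / length(x))
}
oracle_env$MMAV1 <- function(x) {
  n <- length(x); s <- 0
  for (i in 1:n) {
    w <- if (i >= 0.25 * n && i <= 0.75 * n) 1 else 0.5
    s <- s + w * abs(x[i])
  }
  s / n
}
oracle_env$MMAV2 <- function(x) {
  n <- length(x); s <- 0
  for (i in 1:n) {
    w <- if (i < 0.25 * n) 4 * i / n else if (i > 0.75 * n) 4 * (n - i) / n else 1
    s <- s + w * abs(x[i])
  }
  s / n
}
oracle_env$PKAMP <- function(x) { m <- 0; for (v in x) if (abs(v) > m) m <- abs(v); m }
oracle_env$RNG <- function(x) max(x) - min(x)
oracle_env$MEANV <- function(x) sum(x) / length(x)
oracle_env$HJA <- function(x) {
  mu <- sum(x) / length(x); s <- 0
  for (v in x) s <- s + (v - mu)^2
  s / (length(x) - 1)
}
oracle_env$MAVSLP <- function(x) {
  n <- length(x); h <- n %/% 2
  a <- 0; for (i in 1:h) a <- a + abs(x[i])
  b <- 0; for (i in (h + 1):n) b <- b + abs(x[i])
  b / (n - h) - a / h
}
oracle_env$MFL <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1])^2
  log10(sqrt(s) + 1e-12)
}

# thresholded counts at threshold 0 (strict comparisons)
oracle_zc0 <- function(x) {
  c0 <- 0
  for (i in 2:length(x)) if (x[i - 1] * x[i] < 0 && abs(x[i - 1] - x[i]) > 0) c0 <- c0 + 1
  c0
}
oracle_ssc0 <- function(x) {
  c0 <- 0
  for (i in 2:(length(x) - 1))
    if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > 0) c0 <- c0 + 1
  c0
}
oracle_wamp0 <- function(x) {
  c0 <- 0
  for (i in 2:length(x)) if (abs(x[i] - x[i - 1]) > 0) c0 <- c0 + 1
  c0
}

# brute-force Higuchi oracle: literal translation of the definition
oracle_higuchi <- function(x, kmax = 8) {
  n <- length(x)
  lk <- numeric(kmax)
  for (k in 1:kmax) {
    lm <- c()
    for (m in 1:k) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) next
      s <- 0
      for (j in 2:length(idx)) s <- s + abs(x[idx[j]] - x[idx[j - 1]])
      lm <- c(lm, s * (n - 1) / ((length(idx) - 1) * k) / k)
    }
    lk[k] <- mean(lm)
  }
  fit <- lm(log(lk) ~ log(1 / (1:kmax)))
  unname(coef(fit)[2])
}

# pooled one-tailed t oracle: textbook formula
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = pt(t, n1 + n2 - 2, lower.tail = FALSE))
}

# tiny deterministic dataset helpers used across test files
tiny_dataset <- function(n_subjects = 4, reps = 3, severity = 1,
                         crosstalk = 0, seed = 1, ...) {
  generate_dataset(synth_config(n_subjects = n_subjects,
                                reps_per_gesture = reps,
                                severity = severity, crosstalk = crosstalk,
                                seed = seed, ...))
}

random_segment_signal <- function(n = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rnorm(n) + 0.3 * sin(2 * pi * seq_len(n) / 17)
}
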