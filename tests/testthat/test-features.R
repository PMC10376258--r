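# Feature bank: registry composition, worked examples, oracle agreement,
# scale behaviour, and the heavier decomposition features.

extract1 <- function(x, feature, fs = 1000) {
  seg <- segment(matrix(x, ncol = 1), label = "fist", channel_roles = "flexor",
                 fs = fs)
  fm <- extract_features(list(seg), features = feature)
  unname(as.matrix(fm[, -(1:3)])[1, ])
}

test_that("registry holds 127 features, exactly 80 time-domain", {
  reg <- feature_registry()
  expect_equal(nrow(reg$specs), 127)
  expect_equal(sum(reg$specs$domain == "TD"), 80)
  expect_setequal(unique(reg$specs$domain), c("TD", "FD", "TFD", "FRD", "SD"))
  expect_equal(anyDuplicated(reg$specs$name), 0)
})

test_that("registry matches the shipped manifest", {
  man <- feature_manifest()
  reg <- feature_registry()$specs
  expect_equal(man$name, reg$name)
  expect_equal(man$domain, reg$domain)
  expect_equal(man$arity, reg$arity)
})

test_that("all baseline and reported best-set names resolve", {
  for (set in mfs_baselines()) expect_length(resolve_features(set), length(set))
  # winning sets reported for the three source depths, plus mono-level names
  listed <- c("MMAV5", "SSI", "LSSI", "RSM0", "MSR", "MHW", "MTW", "AR3",
              "AEN", "MLASP", "SMN", "FDD", "STFT", "EWP-6", "EWP-10",
              "EWT-4", "HHT", "SWT", "DWT",
              "ASM", "EWL", "LCARD", "MASP", "MNP", "EWT-6", "EWT-8",
              "EWT-10", "EWP-8", "CC-R", "FR4",
              "IEMG", "VAR", "RSD1", "RSD2", "WL", "SSC", "SM2", "SM1",
              "CRD", "PERC2", "EWT10", "MNPD")
  expect_length(resolve_features(listed), length(unique(normalize <- resolve_features(listed))))
  expect_error(resolve_features("NOSUCH"), class = "snailfs_config_error")
  expect_error(resolve_features(character(0)), class = "snailfs_config_error")
})

test_that("worked examples of the simple time-domain features", {
  expect_equal(extract1(c(1, -2, 3), "MAV"), 2)
  expect_equal(extract1(c(0, 1, 3, 2), "WL"), 4)
  expect_equal(extract1(c(1, -1, 1, -1), "ZC"), 3)
  expect_equal(extract1(c(0, 1, 0, 1, 0), "SSC"), 3)
  expect_equal(extract1(c(3, 4), "RMS"), sqrt(12.5))
  expect_equal(extract1(c(3, 4), "SSI"), 25)
  expect_equal(extract1(c(4, 9), "MSR"), 2.5)
  expect_equal(extract1(c(3, 4), "LSSI"), log(1 + 25))
})

test_that("closed-form features agree with direct-summation oracles to 1e-9", {
  set.seed(42)
  reg <- feature_registry(names(oracle_env))
  for (rep in 1:100) {
    x <- random_segment_signal(sample(40:80, 1))
    for (nm in names(oracle_env)) {
      got <- extract1(x, nm)
      expect_equal(got, oracle_env[[nm]](x), tolerance = 1e-9,
                   label = sprintf("%s (rep %d)", nm, rep))
    }
  }
})

test_that("threshold-zero counting features match loop oracles", {
  set.seed(7)
  for (rep in 1:20) {
    x <- random_segment_signal(60)
    expect_equal(snailfs:::feat_zc(x, 1000, NULL, threshold = 0), oracle_zc0(x))
    expect_equal(snailfs:::feat_ssc(x, 1000, NULL, threshold = 0), oracle_ssc0(x))
    expect_equal(snailfs:::feat_wamp(x, 1000, NULL, threshold = 0), oracle_wamp0(x))
  }
})

test_that("AR coefficients recover simulated processes", {
  set.seed(3)
  n <- 10000
  x <- as.numeric(arima.sim(list(ar = 0.5), n))
  expect_equal(ar_coefficients(x, 1)[1], 0.5, tolerance = 0.05)
  w <- rnorm(n)
  expect_equal(ar_coefficients(w, 2), c(0, 0), tolerance = 0.05)
  expect_error(ar_coefficients(rep(1, 100), 2),
               class = "snailfs_degenerate_error")
  cc <- cepstral_coefficients(x, 4)
  expect_length(cc, 4)
  expect_true(all(is.finite(cc)))
  expect_equal(cc[1], ar_coefficients(x, 4)[1])  # first-order recursion
})

test_that("spectral features locate tones and flat spectra", {
  fs <- 1000
  tone <- sin(2 * pi * 50 * seq_len(512) / fs)
  expect_equal(extract1(tone, "MNF"), 50, tolerance = 2)
  expect_equal(extract1(tone, "MDF"), 50, tolerance = 2)
  expect_equal(extract1(tone, "PKF"), 50, tolerance = 2)
  set.seed(1)
  w <- rnorm(8192)
  expect_equal(extract1(w, "MNF"), fs / 4, tolerance = 0.1 * fs / 4)
  # scale invariance of normalized spectral descriptors
  x <- random_segment_signal(64, seed = 2)
  for (nm in c("MNF", "MDF", "SEN", "PSR", "ER", "SMN"))
    expect_equal(extract1(7 * x, nm), extract1(x, nm), tolerance = 1e-9,
                 label = nm)
  expect_error(extract1(rep(0.5, 64), "MNF"))
})

test_that("amplitude scaling behaves per the equivariance table", {
  x <- random_segment_signal(60, seed = 4)
  a <- 3.7
  expect_equal(extract1(a * x, "MAV"), a * extract1(x, "MAV"), tolerance = 1e-9)
  expect_equal(extract1(a * x, "WL"), a * extract1(x, "WL"), tolerance = 1e-9)
  expect_equal(snailfs:::feat_zc(a * x, 1000, NULL, threshold = 0),
               snailfs:::feat_zc(x, 1000, NULL, threshold = 0))
  expect_equal(snailfs:::feat_ssc(a * x, 1000, NULL, threshold = 0),
               snailfs:::feat_ssc(x, 1000, NULL, threshold = 0))
  expect_equal(extract1(a * x, "HFD"), extract1(x, "HFD"), tolerance = 1e-9)
  long <- rnorm(4096)
  expect_equal(dfa_exponent(a * long), dfa_exponent(long), tolerance = 1e-9)
})

test_that("fractal features match their theory anchors", {
  line <- seq(0, 1, length.out = 200)
  expect_equal(higuchi_fd(line), 1, tolerance = 0.05)
  expect_equal(higuchi_fd(line), oracle_higuchi(line), tolerance = 1e-9)
  set.seed(5)
  w <- rnorm(400)
  expect_equal(higuchi_fd(w), oracle_higuchi(w), tolerance = 1e-9)
  expect_equal(dfa_exponent(rnorm(4096)), 0.5, tolerance = 0.1)
  expect_equal(extract1(line, "FR1"), 1, tolerance = 0.05)
  expect_equal(extract1(c(line, rev(line)), "FR4"), 1, tolerance = 0.1)
  expect_error(higuchi_fd(c(1, 2)), class = "snailfs_degenerate_error")
  expect_error(dfa_exponent(rnorm(10)), class = "snailfs_degenerate_error")
})

test_that("timescale decompositions satisfy their invariants", {
  # constant signal: negligible detail energy at every level
  const <- rep(2, 64)
  e_dwt <- snailfs:::dwt_detail_energies(const)
  expect_true(all(e_dwt < 1e-9 * sum(const^2)))
  e_swt <- snailfs:::swt_detail_energies(const)
  expect_true(all(e_swt < 1e-9 * sum(const^2)))

  # relative band powers sum to one
  x <- random_segment_signal(60, seed = 6)
  ctx <- new.env()
  bp <- snailfs:::ewt_bands(x, 1000, ctx)
  expect_equal(sum(bp$power), 1, tolerance = 1e-6)
  expect_length(bp$power, 10)

  # band-limited noise leaves the lowest empirical band nearly empty
  set.seed(8)
  bl <- snailfs:::band_limited_noise(1024, 1000, c(20, 300))
  bp2 <- snailfs:::ewt_bands(bl, 1000, new.env())
  expect_lt(bp2$power[1], 0.05)
  # cross-check against direct periodogram band power over the same edges
  p <- abs(fft(bl - mean(bl)))^2
  f <- (0:(length(bl) / 2)) * 1000 / length(bl)
  p <- p[seq_along(f)]
  expect_lt(sum(p[f < 20]) / sum(p), 0.05)
})

test_that("spatial ratios respect identity, scaling and the epsilon guard", {
  w <- matrix(rnorm(200), ncol = 4)
  roles <- c("flexor", "flexor", "extensor", "extensor")
  same <- cbind(w[, 1], w[, 1], w[, 1], w[, 1])
  vals <- spatial_features(same, roles)
  expect_equal(unname(vals), rep(1, 5), tolerance = 1e-9)
  base <- spatial_features(w, roles)
  doubled <- spatial_features(cbind(2 * w[, 1:2], w[, 3:4]), roles)
  expect_equal(doubled[["SDMAVR"]], 2 * base[["SDMAVR"]], tolerance = 1e-9)
  quiet_ext <- cbind(w[, 1:2], 0 * w[, 3:4])
  guarded <- spatial_features(quiet_ext, roles)
  expect_true(all(is.finite(guarded)))
  expect_equal(guarded[["SDPR"]], snailfs:::SD_RATIO_CAP)
  expect_error(spatial_features(w, rep("flexor", 4)),
               class = "snailfs_config_error")
})

test_that("log variants are monotone and vanish at zero", {
  reg <- feature_registry()
  base <- reg$specs[reg$specs$name == "MAV", ]
  lv <- log_variant(base)
  expect_equal(lv$name, "LMAV")
  f <- lv$fn[[1]]
  expect_equal(f(c(0, 0, 0.0), 1000, NULL), 0)
  v1 <- f(random_segment_signal(50, seed = 1), 1000, NULL)
  v2 <- f(10 * random_segment_signal(50, seed = 1), 1000, NULL)
  expect_lt(v1, v2)
})

test_that("extract_features shapes, provenance and errors", {
  ds <- tiny_dataset(n_subjects = 3, reps = 2, seed = 10)
  segs <- segment_dataset(ds)
  fm <- extract_features(segs, features = c("MAV", "WL"))
  expect_equal(ncol(fm) - 3L, 2 * 5)  # 2 features x 5 channels
  expect_equal(nrow(fm), length(segs))
  expect_error(extract_features(segs, features = character(0)),
               class = "snailfs_config_error")
  # full default registry column count equals the manifest bookkeeping
  man <- feature_manifest()
  expected_cols <- sum(man$arity[man$domain != "SD"]) * 5 +
    sum(man$domain == "SD")
  fm_full <- extract_features(segs[1:3])
  expect_equal(ncol(fm_full) - 3L, expected_cols)
  expect_true(all(is.finite(as.matrix(fm_full[, -(1:3)]))))
  map <- feature_map(fm_full)
  expect_equal(nrow(map), expected_cols)
  expect_setequal(unique(map$feature), man$name)
})

test_that("feature matrices round-trip through CSV + sidecar", {
  ds <- tiny_dataset(n_subjects = 3, reps = 2, seed = 11)
  fm <- extract_features(segment_dataset(ds), features = c("MAV", "MNF"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(as.data.frame(back), as.data.frame(fm), tolerance = 1e-12)
  expect_equal(feature_map(back)$column, feature_map(fm)$column)
})
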