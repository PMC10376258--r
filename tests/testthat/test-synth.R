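# Synthetic dataset generator and recording I/O.

test_that("identical configs give bit-identical datasets", {
  cfg <- synth_config(n_subjects = 3, reps_per_gesture = 2, seed = 11)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$annotations, d2$annotations)
  expect_identical(d1$recordings[[2]]$samples, d2$recordings[[2]]$samples)
  d3 <- generate_dataset(synth_config(n_subjects = 3, reps_per_gesture = 2,
                                      seed = 12))
  expect_false(identical(d1$recordings[[1]]$samples, d3$recordings[[1]]$samples))
})

test_that("ground truth lists n_subjects x 6 x reps bursts with onset/duration/label", {
  cfg <- synth_config(n_subjects = 4, reps_per_gesture = 3, seed = 2)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$annotations), 4 * 6 * 3)
  expect_setequal(unique(ds$annotations$label),
                  setdiff(c("fist", "pinch", "wrist_flexion", "wrist_extension",
                            "palm_open", "thumb", "rest"), "rest"))
  expect_true(all(ds$annotations$onset > 0))
  expect_true(all(ds$annotations$duration > 0))
  counts <- table(ds$annotations$subject_id, ds$annotations$label)
  expect_true(all(counts == 3))
})

test_that("burst spectral power is at least 95% inside the configured band", {
  cfg <- synth_config(n_subjects = 1, reps_per_gesture = 2, severity = 1,
                      crosstalk = 0, seed = 4)
  ds <- generate_dataset(cfg)
  rec <- ds$recordings[[1]]
  ann <- ds$annotations
  for (i in seq_len(min(4, nrow(ann)))) {
    x <- rec$samples[ann$onset[i]:(ann$onset[i] + ann$duration[i]), 1]
    x <- x - mean(x)
    p <- abs(fft(x))^2
    half <- floor(length(x) / 2)
    f <- (0:half) * cfg$fs / length(x)
    p <- p[1:(half + 1)]
    inband <- sum(p[f >= cfg$burst_band[1] & f <= cfg$burst_band[2]])
    expect_gt(inband / sum(p), 0.95)
  }
})

test_that("severity scales class separability monotonically", {
  # mean CCR of a fixed feature set is non-decreasing in severity
  means <- sapply(c(0, 0.5, 1), function(sv) {
    mean(sapply(1:5, function(s) {
      ds <- generate_dataset(synth_config(n_subjects = 4, reps_per_gesture = 2,
                                          severity = sv, seed = s))
      fm <- extract_features(segment_dataset(ds), features = "MAV")
      evaluate(fm, "MAV", eval_protocol(n_iterations = 5, seed = s))$mean_ccr
    }))
  })
  expect_true(all(diff(means) >= 0))
  expect_gt(means[3], means[1] + 20)  # severity matters, not just noise
})

test_that("severity-0 data are chance-level for any feature set", {
  ds <- tiny_dataset(n_subjects = 6, reps = 3, severity = 0, seed = 7)
  fm <- extract_features(segment_dataset(ds), features = c("MAV", "WL"))
  res <- evaluate(fm, c("MAV", "WL"), eval_protocol(n_iterations = 20, seed = 7))
  p0 <- 1 / 7
  se <- 100 * sqrt(p0 * (1 - p0) / nrow(fm))  # binomial error, distinct instances
  expect_lt(abs(res$mean_ccr - 100 / 7), 3 * se)
})

test_that("artifact injection adds spikes of at least 10x local RMS", {
  cfg_clean <- synth_config(n_subjects = 1, reps_per_gesture = 2,
                            artifact_rate = 0, seed = 9)
  cfg_spiky <- synth_config(n_subjects = 1, reps_per_gesture = 2,
                            artifact_rate = 2, seed = 9)
  clean <- generate_dataset(cfg_clean)$recordings[[1]]$samples
  spiky <- generate_dataset(cfg_spiky)$recordings[[1]]$samples
  hit <- which(abs(spiky - clean) > 1e-12, arr.ind = TRUE)
  expect_gt(nrow(hit), 0)
  for (k in seq_len(nrow(hit))) {
    i <- hit[k, 1]; ch <- hit[k, 2]
    local_rms <- sqrt(mean(clean[max(1, i - 50):min(nrow(clean), i + 50), ch]^2))
    expect_gte(abs(spiky[i, ch] - clean[i, ch]), 10 * local_rms)
  }
})

test_that("invalid configs are rejected", {
  expect_error(synth_config(n_subjects = 0), class = "snailfs_config_error")
  expect_error(synth_config(burst_band = c(300, 20)), class = "snailfs_config_error")
  expect_error(synth_config(fs = 1000, burst_band = c(20, 600)),
               class = "snailfs_config_error")
  expect_error(synth_config(severity = 1.5), class = "snailfs_config_error")
  expect_error(synth_config(crosstalk = 1), class = "snailfs_config_error")
})

test_that("delimited recording round-trips to 1e-12", {
  rec <- recording(matrix(rnorm(30), ncol = 2), fs = 1000,
                   channel_roles = c("flexor", "extensor"), subject_id = "S07")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_equal(back$fs, 1000)
  expect_equal(back$subject_id, "S07")
  expect_equal(back$channel_roles, rec$channel_roles)
})

test_that("malformed delimited files raise format errors naming the cell", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("flexor,extensor", "0.1,0.2", "0.3,oops"), path)
  expect_error(read_recording(path, fs = 1000), "row 2",
               class = "snailfs_format_error")
  writeLines(c("flexor,extensor", "0.1,0.2", "0.3"), path)
  expect_error(read_recording(path, fs = 1000), "ragged",
               class = "snailfs_format_error")
  writeLines(c("flexor,extensor", "0.1,0.2"), path)
  expect_error(read_recording(path), "sampling rate",
               class = "snailfs_format_error")
})

test_that("segment_dataset yields balanced 7-class windows inside the source", {
  ds <- tiny_dataset(n_subjects = 3, reps = 2, seed = 5)
  segs <- segment_dataset(ds)
  labs <- vapply(segs, function(s) s$label, character(1))
  expect_equal(sum(labs != "rest"), 3 * 6 * 2)
  expect_equal(sum(labs == "rest"), 3 * 2)
  expect_true(all(vapply(segs, function(s) nrow(s$window), integer(1)) == 48))
})

test_that("annotations round-trip through JSON", {
  ds <- tiny_dataset(n_subjects = 2, reps = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(ds$annotations, path)
  back <- read_annotations(path)
  expect_equal(as.data.frame(back), as.data.frame(ds$annotations))
})
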