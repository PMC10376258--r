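# SNAiL spiral amalgamation.

mk_pool <- function(sets, scores, r = NULL) {
  snailfs:::new_ranked_pool(tibble::tibble(
    features = sets,
    r = r %||% lengths(strsplit(sets, "+", fixed = TRUE)),
    mean_ccr = scores, sd_ccr = 0))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("seed pool is the re-sorted union of source-level quintiles", {
  p1 <- mk_pool(sprintf("F%02d", 1:10), seq(90, 9, length.out = 10))
  p2 <- mk_pool(paste0("F01+F", sprintf("%02d", 2:11)),
                seq(95, 50, length.out = 10))
  cfg <- snail_config(source_depth = 2, protocol = eval_protocol(n_iterations = 2))
  seeds <- seed_pool(list(r1 = p1, r2 = p2), cfg)
  expect_equal(nrow(seeds), 2 + 2)  # ceiling(0.2*10) per pool
  expect_true(all(seeds$features %in% c(top_quintile(p1)$features,
                                        top_quintile(p2)$features)))
  expect_equal(seeds$mean_ccr, sort(seeds$mean_ccr, decreasing = TRUE))
  cfg1 <- snail_config(source_depth = 1, protocol = eval_protocol(n_iterations = 2))
  expect_equal(nrow(seed_pool(list(r1 = p1), cfg1)), 2)
  expect_error(seed_pool(list(), cfg), class = "snailfs_protocol_error")
})

test_that("quintile arithmetic on a 127-single pool yields 26 seeds", {
  p1 <- mk_pool(sprintf("F%03d", 1:127), seq(90, 10, length.out = 127))
  cfg <- snail_config(source_depth = 1, protocol = eval_protocol(n_iterations = 2))
  expect_equal(nrow(seed_pool(list(r1 = p1), cfg)), 26)
})

test_that("proposal arithmetic follows the golden-ratio contracts", {
  expect_equal(snailfs:::parent_count(10, 1.618), 6)   # round(10/1.618)
  expect_equal(snailfs:::parent_count(2, 1.618), 2)    # floor at 2
  expect_equal(snailfs:::truncation_size(10, 1.618), 7)  # ceiling(10/1.618)
  expect_equal(snailfs:::truncation_size(1, 1.618), 1)

  pool <- mk_pool(c("A+B"), 80)
  seeds <- mk_pool(c("A", "B", "C"), c(70, 60, 50))
  cfg <- snail_config(source_depth = 2, protocol = eval_protocol(n_iterations = 2))
  cand <- propose_candidates(pool, seeds, cfg)
  expect_equal(cand, "A+B+C")  # single extension available
  # grown candidates contain their parent and have m+1 features
  pool2 <- mk_pool(c("A+B", "A+C"), c(80, 75))
  cand2 <- propose_candidates(pool2, seeds, cfg)
  expect_true(all(lengths(strsplit(cand2, "+", fixed = TRUE)) == 3))
  expect_true(all(vapply(strsplit(cand2, "+", fixed = TRUE),
                         function(f) all(c("A") %in% f), logical(1))))
  # exhausted alphabet signals a protocol error
  done <- mk_pool("A+B+C", 90)
  expect_error(propose_candidates(done, seeds, cfg),
               class = "snailfs_protocol_error")
})

test_that("run_snail recovers planted features and keeps best monotone", {
  fm <- simulate_feature_matrix(n_subjects = 10, reps = 3, seed = 12)
  p <- eval_protocol(n_iterations = 10, seed = 12)
  pools <- run_bfs(fm, r_max = 1, protocol = p)
  cfg <- snail_config(source_depth = 1, max_size = 6, protocol = p)
  sn <- run_snail(fm, pools, cfg)
  expect_true(all(diff(sn$history$best_overall) >= 0))
  expect_equal(max(sn$history$best_overall), sn$best$mean_ccr)
  winner <- strsplit(sn$best$features, "+", fixed = TRUE)[[1]]
  expect_gte(sum(grepl("^INF", winner)), 4)
  # every stage-m candidate has exactly m features
  expect_true(all(lengths(strsplit(sn$history$best_set, "+", fixed = TRUE)) ==
                    sn$history$stage))
  # determinism
  sn2 <- run_snail(fm, pools, cfg)
  expect_identical(as.data.frame(sn$history), as.data.frame(sn2$history))
})

test_that("flat (severity-0-like) scores trigger the patience stop early", {
  fm <- simulate_feature_matrix(n_subjects = 8, reps = 2, n_informative = 1,
                                n_noise = 10, separation = 0, seed = 13)
  p <- eval_protocol(n_iterations = 4, seed = 13)
  pools <- run_bfs(fm, r_max = 1, protocol = p)
  cfg <- snail_config(source_depth = 1, max_size = 20, patience = 2,
                      protocol = p)
  sn <- run_snail(fm, pools, cfg)
  last <- max(sn$history$stage)
  expect_lt(last, 20)
  expect_lte(nrow(sn$history), 20 - 1 + 1)
})

test_that("degenerate phi reduces the spiral to greedy forward selection", {
  fm <- simulate_feature_matrix(n_subjects = 8, reps = 2, n_informative = 5,
                                n_noise = 20, seed = 14)
  p <- eval_protocol(n_iterations = 6, seed = 14)
  pools <- run_bfs(fm, r_max = 1, protocol = p)
  # 25 singles -> 5 seeds; huge phi truncates each stage pool to one set,
  # so growth after the first stage is greedy from that single parent
  cfg <- snail_config(phi = 1e9, source_depth = 1, max_size = 5,
                      patience = 10, protocol = p)
  sn <- run_snail(fm, pools, cfg)
  expect_true(all(snailfs:::truncation_size(1:50, 1e9) == 1))

  # hand-rolled greedy oracle: argmax single-feature extension of the
  # stage-2 winner over the seed alphabet, under the same tie-break key
  alphabet <- unlist(strsplit(top_quintile(pools$r1)$features, "+", fixed = TRUE))
  current <- strsplit(sn$history$best_set[1], "+", fixed = TRUE)[[1]]
  greedy_path <- character(0)
  while (length(current) < 5) {
    cands <- setdiff(alphabet, current)
    if (length(cands) == 0) break
    evs <- lapply(cands, function(f) evaluate(fm, c(current, f), p))
    scores <- vapply(evs, function(e) e$mean_ccr, numeric(1))
    sds <- vapply(evs, function(e) e$sd_ccr, numeric(1))
    keys <- vapply(cands, function(f) paste(sort(c(current, f)), collapse = "+"),
                   character(1), USE.NAMES = FALSE)
    ord <- order(-scores, sds, keys)
    current <- sort(c(current, cands[ord[1]]))
    greedy_path <- c(greedy_path, paste(current, collapse = "+"))
  }
  expect_equal(sn$history$best_set[-1], greedy_path)
})

test_that("compare_sources runs identical seeds per depth and reports overlap", {
  fm <- simulate_feature_matrix(n_subjects = 8, reps = 2, n_informative = 3,
                                n_noise = 6, seed = 15)
  p <- eval_protocol(n_iterations = 5, seed = 15)
  pools <- run_bfs(fm, r_max = 2, protocol = p,
                   max_candidates = 100, allow_large = TRUE)
  cfg <- snail_config(max_size = 5, protocol = p)
  cs <- compare_sources(fm, pools, cfg, depths = c(2, 2))
  # identical sources with identical seeds give identical winners
  expect_equal(cs$results$best_set[1], cs$results$best_set[2])
  expect_equal(cs$overlap$jaccard, 1)
  cs2 <- compare_sources(fm, pools, cfg, depths = 1:2)
  expect_equal(nrow(cs2$results), 2)
  expect_equal(cs2$overlap$jaccard,
               snailfs:::jaccard(strsplit(cs2$results$best_set[1], "+", fixed = TRUE)[[1]],
                                 strsplit(cs2$results$best_set[2], "+", fixed = TRUE)[[1]]))
})

test_that("snail_config validates the 5-20 size envelope and phi", {
  expect_error(snail_config(min_size = 3), class = "snailfs_config_error")
  expect_error(snail_config(max_size = 25), class = "snailfs_config_error")
  expect_error(snail_config(phi = 1), class = "snailfs_config_error")
})
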