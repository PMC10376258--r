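#' SNAiL search configuration
#'
#' The semi-brute-force navigated amalgamation in linkage (SNAiL) grows
#' feature sets from brute-force seed pools up to `max_size` features,
#' using the golden ratio `phi = 1.618` both to pick the parents of each
#' growth stage (top `1/phi` fraction of the pool) and to truncate the
#' ranked candidate pool after scoring (`ceiling(k / phi)` kept).
#'
#' @param phi Magnification/truncation factor (> 1, default 1.618).
#' @param min_size Smallest reported set size (default 5).
#' @param max_size Largest set size grown (default 20).
#' @param source_depth Which brute-force levels seed the search (1 to 4;
#'   default 2 = mono-to-binary sourcing).
#' @param patience Stages without improvement before stopping, the
#'   deferred-overfitting criterion (default 2).
#' @param protocol An [eval_protocol()].
#' @return A `snail_config` list.
#' @export
snail_config <- function(phi = 1.618, min_size = 5, max_size = 20,
                         source_depth = 2, patience = 2,
                         protocol = eval_protocol()) {
  phi <- check_number(phi, "phi", lo = 1 + 1e-9)
  min_size <- check_count(min_size, "min_size")
  max_size <- check_count(max_size, "max_size")
  if (min_size < 5L || max_size > 20L || min_size > max_size)
    abort_config("need 5 <= min_size <= max_size <= 20")
  structure(list(phi = phi, min_size = min_size, max_size = max_size,
                 source_depth = check_count(source_depth, "source_depth"),
                 patience = check_count(patience, "patience"),
                 protocol = protocol),
            class = "snail_config")
}

#' Seed pool from brute-force rankings
#'
#' The union of the top-quintile candidates of every brute-force pool up to
#' `source_depth`, re-sorted by the ranking key.
#'
#' @param bfs_pools Named list of `ranked_pool`s from [run_bfs()].
#' @param cfg A [snail_config()].
#' @return A `ranked_pool` of seed candidates.
#' @export
seed_pool <- function(bfs_pools, cfg) {
  depths <- vapply(bfs_pools, function(p) p$r[1], numeric(1))
  use <- bfs_pools[depths <= cfg$source_depth]
  if (length(use) == 0L || any(vapply(use, nrow, integer(1)) == 0L))
    abort_protocol("seed pools missing or empty for the requested source depth")
  seeds <- dplyr::bind_rows(lapply(use, top_quintile))
  seeds <- seeds[!duplicated(seeds$features), ]
  new_ranked_pool(seeds)
}

parent_count <- function(pool_size, phi) {
  min(pool_size, max(2L, round(pool_size / phi)))
}

truncation_size <- function(k, phi) max(1L, ceiling(k / phi))

#' Propose grown candidates for the next SNAiL stage
#'
#' Parents are the top `max(2, round(|pool| / phi))` sets of the current
#' pool; each parent is extended by one feature drawn from the extension
#' alphabet (seed-pool features plus features present in any parent),
#' deduplicated canonically and capped at `ceiling(phi * |pool|)`
#' candidates in parent-rank order.
#'
#' @param pool Current `ranked_pool` of size-m candidates.
#' @param seeds Seed `ranked_pool` (defines the extension alphabet).
#' @param cfg A [snail_config()].
#' @return Character vector of candidate keys (sorted `+`-joined sets),
#'   each with m + 1 features.
#' @export
propose_candidates <- function(pool, seeds, cfg) {
  if (nrow(pool) == 0L) abort_protocol("cannot propose from an empty pool")
  n_par <- parent_count(nrow(pool), cfg$phi)
  parents <- strsplit(pool$features[seq_len(n_par)], "+", fixed = TRUE)
  alphabet <- unique(c(
    unlist(strsplit(seeds$features, "+", fixed = TRUE)),
    unlist(parents)))
  cap <- ceiling(cfg$phi * nrow(pool))
  out <- character(0)
  for (p in parents) {
    ext <- setdiff(alphabet, p)
    if (length(ext) == 0L) next
    keys <- vapply(ext, function(f) paste(sort(c(p, f)), collapse = "+"),
                   character(1), USE.NAMES = FALSE)
    out <- c(out, keys[!(keys %in% out)])
    if (length(out) >= cap) { out <- out[seq_len(cap)]; break }
  }
  if (length(out) == 0L)
    abort_protocol("search exhausted: every alphabet feature already in every parent")
  out
}

#' Run the SNAiL semi-brute-force spiral search
#'
#' Starting from the brute-force seed pool, the search repeatedly proposes
#' size-(m+1) candidates, scores them with the shared-split evaluator,
#' ranks them, truncates the pool by the golden ratio, and reimplants the
#' stage winners into the seed pool. It stops at `max_size` or once the
#' best mean CCR has not improved for `patience` consecutive stages (the
#' deferred-overfitting rule). Scored sets are cached so a set re-proposed
#' at a later stage is never re-evaluated.
#'
#' @param fm A `feature_matrix`.
#' @param bfs_pools Named list of `ranked_pool`s from [run_bfs()].
#' @param cfg A [snail_config()].
#' @return A `snail_result`: `best` (one-row tibble of the best set found),
#'   `history` (per-stage tibble: stage, n_candidates, best_set, mean_ccr,
#'   sd_ccr, best_overall), `pool` (final stage pool), and `config`.
#' @export
run_snail <- function(fm, bfs_pools, cfg = snail_config()) {
  stopifnot(inherits(cfg, "snail_config"))
  seeds <- seed_pool(bfs_pools, cfg)
  # stage pools are uniform-size (grow-by-one rule); the deepest-sourced
  # seeds start the spiral while the full union feeds the alphabet
  seed_sizes <- lengths(strsplit(seeds$features, "+", fixed = TRUE))
  pool <- new_ranked_pool(seeds[seed_sizes == max(seed_sizes), ])
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(seeds)))
    assign(seeds$features[i], c(seeds$mean_ccr[i], seeds$sd_ccr[i]), envir = cache)
  score <- function(key) {
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- evaluate(fm, strsplit(key, "+", fixed = TRUE)[[1]], cfg$protocol)
    cache[[key]] <- c(res$mean_ccr, res$sd_ccr)
    cache[[key]]
  }
  best_overall <- pool[1, ]
  history <- list()
  stall <- 0L
  m <- max(vapply(strsplit(pool$features, "+", fixed = TRUE), length, integer(1)))
  while (m < cfg$max_size) {
    cand <- tryCatch(propose_candidates(pool, seeds, cfg),
                     snailfs_protocol_error = function(e) character(0))
    if (length(cand) == 0L) break
    sc <- t(vapply(cand, score, numeric(2), USE.NAMES = FALSE))
    stage_pool <- new_ranked_pool(tibble::tibble(
      features = cand, r = m + 1L, mean_ccr = unname(sc[, 1]),
      sd_ccr = unname(sc[, 2])))
    keep <- truncation_size(nrow(stage_pool), cfg$phi)
    pool <- stage_pool[seq_len(keep), ]
    # reimplant stage winners into the seed pool for later alphabets
    seeds <- new_ranked_pool(dplyr::bind_rows(seeds, pool[1, ]))
    m <- m + 1L
    improved <- pool$mean_ccr[1] > best_overall$mean_ccr[1] + 1e-12
    if (improved) { best_overall <- pool[1, ]; stall <- 0L } else
      stall <- stall + 1L
    history[[length(history) + 1L]] <- tibble::tibble(
      stage = m, n_candidates = nrow(stage_pool),
      best_set = pool$features[1], mean_ccr = pool$mean_ccr[1],
      sd_ccr = pool$sd_ccr[1], best_overall = best_overall$mean_ccr[1])
    if (m >= cfg$min_size && stall >= cfg$patience) break
  }
  structure(list(best = best_overall,
                 history = dplyr::bind_rows(history),
                 pool = pool, config = cfg),
            class = "snail_result")
}

#' @export
print.snail_result <- function(x, ...) {
  cat(sprintf("<snail_result> best set (%d features, mean CCR %.2f%%):\n  %s\n",
              length(strsplit(x$best$features, "+", fixed = TRUE)[[1]]),
              x$best$mean_ccr, x$best$features))
  cat(sprintf("  %d stages explored\n", nrow(x$history)))
  invisible(x)
}

#' @rdname tidy.eval_result
#' @method tidy snail_result
#' @export
tidy.snail_result <- function(x, ...) x$history

#' @rdname tidy.eval_result
#' @method glance snail_result
#' @export
glance.snail_result <- function(x, ...) {
  tibble::tibble(best_set = x$best$features,
                 n_features = length(strsplit(x$best$features, "+",
                                              fixed = TRUE)[[1]]),
                 mean_ccr = x$best$mean_ccr, sd_ccr = x$best$sd_ccr,
                 n_stages = nrow(x$history))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Compare SNAiL runs across brute-force source depths
#'
#' Runs the spiral search once per requested source depth under identical
#' seeds and reports each depth's best set plus the Jaccard overlap between
#' depth-specific winners.
#'
#' @param fm A `feature_matrix`.
#' @param bfs_pools Named list of `ranked_pool`s covering the requested
#'   depths.
#' @param cfg A [snail_config()]; its `source_depth` is overridden.
#' @param depths Source depths to compare (default 2:4, clipped to the
#'   available pools).
#' @return List with `results` (tibble: source_depth, best_set, mean_ccr,
#'   sd_ccr) and `overlap` (tibble: depth_a, depth_b, jaccard).
#' @export
compare_sources <- function(fm, bfs_pools, cfg = snail_config(),
                            depths = 2:4) {
  avail <- vapply(bfs_pools, function(p) p$r[1], numeric(1))
  depths <- depths[depths <= max(avail)]
  if (length(depths) == 0L) abort_config("no usable source depths")
  runs <- lapply(depths, function(d) {
    cfg_d <- cfg; cfg_d$source_depth <- as.integer(d)
    run_snail(fm, bfs_pools, cfg_d)
  })
  results <- dplyr::bind_rows(lapply(seq_along(depths), function(i)
    tibble::tibble(source_depth = depths[i],
                   best_set = runs[[i]]$best$features,
                   mean_ccr = runs[[i]]$best$mean_ccr,
                   sd_ccr = runs[[i]]$best$sd_ccr)))
  ov <- list()
  for (i in seq_along(depths)) for (j in seq_along(depths)) {
    if (i >= j) next
    ov[[length(ov) + 1L]] <- tibble::tibble(
      depth_a = depths[i], depth_b = depths[j],
      jaccard = jaccard(strsplit(runs[[i]]$best$features, "+", fixed = TRUE)[[1]],
                        strsplit(runs[[j]]$best$features, "+", fixed = TRUE)[[1]]))
  }
  list(results = results,
       overlap = if (length(ov)) dplyr::bind_rows(ov)
                 else tibble::tibble(depth_a = numeric(), depth_b = numeric(),
                                     jaccard = numeric()))
}
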