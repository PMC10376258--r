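#' Number of size-r feature combinations
#'
#' `n! / (r! (n-r)!)`: the size of the brute-force search space over `n`
#' features at concatenation level `r`.
#'
#' @param n Number of features.
#' @param r Combination size.
#' @return The binomial coefficient, as a double (exact for this range).
#' @examples
#' n_combinations(127, 2)  # 8001
#' @export
n_combinations <- function(n, r) {
  n <- check_count(n, "n"); r <- check_count(r, "r")
  if (r > n) abort_config("r must not exceed n")
  choose(n, r)
}

#' Stream all size-r combinations of a name list
#'
#' Lexicographic streaming enumerator: yields canonical (sorted-index)
#' combinations in batches without materializing the full set, so tetra
#' level enumeration over 127 names stays memory-bounded.
#'
#' @param names Ordered character vector of feature names.
#' @param r Combination size (1 to `length(names)`).
#' @return A closure; each call returns a character matrix with `r` columns
#'   (one combination per row, up to `batch` rows) or `NULL` when the
#'   stream is exhausted.
#' @param batch Maximum combinations per yielded batch (default 10000).
#' @export
combination_stream <- function(names, r, batch = 10000L) {
  n <- length(names)
  r <- check_count(r, "r")
  if (r > n) abort_config("r must not exceed the number of names")
  idx <- seq_len(r)
  done <- FALSE
  function() {
    if (done) return(NULL)
    out <- matrix(NA_integer_, nrow = batch, ncol = r)
    k <- 0L
    while (k < batch) {
      k <- k + 1L
      out[k, ] <- idx
      # lexicographic successor
      j <- r
      while (j >= 1L && idx[j] == n - r + j) j <- j - 1L
      if (j < 1L) { done <<- TRUE; break }
      idx[j] <<- idx[j] + 1L
      if (j < r) for (t in (j + 1L):r) idx[t] <<- idx[t - 1L] + 1L
    }
    matrix(names[out[seq_len(k), , drop = FALSE]], nrow = k)
  }
}

new_ranked_pool <- function(df) {
  df <- dplyr::arrange(df, dplyr::desc(.data$mean_ccr), .data$sd_ccr,
                       .data$features)
  class(df) <- c("ranked_pool", class(df))
  df
}

pool_key <- function(feature_list) {
  vapply(feature_list, function(f) paste(sort(f), collapse = "+"), character(1))
}

#' Exhaustive brute-force search over feature combinations
#'
#' Scores every combination of `r = 1..r_max` features with the subject-wise
#' SVM evaluator and ranks each level by (mean CCR desc, SD asc, name).
#' Per-level results can be checkpointed to CSV and a run resumed without
#' rescoring completed candidates.
#'
#' @param fm A `feature_matrix`.
#' @param features Candidate feature names (default: all features in `fm`).
#' @param r_max Maximum combination size, 1 to 4.
#' @param protocol An [eval_protocol()].
#' @param checkpoint_dir Optional directory for per-level checkpoint CSVs
#'   (`bfs_r<r>.csv`); an interrupted run resumes from them.
#' @param allow_large Guard flag: combination spaces above
#'   `max_candidates` (default 20000) are refused unless TRUE.
#' @param max_candidates Desk-scale candidate budget per level.
#' @return Named list of `ranked_pool` tibbles (`r1`, `r2`, ...), each with
#'   columns features (the sorted `+`-joined set), r, mean_ccr, sd_ccr.
#' @export
run_bfs <- function(fm, features = NULL, r_max = 2,
                    protocol = eval_protocol(), checkpoint_dir = NULL,
                    allow_large = FALSE, max_candidates = 20000) {
  r_max <- check_count(r_max, "r_max")
  if (r_max > 4L) abort_config("r_max is capped at 4 (mono-to-tetra search)")
  features <- features %||% unique(feature_map(fm)$feature)
  features <- sort(unique(features))
  pools <- list()
  for (r in seq_len(min(r_max, length(features)))) {
    n_cand <- n_combinations(length(features), r)
    if (n_cand > max_candidates && !allow_large)
      abort_config(sprintf(
        "level r=%d has %.0f candidates; pass allow_large=TRUE to proceed",
        r, n_cand))
    ck_path <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, sprintf("bfs_r%d.csv", r)) else NULL
    scored <- if (!is.null(ck_path) && file.exists(ck_path))
      readr::read_csv(ck_path, show_col_types = FALSE, progress = FALSE)
    else tibble::tibble(features = character(), r = integer(),
                        mean_ccr = numeric(), sd_ccr = numeric())
    have <- scored$features
    stream <- combination_stream(features, r)
    rows <- list(dplyr::as_tibble(scored))
    repeat {
      b <- stream()
      if (is.null(b)) break
      for (i in seq_len(nrow(b))) {
        key <- paste(sort(b[i, ]), collapse = "+")
        if (key %in% have) next
        res <- evaluate(fm, b[i, ], protocol)
        row <- tibble::tibble(features = key, r = r,
                              mean_ccr = res$mean_ccr, sd_ccr = res$sd_ccr)
        rows[[length(rows) + 1L]] <- row
        if (!is.null(ck_path)) {
          readr::write_csv(row, ck_path, append = file.exists(ck_path),
                           progress = FALSE)
        }
      }
    }
    pools[[paste0("r", r)]] <- new_ranked_pool(dplyr::bind_rows(rows))
  }
  pools
}

#' Top-quintile cutoff of a ranked pool
#'
#' Keeps the first `ceiling(0.2 * nrow(pool))` candidates of the ranking.
#'
#' @param pool A `ranked_pool` tibble.
#' @return The truncated `ranked_pool` (a prefix of the input).
#' @export
top_quintile <- function(pool) {
  if (nrow(pool) == 0L) abort_protocol("cannot take the quintile of an empty pool")
  k <- ceiling(0.2 * nrow(pool))
  pool[seq_len(k), ]
}

#' Domain distribution of a candidate pool
#'
#' Classifies every candidate set by the multiset of its features' domains:
#' single-domain pools are labelled by that domain (`"TD-only"` etc.), sets
#' mixing TD with anything else are `"TD+Other"`, and non-TD mixtures are
#' `"multi-domain"`. Proportions sum to one.
#'
#' @param pool A `ranked_pool`.
#' @param registry A [feature_registry()].
#' @return Tibble with columns `combination` and `proportion`.
#' @export
domain_distribution <- function(pool, registry = feature_registry()) {
  if (nrow(pool) == 0L)
    return(tibble::tibble(combination = character(), proportion = numeric()))
  cls <- vapply(strsplit(pool$features, "+", fixed = TRUE), function(fs) {
    doms <- unique(feature_domains(fs, registry))
    if (length(doms) == 1L) paste0(doms, "-only")
    else if ("TD" %in% doms) "TD+Other"
    else "multi-domain"
  }, character(1))
  out <- dplyr::count(tibble::tibble(combination = cls), .data$combination)
  tibble::tibble(combination = out$combination,
                 proportion = out$n / sum(out$n))
}

#' Lineage trace across brute-force levels
#'
#' Connects each size-r candidate to the size-(r+1) candidates that contain
#' it, restricted to the top `top_k` of each pool; the superset edges trace
#' how superior features persist into larger combinations.
#'
#' @param pools Named list of `ranked_pool`s (as from [run_bfs()]).
#' @param top_k Candidates retained per pool (default 50).
#' @return Tibble of edges: from_r, from, to_r, to.
#' @export
linkage_trace <- function(pools, top_k = 50) {
  if (length(pools) < 2L) abort_config("linkage tracing needs >= 2 pools")
  rs <- sort(vapply(pools, function(p) p$r[1], numeric(1)))
  edges <- list()
  for (j in seq_len(length(rs) - 1L)) {
    a <- pools[[which(vapply(pools, function(p) p$r[1], numeric(1)) == rs[j])]]
    b <- pools[[which(vapply(pools, function(p) p$r[1], numeric(1)) == rs[j + 1])]]
    a <- a[seq_len(min(top_k, nrow(a))), ]
    b <- b[seq_len(min(top_k, nrow(b))), ]
    fa <- strsplit(a$features, "+", fixed = TRUE)
    fb <- strsplit(b$features, "+", fixed = TRUE)
    for (i in seq_along(fa)) for (k in seq_along(fb)) {
      if (all(fa[[i]] %in% fb[[k]]))
        edges[[length(edges) + 1L]] <- tibble::tibble(
          from_r = rs[j], from = a$features[i],
          to_r = rs[j + 1], to = b$features[k])
    }
  }
  if (length(edges) == 0L)
    return(tibble::tibble(from_r = numeric(), from = character(),
                          to_r = numeric(), to = character()))
  dplyr::bind_rows(edges)
}

#' Export a lineage trace as JSON
#'
#' @param edges Edge tibble from [linkage_trace()].
#' @param path JSON path.
#' @export
write_linkage <- function(edges, path) {
  jsonlite::write_json(edges, path, digits = NA)
  invisible(path)
}
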