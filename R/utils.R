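# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(msg) stop(structure(
  class = c("snailfs_config_error", "error", "condition"),
  list(message = msg, call = NULL)))

abort_format <- function(msg) stop(structure(
  class = c("snailfs_format_error", "error", "condition"),
  list(message = msg, call = NULL)))

abort_degenerate <- function(msg) stop(structure(
  class = c("snailfs_degenerate_error", "error", "condition"),
  list(message = msg, call = NULL)))

abort_protocol <- function(msg) stop(structure(
  class = c("snailfs_protocol_error", "error", "condition"),
  list(message = msg, call = NULL)))

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    abort_config(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < lo || x > hi)
    abort_config(sprintf("`%s` must be a single finite number in [%s, %s]",
                         name, format(lo), format(hi)))
  as.numeric(x)
}

#' @importFrom stats runif rnorm median mad sd var quantile fft
NULL

# Deterministic small integer hash of a sorted character vector, used in the
# evaluator seed ladder so every candidate sees the same split sequence only
# when configured to (candidate_hash = 0 pairs all candidates on one ladder).
name_hash <- function(names) {
  s <- paste(sort(names), collapse = "|")
  h <- 0
  for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% 1048573
  as.integer(h)
}

# Seed ladder: combine base seed, iteration index and candidate hash into a
# 31-bit seed. Keeps every derived seed below 2^31.
ladder_seed <- function(seed, iteration, candidate_hash = 0L) {
  # double arithmetic: products exceed .Machine$integer.max long before
  # losing exactness below 2^53
  as.integer((abs(as.numeric(seed)) * 2654435 + as.numeric(iteration) * 97003 +
                as.numeric(candidate_hash)) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Canonical feature-name normalization: upper case, dashes/underscores and
# whitespace stripped, so "EWT-4", "ewt_4" and "EWT4" name one registry entry.
normalize_feature_name <- function(x) {
  x <- gsub("[-_ ]", "", toupper(trimws(x)))
  # literature aliases: the AR-derived cepstral coefficients appear as CC-R
  x[x == "CCR"] <- "CC"
  x
}
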