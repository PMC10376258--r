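#' Canonical multi-feature baseline sets (MFS1-MFS8)
#'
#' The eight literature feature sets used as comparison baselines:
#' Hudgins' TD set (MFS1), TD-AR (MFS2), TD-NLS (MFS3), Du's set (MFS4),
#' the NTDFS time-domain set (MFS5), TD-DFA (MFS6), Oskoei & Hu's set
#' (MFS7) and Wang's set (MFS8).
#'
#' @return Named list of character vectors of registry feature names.
#' @examples
#' mfs_baselines()$MFS1
#' @export
mfs_baselines <- function() {
  list(
    MFS1 = c("MAV", "WL", "ZC", "SSC"),
    MFS2 = c("RMS", "AR6"),
    MFS3 = c("LMAV", "NSV"),
    MFS4 = c("IEMG", "VAR", "WL", "ZC", "SSC", "WAMP"),
    MFS5 = c("SSI", "RSD1", "RSD2", "MSR", "ASM", "ROG"),
    MFS6 = c("ZC", "SSC", "AR4", "PSR", "DFA", "HFD"),
    MFS7 = c("MAV", "RMS", "WL", "VAR", "ZC", "SSC", "WAMP", "MMAV1",
             "MMAV2", "PSP", "AR2", "AR5", "MDF", "MNF"),
    MFS8 = c("MAV", "VAR", "AR4", "ZC", "MNF", "MDF"))
}

#' One-tailed unpaired t-test on CCR samples
#'
#' Pooled-variance (Student) two-sample t-test of H1: mean(a) > mean(b),
#' with DF = n1 + n2 - 2 (two 100-iteration groups give DF = 198). The
#' pooled form matches equal-n cross-validation comparisons. Zero pooled
#' variance is handled explicitly: equal means give t = 0, p = 0.5;
#' unequal means give the limit p of 0 or 1 with `degenerate = TRUE`.
#'
#' @param group_a,group_b Numeric CCR vectors, each length >= 2.
#' @return List with `t`, `df`, `p` and `degenerate`.
#' @examples
#' t_test_one_tailed(rnorm(100, 76, 12), rnorm(100, 60, 12))$df  # 198
#' @export
t_test_one_tailed <- function(group_a, group_b) {
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 2L || n2 < 2L)
    abort_protocol("each group needs >= 2 observations")
  df <- n1 + n2 - 2L
  pooled <- ((n1 - 1) * stats::var(group_a) + (n2 - 1) * stats::var(group_b)) / df
  if (pooled == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = df, p = 0.5, degenerate = FALSE))
    p <- if (mean(group_a) > mean(group_b)) 0 else 1
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf, df = df,
                p = p, degenerate = TRUE))
  }
  ht <- stats::t.test(group_a, group_b, alternative = "greater",
                      var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), degenerate = FALSE)
}

significance_stars <- function(p) {
  dplyr::case_when(p < 1e-4 ~ "****", p < 1e-3 ~ "***",
                   p < 1e-2 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' Evaluate the full concatenated feature bank
#'
#' Scores all features of the matrix as one selection: the control
#' condition against which selected subsets are compared.
#'
#' @param fm A `feature_matrix`.
#' @param protocol An [eval_protocol()].
#' @return An `eval_result`.
#' @export
all_features_baseline <- function(fm, protocol = eval_protocol()) {
  evaluate(fm, unique(feature_map(fm)$feature), protocol)
}

#' Compare best empirical sets against the canonical baselines
#'
#' Evaluates every row (the best sets from the searches plus the MFS
#' baselines) under one protocol and seed, so all sets see the same
#' subject splits, then tests the first best set against every other row
#' with the one-tailed unpaired t-test. Output mirrors the standard
#' comparison-table schema: set id, mean CCR, SD, DF, t, p, stars.
#'
#' @param fm A `feature_matrix`.
#' @param best_sets Named list of character vectors (the empirical sets;
#'   the first is the reference).
#' @param baselines Named list of baseline sets (default [mfs_baselines()]
#'   filtered to features present in `fm`).
#' @param protocol An [eval_protocol()].
#' @return A `comparison_report` tibble: set, features, mean_ccr, sd_ccr,
#'   df, t, p, stars (reference row has NA test columns).
#' @export
compare_all <- function(fm, best_sets, baselines = mfs_baselines(),
                        protocol = eval_protocol()) {
  if (length(best_sets) == 0L) abort_config("need at least one best set")
  if (is.null(names(best_sets)))
    names(best_sets) <- sprintf("Best%d", seq_along(best_sets))
  available <- unique(feature_map(fm)$feature)
  for (nm in names(baselines)) {
    missing <- setdiff(normalize_feature_name(baselines[[nm]]),
                       normalize_feature_name(available))
    if (length(missing) > 0L)
      abort_config(sprintf("baseline %s names unavailable feature(s): %s",
                           nm, paste(missing, collapse = ", ")))
  }
  sets <- c(best_sets, baselines)
  evals <- lapply(sets, function(f) evaluate(fm, f, protocol))
  ref <- evals[[1]]
  rows <- lapply(seq_along(sets), function(i) {
    e <- evals[[i]]
    if (i == 1L)
      return(tibble::tibble(set = names(sets)[1],
                            features = paste(e$features, collapse = "+"),
                            mean_ccr = e$mean_ccr, sd_ccr = e$sd_ccr,
                            df = NA_integer_, t = NA_real_, p = NA_real_,
                            stars = ""))
    tt <- t_test_one_tailed(ref$per_iteration_ccr, e$per_iteration_ccr)
    tibble::tibble(set = names(sets)[i],
                   features = paste(e$features, collapse = "+"),
                   mean_ccr = e$mean_ccr, sd_ccr = e$sd_ccr,
                   df = as.integer(tt$df), t = tt$t, p = tt$p,
                   stars = significance_stars(tt$p))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("comparison_report", class(out))
  out
}

#' Write a comparison report as CSV and JSON
#'
#' @param report A `comparison_report`.
#' @param path Output path without extension; `.csv` and `.json` files are
#'   written.
#' @export
write_comparison <- function(report, path) {
  readr::write_csv(tibble::as_tibble(report), paste0(path, ".csv"),
                   progress = FALSE)
  jsonlite::write_json(tibble::as_tibble(report), paste0(path, ".json"),
                       digits = NA, na = "null")
  invisible(path)
}
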