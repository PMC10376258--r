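#' Run the full demonstration pipeline
#'
#' Wires every stage end to end on synthetic data: simulate, preprocess,
#' segment, extract, brute-force search, spiral search, and the statistical
#' comparison against the canonical baselines. One global seed governs all
#' stage seeds through the package's seed ladder. Each returned component
#' is the corresponding stage's native result object.
#'
#' @param cfg A [synth_config()] describing the dataset.
#' @param features Candidate feature names for the searches (default: a
#'   25-feature desk-scale subset spanning all five domains).
#' @param r_max Brute-force depth (default 2).
#' @param snail_cfg A [snail_config()]; defaults to a small search to
#'   `max_size = 8`.
#' @param protocol An [eval_protocol()]; defaults to 20 iterations.
#' @param out_dir Optional directory for artifacts (ranked CSVs, lineage
#'   JSON, comparison CSV/JSON, run manifest).
#' @return List: dataset, segments, feature_matrix, bfs_pools, snail,
#'   comparison.
#' @export
run_pipeline <- function(cfg = synth_config(n_subjects = 8, reps_per_gesture = 4),
                         features = default_search_features(),
                         r_max = 2,
                         snail_cfg = NULL,
                         protocol = eval_protocol(n_iterations = 20,
                                                  seed = cfg$seed),
                         out_dir = NULL) {
  ds <- generate_dataset(cfg)
  segs <- segment_dataset(ds)
  union_features <- unique(c(features, unlist(mfs_baselines())))
  fm <- extract_features(segs, features = union_features)
  pools <- run_bfs(fm, features = resolve_features(features), r_max = r_max,
                   protocol = protocol,
                   checkpoint_dir = out_dir)
  snail_cfg <- snail_cfg %||% snail_config(max_size = 8, source_depth = min(r_max, 2),
                                           protocol = protocol)
  sn <- run_snail(fm, pools, snail_cfg)
  best <- strsplit(sn$best$features, "+", fixed = TRUE)[[1]]
  cmp <- compare_all(fm, best_sets = list(SNAiL = best), protocol = protocol)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(pools))
      readr::write_csv(tibble::as_tibble(pools[[nm]]),
                       file.path(out_dir, sprintf("ranked_%s.csv", nm)),
                       progress = FALSE)
    if (length(pools) >= 2L)
      write_linkage(linkage_trace(pools), file.path(out_dir, "lineage.json"))
    write_comparison(cmp, file.path(out_dir, "comparison"))
    jsonlite::write_json(
      list(seed = cfg$seed, n_subjects = cfg$n_subjects,
           features = features, r_max = r_max,
           n_iterations = protocol$n_iterations,
           snail_max_size = snail_cfg$max_size,
           package_version = as.character(utils::packageVersion("snailfs"))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(dataset = ds, segments = segs, feature_matrix = fm,
       bfs_pools = pools, snail = sn, comparison = cmp)
}

#' Default desk-scale search feature subset
#'
#' Twenty-five features spanning all five domains, used by the demo
#' pipeline so brute-force levels stay desk-sized.
#'
#' @return Character vector of feature names.
#' @export
default_search_features <- function() {
  c("MAV", "IEMG", "RMS", "VAR", "SSI", "WL", "ZC", "SSC", "WAMP", "MMAV5",
    "MSR", "RSM0", "LMAV", "LSSI", "NSV",
    "MNF", "MDF", "MASP", "PERC2",
    "DWT", "STFT", "EWP6",
    "FR4", "HFD",
    "SDMAVR")
}
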