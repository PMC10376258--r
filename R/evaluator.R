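#' Cross-validation protocol
#'
#' Repeated random subject-wise holdout: in every iteration
#' `max(1, round(n_subjects * test_fraction))` subjects are held out (with
#' 19 subjects and the default fraction 0.1 that is 2 subjects), the
#' classifier is trained on the rest, and the correct classification rate
#' (CCR) is measured on the held-out subjects' instances. The headline
#' score of a feature set is the mean CCR over iterations.
#'
#' @param test_fraction Fraction of subjects held out (default 0.1).
#' @param n_iterations Number of holdout repetitions (default 100).
#' @param kernel SVM kernel, `"linear"` (default) or `"radial"`.
#' @param cost Soft-margin cost C (default 1).
#' @param standardize Standardize columns on training statistics
#'   (default TRUE).
#' @param seed Base seed of the split ladder; iteration i of candidate c
#'   uses a seed derived from (seed, i, hash(c)) so runs are reproducible.
#' @param paired_splits If TRUE (default) the candidate hash is dropped
#'   from the ladder, so every candidate sees the same split sequence and
#'   rankings are paired comparisons.
#' @param max_redraws Redraw budget for splits whose training fold misses a
#'   class (default 10).
#' @return An `eval_protocol` list.
#' @export
eval_protocol <- function(test_fraction = 0.1, n_iterations = 100,
                          kernel = c("linear", "radial"), cost = 1,
                          standardize = TRUE, seed = 1,
                          paired_splits = TRUE, max_redraws = 10) {
  if (test_fraction <= 0 || test_fraction >= 0.5)
    abort_config("test_fraction must lie in (0, 0.5)")
  structure(list(
    test_fraction = test_fraction,
    n_iterations = check_count(n_iterations, "n_iterations"),
    kernel = match.arg(kernel), cost = check_number(cost, "cost", lo = 1e-9),
    standardize = isTRUE(standardize), seed = check_count(seed, "seed", min = 0L),
    paired_splits = isTRUE(paired_splits),
    max_redraws = check_count(max_redraws, "max_redraws")),
    class = "eval_protocol")
}

#' Random subject-wise split
#'
#' @param subject_ids Character vector of distinct subject ids (>= 3).
#' @param test_fraction Fraction of subjects to hold out.
#' @return List with `train` and `test` id vectors; disjoint and exhaustive.
#'   Test size is `max(1, round(n * test_fraction))`.
#' @export
split_subjects <- function(subject_ids, test_fraction = 0.1) {
  subject_ids <- unique(subject_ids)
  n <- length(subject_ids)
  if (n < 3L) abort_protocol("subject-wise splitting needs >= 3 subjects")
  n_test <- max(1L, round(n * test_fraction))
  test <- sample(subject_ids, n_test)
  list(train = setdiff(subject_ids, test), test = test)
}

#' Correct classification rate
#'
#' `100 * (# matching labels) / length`.
#'
#' @param predicted,truth Equal-length label vectors.
#' @return CCR in percent.
#' @export
ccr <- function(predicted, truth) {
  if (length(predicted) == 0L || length(predicted) != length(truth))
    abort_protocol("ccr needs equal-length non-empty label vectors")
  100 * mean(as.character(predicted) == as.character(truth))
}

#' Evaluate a feature selection by repeated subject-wise SVM holdout
#'
#' For each iteration: draw a subject-wise split, standardize the selected
#' columns on training statistics only, fit a one-vs-one soft-margin SVM on
#' the training subjects, and score CCR on the held-out subjects. Splits
#' whose training fold misses a class are redrawn (bounded). Constant
#' training columns are dropped for that iteration.
#'
#' @param fm A `feature_matrix`.
#' @param features Feature names to evaluate (non-empty).
#' @param protocol An [eval_protocol()].
#' @param .instrument Optional function called once per iteration with
#'   `list(iteration, train_subjects, test_subjects, standardized_on)`;
#'   used to audit the absence of train/test leakage.
#' @return An `eval_result`: mean_ccr, sd_ccr, per_iteration_ccr,
#'   n_iterations, features, seed.
#' @export
evaluate <- function(fm, features, protocol = eval_protocol(),
                     .instrument = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(features) == 0L) abort_config("empty feature selection")
  cols <- feature_columns(fm, features)
  subjects <- fm$subject
  labels <- factor(fm$label)
  if (nlevels(labels) < 2L) abort_protocol("need >= 2 classes to evaluate")
  if (length(unique(subjects)) < 3L) abort_protocol("need >= 3 subjects")
  X <- as.matrix(fm[, cols, drop = FALSE])
  chash <- if (protocol$paired_splits) 0L else name_hash(features)
  per_iter <- numeric(protocol$n_iterations)
  for (i in seq_len(protocol$n_iterations)) {
    draw <- 0L
    repeat {
      sp <- with_seed(ladder_seed(protocol$seed, i + 1000L * draw, chash),
                      split_subjects(subjects, protocol$test_fraction))
      tr <- subjects %in% sp$train
      if (nlevels(droplevels(labels[tr])) == nlevels(labels)) break
      draw <- draw + 1L
      if (draw > protocol$max_redraws)
        abort_protocol(sprintf("iteration %d: training fold misses a class after %d redraws",
                               i, protocol$max_redraws))
    }
    te <- !tr
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (protocol$standardize) {
      mu <- colMeans(Xtr); sg <- apply(Xtr, 2, stats::sd)
      keep <- sg > 0
      if (!any(keep))
        abort_degenerate("all selected columns are constant on the training fold")
      Xtr <- sweep(sweep(Xtr[, keep, drop = FALSE], 2, mu[keep]), 2, sg[keep], "/")
      Xte <- sweep(sweep(Xte[, keep, drop = FALSE], 2, mu[keep]), 2, sg[keep], "/")
    }
    if (!is.null(.instrument))
      .instrument(list(iteration = i, train_subjects = sp$train,
                       test_subjects = sp$test,
                       standardized_on = unique(subjects[tr])))
    fit <- e1071::svm(Xtr, droplevels(labels[tr]), kernel = protocol$kernel,
                      cost = protocol$cost, scale = FALSE)
    pred <- stats::predict(fit, Xte)
    per_iter[i] <- ccr(pred, labels[te])
  }
  structure(list(
    mean_ccr = mean(per_iter),
    sd_ccr = stats::sd(per_iter),
    per_iteration_ccr = per_iter,
    n_iterations = protocol$n_iterations,
    features = sort(resolve_features(features, feature_registry_of(fm))),
    seed = protocol$seed),
    class = "eval_result")
}

# Resolving against the global registry would reject simulated feature
# names (INF1 etc.), so resolution is done against the matrix's own map.
feature_registry_of <- function(fm) {
  m <- feature_map(fm)
  structure(list(specs = tibble::tibble(
    name = unique(m$feature),
    domain = m$domain[match(unique(m$feature), m$feature)],
    arity = 1L, kind = "channel", fn = vector("list", length(unique(m$feature))))),
    class = "feature_registry")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> {%s}: mean CCR %.2f%% (SD %.2f) over %d iterations\n",
              paste(x$features, collapse = ", "), x$mean_ccr, x$sd_ccr,
              x$n_iterations))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation result
#'
#' @param x An `eval_result`.
#' @param ... Unused.
#' @return One row per iteration: iteration, ccr.
#' @method tidy eval_result
#' @export
tidy.eval_result <- function(x, ...) {
  tibble::tibble(iteration = seq_len(x$n_iterations),
                 ccr = x$per_iteration_ccr)
}

#' @rdname tidy.eval_result
#' @return For `glance`: a one-row summary (features, mean_ccr, sd_ccr,
#'   n_iterations, seed).
#' @method glance eval_result
#' @export
glance.eval_result <- function(x, ...) {
  tibble::tibble(features = paste(x$features, collapse = "+"),
                 n_features = length(x$features),
                 mean_ccr = x$mean_ccr, sd_ccr = x$sd_ccr,
                 n_iterations = x$n_iterations, seed = x$seed)
}
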