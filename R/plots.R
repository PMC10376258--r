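#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-iteration CCR of an evaluation
#'
#' @param object An `eval_result`.
#' @param ... Unused.
#' @return A ggplot: CCR per holdout iteration with the mean marked.
#' @method autoplot eval_result
#' @export
autoplot.eval_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$ccr)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_ccr, colour = "red") +
    ggplot2::labs(x = "holdout iteration", y = "CCR (%)",
                  title = paste(object$features, collapse = " + ")) +
    ggplot2::theme_minimal()
}

#' Plot the SNAiL growth trajectory
#'
#' @param object A `snail_result`.
#' @param ... Unused.
#' @return A ggplot: best stage CCR and running best against set size.
#' @method autoplot snail_result
#' @export
autoplot.snail_result <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$stage)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$mean_ccr), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$best_overall), colour = "red") +
    ggplot2::geom_point(ggplot2::aes(y = .data$best_overall), colour = "red") +
    ggplot2::labs(x = "feature-set size", y = "mean CCR (%)",
                  title = "Spiral amalgamation trajectory") +
    ggplot2::theme_minimal()
}

#' Plot a comparison report
#'
#' @param object A `comparison_report` from [compare_all()].
#' @param ... Unused.
#' @return A ggplot: mean CCR with SD error bars and significance stars.
#' @method autoplot comparison_report
#' @export
autoplot.comparison_report <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$set <- factor(d$set, levels = d$set)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$set, y = .data$mean_ccr)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_ccr - .data$sd_ccr,
                                        ymax = .data$mean_ccr + .data$sd_ccr),
                           width = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars,
                                    y = .data$mean_ccr + .data$sd_ccr + 2)) +
    ggplot2::labs(x = NULL, y = "mean CCR (%)",
                  title = "Feature-set comparison") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the domain distribution of a ranked pool's top quintile
#'
#' @param distribution Tibble from [domain_distribution()].
#' @return A ggplot bar chart of domain-combination proportions.
#' @export
plot_domain_distribution <- function(distribution) {
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = .data$combination, y = .data$proportion)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "proportion of top candidates") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
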