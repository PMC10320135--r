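# broom-style tidiers and ggplot2 autoplot methods for jury results.

#' Tidy a jury result
#'
#' @param x A [jury_assess()] result.
#' @param ... Unused.
#' @return The per-model score tibble (`model`, component jury scores,
#'   `combined_linear`, `rank_score`, ranks).
#' @method tidy jury_result
#' @export
tidy.jury_result <- function(x, ...) x$scores

#' One-row summary of a jury result
#'
#' @param x A [jury_assess()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n_models`, `best_model` (by rank score),
#'   `best_rank_score`, `mean_combined`, `sd_combined`.
#' @method glance jury_result
#' @export
glance.jury_result <- function(x, ...) {
  sc <- x$scores
  best <- sc[which.max(sc$rank_score), ]
  tibble(
    n_models = nrow(sc),
    best_model = best$model,
    best_rank_score = best$rank_score,
    mean_combined = mean(sc$combined_linear),
    sd_combined = stats::sd(sc$combined_linear)
  )
}

#' Tidy a single-model result
#'
#' @param x A [score_single_model()] result.
#' @param ... Unused.
#' @return The one-row score tibble.
#' @method tidy single_model_result
#' @export
tidy.single_model_result <- function(x, ...) x$scores

#' Plot the per-model jury scores
#'
#' Component jury scores and the combined linear score, one point per
#' model, ordered by the rank-variant ranking.
#'
#' @param object A [jury_assess()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot jury_result
#' @export
autoplot.jury_result <- function(object, ...) {
  sc <- rank_models(object, "modfolddockr")
  long <- tidyr::pivot_longer(
    sc[c("model", "dockq_jury", "qs_jury", "lddt_jury", "combined_linear")],
    -"model", names_to = "component", values_to = "score")
  long$model <- factor(long$model, levels = rev(sc$model))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score, y = .data$model,
                                     colour = .data$component)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "jury score", y = NULL, colour = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot per-residue local quality profiles
#'
#' Local consensus score along the sequence, one panel per chain, one line
#' per model; interface residues are marked.
#'
#' @param jury A [jury_assess()] result.
#' @param models Optional subset of model names.
#' @return A ggplot object.
#' @export
plot_local_quality <- function(jury, models = NULL) {
  loc <- jury$local
  if (!is.null(models)) loc <- loc[loc$model %in% models, ]
  ggplot2::ggplot(loc, ggplot2::aes(x = .data$res_index, y = .data$score,
                                    colour = .data$model)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(data = loc[loc$interface, ], size = 0.8) +
    ggplot2::facet_wrap(~chain, ncol = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "residue", y = "local consensus score",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
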