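# ggplot2 displays: the score-distribution bar chart (one bar per compound,
# ordered by ddE, coloured by Ames call) and the cutoff-sweep profile.

#' Plot the ddE distribution by Ames call
#'
#' One bar per compound, ordered by ddE, mutagens in red and nonmutagens in
#' green — the standard at-a-glance view of how well nitrenium stability
#' separates the two classes.
#'
#' @param data Data frame with a ddE column and a label column (e.g.
#'   [reference_set()] joined with predictions, or [synthetic_scores()]).
#' @param ddE_col,label_col Column names.
#' @return A ggplot object.
#' @export
plot_ddE_distribution <- function(data, ddE_col = "ddE", label_col = "ames") {
  stopifnot(ddE_col %in% names(data), label_col %in% names(data))
  d <- data[!is.na(data[[ddE_col]]), , drop = FALSE]
  d$.rank <- rank(d[[ddE_col]], ties.method = "first")
  d$.label <- .norm_label(d[[label_col]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$.rank,
                                  y = .data[[ddE_col]],
                                  fill = .data$.label)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_fill_manual(
      values = c(mutagen = "#c0392b", nonmutagen = "#27ae60"),
      name = "Ames") +
    ggplot2::labs(x = "compounds ordered by ΔΔE",
                  y = "ΔΔE (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' @describeIn cutoff_sweep Plot accuracy, sensitivity, specificity and MCC
#'   against the cutoff; the best cutoff is marked.
#' @param object A `nitrenium_sweep`.
#' @param ... Ignored.
#' @export
autoplot.nitrenium_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object)[, c("cutoff", "accuracy", "sensitivity", "specificity")],
    -"cutoff", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best_cutoff(object), linetype = 2) +
    ggplot2::labs(x = "cutoff (kcal/mol)", y = "percent") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
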