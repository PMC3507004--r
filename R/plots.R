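#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot gene signatures of a fastICA decomposition
#'
#' Strip plot of every gene's weight on each independent component; module
#' genes show up as extreme outliers on "their" component while background
#' genes concentrate near zero.
#'
#' @param object an `ica_decomposition`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ica_decomposition <- function(object, ...) {
  tidy(object, matrix = "S") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$component, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.25, height = 0, alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = "independent component", y = "gene signature weight",
                  title = sprintf("Gene signature matrix S (k = %d)",
                                  object$k)) +
    ggplot2::theme_minimal()
}

#' Plot a guide-gene screen
#'
#' Candidate-by-guide heatmap of correlation coefficients for the top
#' candidates, with passing links outlined.
#'
#' @param object a `screen_result`.
#' @param top number of top candidates to show (default 30).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.screen_result <- function(object, top = 30L, ...) {
  threshold <- attr(object, "threshold")
  shown <- utils::head(object$gene_id, top)
  links <- tidy(object) |>
    dplyr::filter(.data$gene_id %in% shown) |>
    dplyr::mutate(gene_id = factor(.data$gene_id, levels = rev(shown)))
  ggplot2::ggplot(links, ggplot2::aes(x = .data$guide, y = .data$gene_id,
                                      fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(links, .data$passes_link),
                       fill = NA, colour = "black", linewidth = 0.4) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "guide gene", y = "candidate",
                  title = sprintf("Guide-gene screen (r > %g)", threshold)) +
    ggplot2::theme_minimal()
}

#' Plot recovery across an IC-number sweep
#'
#' ARI and per-module Jaccard against the number of independent components.
#'
#' @param object an `ic_sweep`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ic_sweep <- function(object, ...) {
  per_mod <- tidy(object)
  summary <- glance(object)
  ggplot2::ggplot(per_mod, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$jaccard,
                                    colour = .data$module)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$jaccard,
                                     colour = .data$module)) +
    ggplot2::geom_line(data = summary, ggplot2::aes(y = .data$ari),
                       linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = object$k_values) +
    ggplot2::labs(y = "module Jaccard (solid) / ARI (dashed)",
                  x = "number of independent components k",
                  title = "Module recovery vs IC number") +
    ggplot2::theme_minimal()
}
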