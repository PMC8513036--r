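#' Fold-change overview of group-level glycan changes
#'
#' Bar chart of melanoma/control fold changes per feature with per-class
#' RSD whiskers, the group-level view of up-regulated fucosylated and
#' down-regulated nonfucosylated species.
#'
#' @param summary A [group_summary()] tibble.
#' @param top_n Show only the `top_n` features with the largest absolute
#'   log2 fold change (default 25).
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summary, top_n = 25) {
  df <- summary |>
    dplyr::filter(is.finite(.data$fold_change), .data$fold_change > 0) |>
    dplyr::arrange(dplyr::desc(abs(log2(.data$fold_change)))) |>
    utils::head(top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$fold_change),
    y = .data$fold_change)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$fold_change > 1)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "#2166ac"),
                               labels = c(`TRUE` = "up in melanoma",
                                          `FALSE` = "down in melanoma"),
                               name = NULL) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fold change (melanoma / control)") +
    ggplot2::theme_minimal()
}

#' Discriminant projection plot
#'
#' One-dimensional scatter of the projected discriminant scores by
#' class, with the decision threshold. An optional vertical jitter axis
#' is purely for display (it has zero effect on classification) and is
#' labeled as such.
#'
#' @param x An `agp_lda` model.
#' @param features Feature matrix to project (e.g. the training data).
#' @param jitter_axis Add a non-inferential vertical jitter axis for
#'   readability (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agp_lda <- function(x, features, jitter_axis = TRUE, ...) {
  proj <- classify(x, features)
  proj$class <- features$class
  proj$misclassified <- proj$class != proj$predicted
  set_y <- if (jitter_axis) stats::runif(nrow(proj), -1, 1) else 0
  proj$display_y <- set_y
  ggplot2::ggplot(proj, ggplot2::aes(x = .data$score, y = .data$display_y,
                                     colour = .data$class)) +
    ggplot2::geom_vline(xintercept = x$threshold, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$misclassified), size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                name = "misclassified") +
    ggplot2::labs(x = "discriminant score", y = "display jitter (non-inferential)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Pooled cross-validation score distribution
#'
#' @param x An `agp_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agp_cv <- function(x, ...) {
  ggplot2::ggplot(x$predictions,
                  ggplot2::aes(x = .data$score, fill = .data$truth)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "held-out discriminant score", y = "count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
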