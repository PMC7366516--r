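# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tile view of a binary character matrix
#'
#' @param object A `char_matrix`.
#' @param ... Unused.
#' @return A ggplot: taxa by characters, cells coloured by state.
#' @export
autoplot.char_matrix <- function(object, ...) {
  df <- tidy(object)
  df$taxon <- factor(df$taxon, levels = rev(object$taxa))
  df$character <- factor(df$character, levels = colnames(object$states))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$character, y = .data$taxon,
    fill = .data$state)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(
      values = c(`0` = "grey95", `1` = "grey25", `?` = "white"),
      name = "state"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
      vjust = 0.5, size = 7))
}

#' Per-character fit of a parsimony search
#'
#' Observed versus minimum steps per character; characters needing extra
#' steps are the homoplastic ones.
#'
#' @param object A `parsimony_search`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.parsimony_search <- function(object, ...) {
  df <- tidy(object)
  df$id <- factor(df$id, levels = df$id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = 0, ymax = .data$observed_steps),
      colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed_steps,
      colour = .data$observed_steps > .data$min_steps), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey25", `TRUE` = "firebrick"),
      labels = c(`FALSE` = "clean", `TRUE` = "homoplastic"), name = NULL
    ) +
    ggplot2::labs(x = NULL, y = "observed steps") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
      vjust = 0.5, size = 7))
}

#' Bootstrap clade supports
#'
#' @param object A `parsimony_bootstrap`.
#' @param min_support Hide clades below this percentage (default 5).
#' @param ... Unused.
#' @return A ggplot: horizontal bars of support per clade.
#' @export
autoplot.parsimony_bootstrap <- function(object, min_support = 5, ...) {
  df <- object$supports[object$supports$support >= min_support, , drop = FALSE]
  df$clade <- factor(df$clade, levels = rev(df$clade))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$support, y = .data$clade)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_vline(xintercept = 50, linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = "bootstrap support (%)", y = NULL) +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}
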