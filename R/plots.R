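# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a presence/absence matrix
#'
#' Genes-by-species tile plot of detection calls (the classic tick/box
#' figure).
#'
#' @param object a [presence_matrix()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.presence_matrix <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(-"gene", names_to = "species",
                        values_to = "present") |>
    mutate(gene = factor(.data$gene, levels = rev(object$gene)),
           call = ifelse(.data$present == 1, "detected", "not detected"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$species, y = .data$gene,
                                     fill = .data$call)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(detected = "#2e7d32",
                                          `not detected` = "grey15")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a root-to-tip rate table
#'
#' Per-gene root-to-tip substitution distances, coloured by group, with
#' genes on the x-axis in their supplied order.
#'
#' @param object a [rate_table()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.rate_table <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(gene = factor(.data$gene, levels = unique(.data$gene)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$root_to_tip,
                                   colour = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.15,
                                                            height = 0),
                        alpha = 0.8) +
    ggplot2::labs(x = NULL, y = "root-to-tip distance (subs/site)",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Plot the block structure of a disruption report
#'
#' Reference coordinates on the x-axis; one horizontal segment per synteny
#' block, coloured by orientation, with salvaged and lost genes marked
#' below.
#'
#' @param object a `disruption_report`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.disruption_report <- function(object, ...) {
  blocks <- mutate(object$blocks, y = "blocks")
  fates <- object$fates |>
    filter(.data$fate != "retained_in_locus") |>
    mutate(y = .data$fate)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = blocks,
      ggplot2::aes(x = .data$ref_start - 0.45, xend = .data$ref_end + 0.45,
                   y = .data$y, yend = .data$y,
                   colour = .data$orientation),
      linewidth = 4
    ) +
    ggplot2::labs(x = "reference gene index", y = NULL, colour = NULL,
                  title = paste("locus structure:", object$species)) +
    ggplot2::theme_minimal()
  if (nrow(fates) > 0) {
    p <- p + ggplot2::geom_point(
      data = fates,
      ggplot2::aes(x = .data$ref_index, y = .data$y, shape = .data$fate),
      size = 2
    )
  }
  p
}
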