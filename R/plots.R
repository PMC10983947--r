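#' Plot a binned Tajima's D scan
#'
#' @param object A `tajima_scan` tibble (optionally with a `flag`
#'   column).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tajima_scan <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$bin_start + df$bin_end) / 2
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$D)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "position (bp)", y = "Tajima's D")
  if ("flag" %in% names(df)) {
    p <- p + ggplot2::geom_point(
      data = df[!is.na(df$flag) & df$flag != "none", ],
      ggplot2::aes(colour = .data$flag), size = 2) +
      ggplot2::labs(colour = "percentile flag")
  }
  p + ggplot2::theme_minimal()
}

#' Heatmap of a motif usage matrix
#'
#' @param object A [usage_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.usage_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$motif_id, y = .data$haplotype,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = attr(object, "mode")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Stacked-letter frequency plot of a motif PFM
#'
#' A simple text-based logo: residues stacked per motif position with
#' heights proportional to their frequencies.
#'
#' @param object A [position_frequency_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_pfm <- function(object, ...) {
  df <- tidy(object) |>
    filter(.data$freq > 0) |>
    arrange(.data$position, .data$freq) |>
    group_by(.data$position) |>
    mutate(ymax = cumsum(.data$freq), y = .data$ymax - .data$freq / 2) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$y,
                                   label = .data$residue,
                                   size = .data$freq)) +
    ggplot2::geom_text(ggplot2::aes(colour = .data$residue %in%
                                      c("S", "T")),
                       show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("TRUE" = "firebrick",
                                            "FALSE" = "grey30")) +
    ggplot2::scale_size(range = c(1.5, 8)) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(object$pfm))) +
    ggplot2::labs(x = "motif position", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot Gabriel haplotype blocks along the sequence
#'
#' @param blocks A [gabriel_blocks()] tibble.
#' @return A ggplot object.
#' @export
plot_blocks <- function(blocks) {
  df <- as_tibble(blocks)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_pos,
                                    xmax = .data$end_pos,
                                    ymin = 0, ymax = 1),
                       fill = "steelblue", alpha = 0.5) +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
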