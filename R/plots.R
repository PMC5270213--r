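#' Plot an EC frequency spectrum
#'
#' Bar chart of normalized frequencies per grouping key.
#'
#' @param object an `ec_freq` table.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ec_freq <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$key, y = .data$freq)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = paste0("EC ", attr(object, "level")),
      y = "normalized frequency (%)",
      title = paste0(
        "EC ", attr(object, "level"), " spectrum (",
        toupper(attr(object, "role") %||% ""), " side)"
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot overrepresentation ratios against SM frequency
#'
#' Scatter of the overrepresentation ratio versus the key's SM frequency on
#' log scales; keys above the flagging threshold are highlighted and
#' labelled, the pattern used to spot rare but strongly SM-biased reaction
#' chemistries.
#'
#' @param object an `overrep_tbl`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.overrep_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data$ratio), .data$ratio > 0, .data$f_sm > 0)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$f_sm, y = .data$ratio,
    colour = .data$flagged
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      yintercept = attr(object, "flag_threshold"),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_text(
      data = dplyr::filter(df, .data$flagged),
      ggplot2::aes(label = .data$key),
      vjust = -0.6, size = 3, show.legend = FALSE
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::labs(
      x = "f_SM (%)", y = "overrepresentation f_SM / f_PM",
      colour = "flagged"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a functional-change graph
#'
#' Circular node layout with directed edges; edge width encodes the number
#' of function-changing homolog hits and colour the mean E-value bin. Node
#' labels carry the rate of functional conservation.
#'
#' @param object a `change_graph`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.change_graph <- function(object, ...) {
  nodes <- object$nodes
  n <- nrow(nodes)
  theta <- if (n > 0) seq(0, 2 * pi, length.out = n + 1)[seq_len(n)] else numeric()
  layout <- tibble::tibble(
    key = nodes$key, x = cos(theta), y = sin(theta),
    fc = nodes$fc, present_in_pm = nodes$present_in_pm
  )
  p <- ggplot2::ggplot()
  if (nrow(object$edges) > 0) {
    seg <- object$edges |>
      dplyr::left_join(layout[c("key", "x", "y")], by = c(from = "key")) |>
      dplyr::rename(x0 = "x", y0 = "y") |>
      dplyr::left_join(layout[c("key", "x", "y")], by = c(to = "key"))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y,
        linewidth = .data$weight, colour = .data$bin
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.18, "cm")),
      alpha = 0.8
    )
  }
  lab <- ifelse(is.na(layout$fc), paste0(layout$key, " (-)"),
    sprintf("%s\nfc=%.2f", layout$key, layout$fc)
  )
  p +
    ggplot2::geom_point(
      data = layout, ggplot2::aes(x = .data$x, y = .data$y),
      size = 3
    ) +
    ggplot2::geom_text(
      data = layout,
      ggplot2::aes(x = .data$x * 1.15, y = .data$y * 1.15),
      label = lab, size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 2.5)) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::labs(
      title = paste0("Functional changes PM → SM (", object$level, " level)"),
      colour = "mean E-value bin", linewidth = "hits"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
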