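# ggplot2 visualisations for profiles and digestions.

#' Plot an activity profile
#'
#' Bar chart of one profiling statistic per protease, faceted by activity
#' class. Enzymes are ordered by the statistic within the plot.
#'
#' @param object An `activity_profile` tibble.
#' @param statistic Column to plot: `"A_E"` (default), `"A"`, `"W"`,
#'   `"B"`, `"V"` or `"dh_t"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.activity_profile <- function(object,
                                      statistic = c("A_E", "A", "W", "B",
                                                    "V", "dh_t"), ...) {
  statistic <- match.arg(statistic)
  d <- object[object$calculable & !is.na(object[[statistic]]), ]
  if (nrow(d) == 0) rlang::abort("nothing to plot (all values undefined).")
  d$enzyme <- stats::reorder(d$enzyme, d[[statistic]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[statistic]],
                                  y = .data$enzyme)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$activity), scales = "free_x") +
    ggplot2::labs(
      x = switch(statistic,
                 A = "A (occurrence frequency)",
                 A_E = expression(A[E] ~ "(release frequency)"),
                 W = "W (relative release)",
                 B = expression(B ~ "(" * mu * M^-1 * ")"),
                 V = "V (released share of potency)",
                 dh_t = expression(DH[t] ~ "(%)")),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.activity_profile
#' @param x An `activity_profile` tibble.
#' @param y Ignored.
#' @export
plot.activity_profile <- function(x, y, ...) print(autoplot(x, ...))

#' Plot a digestion as a fragment map
#'
#' Fragments drawn as horizontal segments along the chain with cut sites
#' marked, a quick visual check of where a protease opens the chain.
#'
#' @param object A `digestion` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.digestion <- function(object, ...) {
  frags <- object$fragments
  frags$index <- seq_len(nrow(frags))
  p <- ggplot2::ggplot(frags) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$index, yend = .data$index),
      linewidth = 2, colour = "steelblue", lineend = "butt") +
    ggplot2::labs(
      title = paste0(object$protein_id, " × ", object$enzyme,
                     "  (DH_t = ",
                     sprintf("%.2f%%", theoretical_dh(object)), ")"),
      x = "residue position", y = "fragment"
    ) +
    ggplot2::theme_minimal()
  if (length(object$cut_sites)) {
    cuts <- tibble::tibble(site = object$cut_sites + 0.5)
    p <- p + ggplot2::geom_point(
      data = cuts, ggplot2::aes(x = .data$site, y = 0),
      shape = 17, colour = "firebrick")
  }
  p
}

#' @rdname autoplot.digestion
#' @param x A `digestion` object.
#' @param y Ignored.
#' @export
plot.digestion <- function(x, y, ...) print(autoplot(x, ...))
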