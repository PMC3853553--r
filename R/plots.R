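# ggplot2 displays for the main result types.

#' Plot an NMDS ordination
#'
#' @param object `trnl_nmds` object.
#' @param groups optional grouping vector (named by sample id or in point
#'   order) mapped to color and shape.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot trnl_nmds
#' @export
autoplot.trnl_nmds <- function(object, groups = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2))
  if (!is.null(groups)) {
    if (!is.null(names(groups))) groups <- groups[df$sample_id]
    df$group <- as.character(groups)
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$NMDS1, y = .data$NMDS2,
      color = .data$group, shape = .data$group
    ))
  }
  p +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      subtitle = sprintf("stress-1 = %.3f", object$stress),
      color = NULL, shape = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-family discrimination rates
#'
#' @param object `trnl_discrimination` object.
#' @param ... unused.
#' @return a ggplot object (horizontal bars of Rf per family).
#' @method autoplot trnl_discrimination
#' @export
autoplot.trnl_discrimination <- function(object, ...) {
  df <- tidy(object) |>
    filter(.data$n_species > 1) |>
    arrange(.data$Rf_percent)
  df$family <- factor(df$family, levels = df$family)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Rf_percent, y = .data$family)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = "within-family species discrimination Rf (%)", y = NULL,
      subtitle = sprintf("Rs = %d%%, Rg = %d%%", object$Rs, object$Rg)
    ) +
    ggplot2::theme_minimal()
}

#' Stacked monthly diet composition plot
#'
#' @param monthly tibble from [monthly_relative_frequency()].
#' @return a ggplot object (stacked bars per month).
#' @export
plot_monthly_diet <- function(monthly) {
  monthly$month <- factor(monthly$month,
    levels = c(9:12, 1:8), labels = month.abb[c(9:12, 1:8)]
  )[drop = TRUE]
  ggplot2::ggplot(monthly, ggplot2::aes(
    x = .data$month, y = .data$rel_freq, fill = .data$label
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative frequency of presence", fill = NULL) +
    ggplot2::theme_minimal()
}
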