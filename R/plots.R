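#' Plot a distance time series
#'
#' Line plot of the probe-phosphorus distance against time with the
#' productive-position cutoff drawn as a dashed reference line.
#'
#' @param object A [distance_series()] tibble.
#' @param cutoff Cutoff to draw, Angstrom (default 4.0; `NA` to omit).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distance_series <- function(object, cutoff = 4.0, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ps, y = .data$dist_A)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::labs(
      x = "time (ps)",
      y = "distance (Å)",
      title = attr(object, "label") %||% "interatomic distance"
    ) +
    ggplot2::theme_minimal()
  if (is.finite(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Plot adduct barrier scores
#'
#' Bar chart of the electrostatic barrier score per adduct, ordered from the
#' easiest to the hardest to reactivate.
#'
#' @param object A [score_reactivation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reactivation_score <- function(object, ...) {
  df <- tidy(object)
  df$adduct_id <- factor(df$adduct_id, levels = df$adduct_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$adduct_id, y = .data$delta_e_el)) +
    ggplot2::geom_col(fill = "steelblue4") +
    ggplot2::labs(
      x = NULL,
      y = expression(Delta * E[el] ~ "(kcal/mol)"),
      title = "Reactivation barrier by adduct (low = easy)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ranking table
#'
#' @param ranking Tibble from [rank_adducts()].
#' @return A ggplot object (dot chart of score by rank).
#' @export
plot_ranking <- function(ranking) {
  ranking$adduct_id <- factor(ranking$adduct_id, levels = ranking$adduct_id)
  ylab <- if (ranking$criterion[1] == "mm_distance") {
    "mean P–F distance (Å)"
  } else {
    "ΔE_el (kcal/mol)"
  }
  ggplot2::ggplot(ranking, ggplot2::aes(x = .data$adduct_id, y = .data$score)) +
    ggplot2::geom_point(size = 2.5, colour = "steelblue4") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$adduct_id, yend = min(.data$score)),
                          colour = "grey70") +
    ggplot2::labs(x = NULL, y = ylab,
                  title = "Adducts by increasing reactivation difficulty") +
    ggplot2::theme_minimal()
}
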