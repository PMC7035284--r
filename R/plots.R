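#' Plot a pen recording
#'
#' Draws the trace (y axis reversed: the capture device's y grows
#' downward), one path per stroke, optionally colored by line of text.
#'
#' @param object A [recording()].
#' @param color `"line"` (default) or `"stroke"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recording <- function(object, color = c("line", "stroke"), ...) {
  color <- match.arg(color)
  object <- segment_lines(object)
  df <- tibble::as_tibble(as.data.frame(object))
  col <- if (color == "line") "line_id" else "stroke_id"
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, group = stroke_id,
                                   colour = factor(.data[[col]]))) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = color, x = "x (device pts)",
                  y = "y (device pts)") +
    ggplot2::theme_minimal()
}

#' Plot a spectrum
#'
#' @param object A [new_spectrum()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(as.data.frame(object)),
                  ggplot2::aes(freq_hz, power)) +
    ggplot2::geom_col(width = min(diff(object$freq_hz)) * 0.9) +
    ggplot2::labs(x = "frequency (Hz)", y = "normalized power") +
    ggplot2::theme_minimal()
}

#' Plot one norm curve with its uncertainty band
#'
#' The fitted mean curve f_mean(age) with a ribbon of +/- one fitted SD
#' f_std(age), optionally overlaid with cohort points.
#'
#' @param norms A `norm_model`.
#' @param feature_id Catalogued feature id.
#' @param cohort Optional cohort table for the point overlay.
#' @return A ggplot faceted by gender.
#' @export
plot_norm_curve <- function(norms, feature_id, cohort = NULL) {
  fid <- feature_id
  grid <- dplyr::bind_rows(lapply(c("F", "M"), function(g) {
    row <- norm_curve(norms, fid, g)
    a <- seq(row$age_min, row$age_max, length.out = 80)
    tibble::tibble(gender = g, age = a,
                   mean = poly_eval(c(row$b0, row$b1, row$b2, row$b3), a),
                   sd = pmax(poly_eval(c(row$s0, row$s1, row$s2, row$s3), a),
                             row$std_floor))
  }))
  p <- ggplot2::ggplot(grid, ggplot2::aes(age, mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - sd, ymax = mean + sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~gender) +
    ggplot2::labs(x = "age (years)",
                  y = paste0("feature ", fid),
                  title = feature_catalogue()$name[
                    match(fid, feature_catalogue()$feature_id)]) +
    ggplot2::theme_minimal()
  if (!is.null(cohort)) {
    col <- paste0("f_", fid)
    pts <- tibble::tibble(age = cohort$age, gender = cohort$gender,
                          value = cohort[[col]], label = cohort$label)
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(age, value, colour = label),
      alpha = 0.5, size = 0.8)
  }
  p
}

#' Plot the per-axis category importance of a scale
#'
#' Bar chart of each category's share of the absolute loadings per
#' principal axis.
#'
#' @param object A `scale_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scale_model <- function(object, ...) {
  imp <- axis_importance(object)
  ggplot2::ggplot(imp$category_shares,
                  ggplot2::aes(factor(axis), share, fill = category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "principal axis", y = "share of |loadings|") +
    ggplot2::theme_minimal()
}

#' Plot a handwriting profile
#'
#' Bar chart of the global and per-category scores on the (0, 1] score
#' scale; the severity category is shown in the title.
#'
#' @param object A `handwriting_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.handwriting_profile <- function(object, ...) {
  df <- dplyr::filter(tidy(object), level != "feature")
  df$name <- factor(df$name,
                    levels = c("global", "static", "kinematic", "pressure",
                               "tilt"))
  ggplot2::ggplot(df, ggplot2::aes(name, score, fill = level)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score",
                  title = paste0(object$child_id, " - severity: ",
                                 object$severity)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
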