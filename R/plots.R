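#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

matrix_heatmap <- function(m, title, fill_lab) {
  df <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1 / 3)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = fill_lab) +
    ggplot2::theme_minimal()
}

#' Heatmap of a coactivation matrix
#' @param object A `ser_coactivation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ser_coactivation <- function(object, ...) {
  m <- object$values
  diag(m) <- 0
  matrix_heatmap(m, "Simulated coactivation", "coactivation")
}

#' Heatmap of a prediction matrix
#' @param object A `ser_prediction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ser_prediction <- function(object, ...) {
  matrix_heatmap(object$values, paste("Predicted coactivation:", object$predictor),
                 "predicted")
}

#' Predictive-power curves of an initial-condition sweep
#'
#' For an E-line sweep, correlation and mean signed difference against the
#' number of initially excited nodes, one curve per predictor; for a simplex
#' sweep, the two triangular heatmaps (correlation and mean difference) over
#' the simplex, one facet per predictor.
#'
#' @param object A `ser_sweep`.
#' @param metric `"pearson"` or `"msd"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ser_sweep <- function(object, metric = c("pearson", "msd"), ...) {
  metric <- match.arg(metric)
  df <- as.data.frame(object)
  if (identical(attr(object, "axis"), "simplex")) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$E, y = .data$S,
                                     fill = .data[[metric]])) +
      ggplot2::geom_tile() +
      ggplot2::facet_wrap(~predictor) +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = "initial P(E)", y = "initial P(S)", fill = metric) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$E_count, y = .data[[metric]],
                                     color = .data$predictor)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "nodes initially excited", y = metric,
                    color = "predictor") +
      ggplot2::theme_minimal()
  }
}
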