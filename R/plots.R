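# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a decoded (or simulated) track coloured by behavioural state
#'
#' @param states Tibble with `x_km`, `y_km` (or `lon`, `lat`) and `state`.
#' @return A ggplot object.
#' @export
plot_track <- function(states) {
  planar <- all(c("x_km", "y_km") %in% names(states))
  xv <- if (planar) "x_km" else "lon"
  yv <- if (planar) "y_km" else "lat"
  ggplot2::ggplot(states,
                  ggplot2::aes(.data[[xv]], .data[[yv]], colour = .data$state)) +
    ggplot2::geom_path(ggplot2::aes(group = 1), colour = "grey70",
                       linewidth = 0.2) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = if (planar) "east of colony (km)" else "longitude",
                  y = if (planar) "north of colony (km)" else "latitude",
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' Plot the per-minute data streams for one bird
#'
#' Faceted time series of the four HMM streams plus DBA, optionally
#' coloured by decoded state.
#'
#' @param minutes Minute-record tibble (see [minute_features()]).
#' @param decoded Optional [hmm_decode()] output to colour by state.
#' @return A ggplot object.
#' @export
plot_minutes <- function(minutes, decoded = NULL) {
  df <- minutes
  if (!is.null(decoded)) {
    df <- left_join(df, select(decoded, dplyr::any_of(c("bird", "minute", "state"))),
                    by = intersect(c("bird", "minute"), names(df)))
  }
  long <- df %>%
    tidyr::pivot_longer(dplyr::any_of(c("colony", "wingbeat_hz", "dive_frac",
                                        "step_m", "dba")),
                        names_to = "stream", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$minute, .data$value))
  p <- if (!is.null(decoded)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$state), size = 0.3)
  } else {
    p + ggplot2::geom_line(linewidth = 0.2)
  }
  p +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$stream), scales = "free_y") +
    ggplot2::labs(x = "minute of deployment", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an AICc model ranking
#'
#' @param object A `dee_model_ranking` from [aicc_rank()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dee_model_ranking
#' @export
autoplot.dee_model_ranking <- function(object, ...) {
  df <- mutate(object, design = factor(.data$design, levels = rev(.data$design)))
  ggplot2::ggplot(df, ggplot2::aes(.data$daicc, .data$design,
                                   fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 2, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = expression(Delta * "AICc"), y = NULL, fill = "kind") +
    ggplot2::theme_minimal()
}

#' Plot predicted vs observed mass-specific DEE for one fit
#'
#' @param object A [fit_dee_model()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dee_model_fit
#' @export
autoplot.dee_model_fit <- function(object, ...) {
  df <- tibble(observed = object$fitted + object$residuals,
               predicted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = object$design,
      subtitle = if (object$r_defined) sprintf("predictive r = %.2f", object$r)
      else "predictive r undefined",
      x = expression("predicted msDEE (kJ " * day^-1 * " " * g^-1 * ")"),
      y = expression("observed msDEE (kJ " * day^-1 * " " * g^-1 * ")")) +
    ggplot2::theme_minimal()
}
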