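#' Plot information-gain curves
#'
#' Draws KLD, BS and IG against prediction error (or surprise): the
#' Wundt-curve picture of the model.
#'
#' @param object A [gain_curve()].
#' @param x_axis `"delta"` or `"surprise"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gain_curve <- function(object, x_axis = c("delta", "surprise"),
                                ...) {
  x_axis <- match.arg(x_axis)
  long <- tidyr::pivot_longer(as_tibble(object), c("kld", "bs", "ig"),
                              names_to = "gain", values_to = "value")
  long$gain <- factor(toupper(long$gain), levels = c("KLD", "BS", "IG"))
  xlab <- if (x_axis == "delta") {
    expression(paste("prediction error ", delta))
  } else {
    "surprise (nats)"
  }
  ggplot2::ggplot(long, ggplot2::aes(.data[[x_axis]], .data$value,
                                     colour = .data$gain)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "information gain (nats)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a sweep quantity over the variance grid
#'
#' @param object A `gain_sweep` from [run_sweep()].
#' @param metric Column to map to fill (default `"max_ig"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gain_sweep <- function(object, metric = "max_ig", ...) {
  stopifnot(metric %in% names(object))
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$lik_var, .data$prior_var,
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = expression(paste("observation uncertainty ", sigma[l]^2)),
      y = expression(paste("prediction uncertainty ", sigma[p]^2)),
      fill = metric
    ) +
    ggplot2::theme_minimal()
}

#' Plot an inquiry-cycle trace
#'
#' Surprise per step, coloured by curiosity phase, with the optimal
#' surprises `s_kld`, `s_ig` and `s_bs` as reference lines: the settled
#' trace oscillates between `s_kld` and `s_bs` around the total-gain
#' optimum.
#'
#' @param object An `inquiry_cycle` from [simulate_cycle()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.inquiry_cycle <- function(object, ...) {
  g <- attr(object, "optima")
  refs <- tibble(
    level = c(g$s_kld, g$s_ig, g$s_bs),
    which = factor(c("s_kld", "s_ig", "s_bs"),
                   levels = c("s_kld", "s_ig", "s_bs"))
  )
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$step, .data$surprise)) +
    ggplot2::geom_hline(data = refs,
                        ggplot2::aes(yintercept = .data$level,
                                     linetype = .data$which),
                        colour = "grey50") +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phase), size = 2.5) +
    ggplot2::labs(x = "step", y = "surprise (nats)",
                  colour = "phase", linetype = NULL) +
    ggplot2::theme_minimal()
}
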