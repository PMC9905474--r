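# ggplot2 visualizations for the main result types.

#' @rdname km_estimate
#' @param object An `irs_km` object.
#' @export
autoplot.irs_km <- function(object, ...) {
  d <- tidy(object)
  # prepend the (0, 1) origin per group so curves start at 1
  origin <- d |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, survival = 1, conf_low = 1, conf_high = 1)
  dplyr::bind_rows(origin, d) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$survival,
                                 colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname select_threshold
#' @param object An `irs_threshold` object.
#' @export
autoplot.irs_threshold <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(x = .data$high_fraction, y = .data$hr)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$hr_target, linetype = "dashed") +
    ggplot2::labs(x = "Fraction called High", y = "Unadjusted HR (High vs Low)") +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold)) {
    at <- which.min(abs(object$curve$threshold - object$threshold))
    p <- p + ggplot2::geom_point(data = object$curve[at, ], size = 2)
  }
  p
}

#' @rdname fit_lasso_cox
#' @param object An `irs_fit` object.
#' @export
autoplot.irs_fit <- function(object, ...) {
  ggplot2::ggplot(object$lambda_path,
                  ggplot2::aes(x = log(.data$penalty), y = .data$cv_concordance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = log(object$chosen_penalty),
                        linetype = "dashed") +
    ggplot2::labs(x = "log penalty", y = "CV concordance index") +
    ggplot2::theme_minimal()
}

#' @rdname nn_match
#' @param object A `match_result` object.
#' @export
autoplot.match_result <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$caliper_width, linetype = "dashed") +
    ggplot2::labs(x = sprintf("Pair distance (%s scale)", object$scale),
                  y = "Pairs") +
    ggplot2::theme_minimal()
}
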