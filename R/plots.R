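#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_path labs theme_minimal annotate
#' @export
ggplot2::autoplot

#' @export
autoplot.psychometric_fit <- function(object, ...) {
  xs <- seq(min(object$data$x), max(object$data$x), length.out = 200)
  curve <- tibble::tibble(x = xs, y = predict(object, xs))
  ggplot(object$data, aes(x = .data$x, y = .data$frac_right)) +
    geom_point(aes(size = .data$n), alpha = 0.6, show.legend = FALSE) +
    geom_line(data = curve, aes(y = .data$y), colour = "steelblue") +
    labs(x = sprintf("%s evidence strength", object$feature),
         y = "fraction rightward choices") +
    theme_minimal()
}

#' @export
autoplot.behavioral_kernel_fit <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$time, y = .data$weight,
                           colour = .data$feature)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    labs(x = "time in trial (s)", y = "kernel weight",
         title = sprintf("%s context", object$context)) +
    theme_minimal()
}

#' @export
autoplot.differential_kernel <- function(object, ...) {
  d <- tibble::tibble(time = object$times, value = object$values)
  ggplot(d, aes(x = .data$time, y = .data$value)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_line() + geom_point() +
    labs(x = "time in trial (s)", y = "differential kernel",
         subtitle = sprintf("slope index = %.3g /s", object$slope_index$slope)) +
    theme_minimal()
}

#' @export
autoplot.differential_pulse_response <- function(object, ...) {
  d <- tibble::tibble(time = object$times, value = object$values)
  ggplot(d, aes(x = .data$time, y = .data$value)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    labs(x = "time after pulse (s)",
         y = "differential choice-axis projection",
         subtitle = sprintf("%s, slope index = %.3g /s",
                            object$source, object$slope_index$slope)) +
    theme_minimal()
}

#' Barycentric triangle plot of network decompositions
#'
#' @param summary A data frame with columns `x`, `y` (from
#'   [barycentric_point()] / [trained_population_map()]).
#' @param colour Optional column name to colour points by.
#' @return A ggplot object.
#' @export
plot_barycentric <- function(summary, colour = NULL) {
  tri <- tibble::tibble(
    x = c(0, 1, 0.5, 0),
    y = c(0, 0, sqrt(3) / 2, 0)
  )
  p <- ggplot(summary, aes(x = .data$x, y = .data$y)) +
    geom_path(data = tri, colour = "grey40") +
    annotate("text", x = -0.04, y = -0.04, label = "SVM") +
    annotate("text", x = 1.04, y = -0.04, label = "IIM") +
    annotate("text", x = 0.5, y = sqrt(3) / 2 + 0.05, label = "DIM") +
    theme_minimal() +
    labs(x = NULL, y = NULL)
  if (!is.null(colour)) {
    p + geom_point(aes(colour = .data[[colour]]), size = 2)
  } else {
    p + geom_point(size = 2, alpha = 0.7)
  }
}
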