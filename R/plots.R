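#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an estimated integration kernel
#'
#' Per-click regression weights with +/- 1 SE ribbons.
#'
#' @param object A `kernel_estimate`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kernel_estimate <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$click), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$click, y = .data$estimate)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$estimate - .data$std.error,
                   ymax = .data$estimate + .data$std.error),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "click position", y = expression(beta^click),
      title = "Integration kernel"
    )
}

#' Plot a psychometric curve
#'
#' Observed probability of choosing left against the net click difference,
#' point size proportional to trial count, with the fitted sigmoid overlaid
#' when available.
#'
#' @param object A `psychometric_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psychometric_curve <- function(object, ...) {
  p <- ggplot2::ggplot(
    object, ggplot2::aes(x = .data$delta_clicks, y = .data$p_left)
  ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(
      x = "#left - #right clicks", y = "P(choose left)",
      title = "Psychometric curve"
    )
  fit <- attr(object, "sigmoid_fit")
  if (!is.null(fit)) {
    xs <- seq(min(object$delta_clicks), max(object$delta_clicks),
              length.out = 200)
    line <- tibble::tibble(
      delta_clicks = xs,
      p_left = stats::plogis(fit$slope * (xs - fit$midpoint))
    )
    p <- p + ggplot2::geom_line(data = line, linetype = "dotted")
  }
  p
}

#' Plot simulated divisive-normalization dynamics
#'
#' Time courses of the two excitatory pools, the inhibitory gain and their
#' difference for one trial.
#'
#' @param object A `divnorm_trajectory` from [simulate_dynamics()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.divnorm_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("R_left", "R_right", "G", "delta"),
    names_to = "unit", values_to = "activity"
  )
  long$unit <- factor(long$unit, levels = c("R_left", "R_right", "G", "delta"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$activity)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~unit, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Divisive-normalization dynamics")
}

#' Plot the cohort-mean integration kernel
#'
#' @param mean_kernel Tibble from [cohort_mean_kernel()].
#' @return A ggplot.
#' @export
plot_cohort_kernel <- function(mean_kernel) {
  ggplot2::ggplot(mean_kernel,
                  ggplot2::aes(x = .data$click, y = .data$mean_beta)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_beta - .data$sem,
                   ymax = .data$mean_beta + .data$sem),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "click position", y = expression(bar(beta)^click),
                  title = "Cohort-mean integration kernel")
}
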