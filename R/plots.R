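#' Plot a mass density profile
#'
#' @param object A [density_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$z, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = expression(rho ~ (amu ~ nm^-3))) +
    ggplot2::theme_minimal()
}

#' Plot a Gaussian fit over its histogram
#'
#' @param object A `gaussian_fit` from [fit_gaussian()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gaussian_fit <- function(object, ...) {
  h <- as_tibble(object$histogram)
  amp <- max(h$density)
  curve <- tibble(x = seq(min(h$x), max(h$x), length.out = 400))
  curve$density <- amp * exp(-(curve$x - object$x0)^2 / (2 * object$sigma^2))
  unit <- if (object$kind == "bond") "Å" else "deg"
  ggplot2::ggplot(h, ggplot2::aes(.data$x, .data$density)) +
    ggplot2::geom_col(width = attr(object$histogram, "bin_width"),
                      fill = "grey80") +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(x = paste0(object$kind, " (", unit, ")"), y = "density",
                  subtitle = sprintf("x0 = %.3f, sigma = %.4f%s", object$x0,
                                     object$sigma,
                                     if (object$multimodal) " (multimodal)" else "")) +
    ggplot2::theme_minimal()
}

#' Side view of a CG frame
#'
#' x-z scatter of bead positions coloured by bead type; a quick visual check
#' of generated or mapped configurations.
#'
#' @param object A [cg_frame()].
#' @param max_beads Subsample cap for large frames.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cg_frame <- function(object, max_beads = 20000, ...) {
  tb <- as_tibble(object)
  if (nrow(tb) > max_beads) tb <- dplyr::slice_sample(tb, n = max_beads)
  ggplot2::ggplot(tb, ggplot2::aes(.data$x, .data$z, colour = .data$bead)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "z (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a structure report
#'
#' Replicate means with error bars per metric.
#'
#' @param object A `structure_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.structure_report <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(.data$metric, .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
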