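#' Plot a potential of mean force profile
#'
#' Line plot of the PMF along the strand-separation coordinate, with a
#' bootstrap-error ribbon when errors are attached.
#'
#' @param object A `pmf_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pmf_profile
#' @export
autoplot.pmf_profile <- function(object, ...) {
  d <- tidy(object)
  d <- d[is.finite(d$pmf), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$xi, y = .data$pmf))
  if (!is.null(object$err)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$pmf - .data$err, ymax = .data$pmf + .data$err),
      fill = "steelblue", alpha = 0.3
    )
  }
  p +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "strand separation (Å)",
      y = "PMF (kcal/mol)",
      title = sprintf("Potential of mean force at %.0f K", object$temperature)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a van't Hoff fit
#'
#' Formation free energies against temperature with the fitted line
#' `ΔG°(T) = ΔH° − T ΔS°`.
#'
#' @param object A `vanthoff_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vanthoff_fit
#' @export
autoplot.vanthoff_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature, y = .data$delta_g))
  if ("delta_g_err" %in% names(d) && any(is.finite(d$delta_g_err))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$delta_g - .data$delta_g_err,
                   ymax = .data$delta_g + .data$delta_g_err),
      width = 1
    )
  }
  p +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$delta_h,
                         slope = -object$delta_s / 1000,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "temperature (K)", y = expression(Delta * G * degree ~ "(kcal/mol)"),
      title = sprintf(
        "ΔH° = %.1f kcal/mol, ΔS° = %.1f cal/(mol K), R² = %.3f",
        object$delta_h, object$delta_s, object$r_squared
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot adjacent-window histogram overlaps
#'
#' Overlap fraction of each adjacent window pair against the pair midpoint,
#' with the acceptance threshold drawn as a dashed line.
#'
#' @param overlap An [adjacent_overlap()] tibble.
#' @return A ggplot.
#' @export
plot_overlap <- function(overlap) {
  if (!all(c("center_lo", "center_hi", "overlap") %in% names(overlap))) {
    abort("`overlap` must come from adjacent_overlap().")
  }
  thr <- attr(overlap, "threshold") %||% 0.20
  d <- dplyr::mutate(overlap, mid = (.data$center_lo + .data$center_hi) / 2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$overlap)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$pass), size = 1) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue",
                                            `FALSE` = "firebrick"),
                                 guide = "none") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "pair midpoint (Å)", y = "histogram overlap") +
    ggplot2::theme_minimal()
}

#' Plot a model free-energy surface
#'
#' @param object A [model_pmf()].
#' @param xi_max Upper end of the plotted range, A.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot model_pmf
#' @export
autoplot.model_pmf <- function(object, xi_max = 48, ...) {
  xs <- seq(0, xi_max, length.out = 1000)
  d <- tibble(xi = xs, pmf = model_pmf_value(object, xs))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$xi, y = .data$pmf)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::coord_cartesian(ylim = c(min(d$pmf) - 1, 10)) +
    ggplot2::labs(x = "strand separation (Å)",
                  y = "model free energy (kcal/mol)") +
    ggplot2::theme_minimal()
}
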