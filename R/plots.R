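#' Plot an equilibrium binding isotherm
#'
#' Bound ligand against total ligand, optionally overlaying the exact
#' Langmuir curve implied by a fitted or generating parameter set.
#'
#' @param data An isotherm table (`As_total_uM`, `As_bound_uM`).
#' @param params Optional [binding_params()] whose exact equilibrium
#'   curve is drawn for comparison.
#' @return A ggplot object.
#' @export
plot_isotherm <- function(data, params = attr(data, "params")) {
  data <- require_columns(data, c("As_total_uM", "As_bound_uM"),
                          "isotherm table")
  p <- ggplot2::ggplot(data, ggplot2::aes(.data$As_total_uM, .data$As_bound_uM)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Total As(III) (µM)", y = "Bound As(III) (µM)") +
    ggplot2::theme_minimal()
  if (!is.null(params) && inherits(params, "binding_params")) {
    grid <- seq(min(data$As_total_uM), max(data$As_total_uM), length.out = 200)
    curve <- solve_single_equilibrium(grid, params$capacity_uM,
                                      params$K_A_per_uM)
    p <- p + ggplot2::geom_line(
      data = curve,
      ggplot2::aes(.data$M_total_uM, .data$M_bound_uM),
      colour = "steelblue"
    )
  }
  p
}

#' @describeIn scatchard_fit Scatchard plot with the fitted line drawn
#'   over the selected linear segment (solid) and extrapolated elsewhere
#'   (dashed); excluded points are hollow.
#' @param object A `scatchard_fit`.
#' @param ... Unused.
#' @method autoplot scatchard_fit
#' @export
autoplot.scatchard_fit <- function(object, ...) {
  pts <- object$points |>
    mutate(in_segment = row_number() %in% object$segment)
  ggplot2::ggplot(pts, ggplot2::aes(.data$M_free_uM, .data$y_uM)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$in_segment), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "in linear segment") +
    ggplot2::labs(
      x = "Free As(III) (µM)",
      y = expression("[M]"[f] / (mu / 10^7) ~ "(µM)"),
      title = object$label,
      subtitle = sprintf("%s   K_A = %.3g × 10⁶ M⁻¹, n = %.3g × 10⁷",
                         object$equation, object$K_A_e6_per_M, object$n_e7)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_pseudo_first_order Linearized kinetics plot (the
#'   regression actually fitted) for either rate law.
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  d <- object$fit$model
  names(d) <- c("y", "t_h")
  ylab <- if (object$model == "PFO") "ln(Qe - Qt)" else "t / Qt (h g/µg)"
  ggplot2::ggplot(d, ggplot2::aes(.data$t_h, .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "t (h)", y = ylab, title = sprintf("%s linearization", object$model),
      subtitle = sprintf("%s   R² = %.4f", object$equation, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_affinity_ratio Competition plot of `R_f/R_b` against
#'   `P_f/P_b` with the fitted ratio line.
#' @param object A `competitive_fit`.
#' @param ... Unused.
#' @method autoplot competitive_fit
#' @export
autoplot.competitive_fit <- function(object, ...) {
  pts <- object$points |> filter(.data$usable)
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$ratio, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = expression("[P]"[f] / "[P]"[b]),
      y = expression("[R]"[f] / "[R]"[b]),
      subtitle = sprintf("K_D1/K_D2 = %.4f   R² = %.4f",
                         object$ratio, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot retention under metal interference
#'
#' Bar chart of retention percentages per adsorbent and competing
#' metal, with the classification threshold drawn as a horizontal line.
#'
#' @param data Output of [retention()].
#' @return A ggplot object.
#' @export
plot_retention <- function(data) {
  data <- require_columns(data, c("adsorbent", "metal", "retention_pct",
                                  "threshold_pct"), "retention report",
                          numeric_cols = c("retention_pct", "threshold_pct"))
  ggplot2::ggplot(data, ggplot2::aes(.data$adsorbent, .data$retention_pct,
                                     fill = .data$metal)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = data$threshold_pct[[1]], colour = "red") +
    ggplot2::labs(x = NULL, y = "As(III) adsorption retained (%)") +
    ggplot2::theme_minimal()
}
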