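#' Fit protein loading capacity onto particles
#'
#' In the sub-saturation regime, bound protein grows linearly with
#' particle molarity; the slope (uM protein per uM particles, i.e.
#' mol/mol) is the maximum immobilization capacity in molecules per
#' particle. Saturated tail points are excluded by the same linear
#' segment selector used for Scatchard plots.
#'
#' @param data A loading table with columns `sphere_conc_uM`,
#'   `protein_bound_uM`.
#' @param min_len,r2_min Segment-selection controls (default run length
#'   3: loading designs are short).
#' @return A `loading_fit`: `capacity` (molecules per particle),
#'   `capacity_sd`, `intercept` (diagnostic, expected ~0), `r_squared`,
#'   segment and `lm`.
#' @export
#' @examples
#' d <- tibble::tibble(sphere_conc_uM = seq(0.5, 3.5, 0.5) * 1e-7,
#'                     protein_bound_uM = 2.733e7 * sphere_conc_uM)
#' fit_loading_capacity(d)
fit_loading_capacity <- function(data, min_len = 3L, r2_min = 0.99) {
  data <- require_columns(data, c("sphere_conc_uM", "protein_bound_uM"),
                          "loading table")
  if (nrow(data) < 3L) {
    abort("Loading fit needs at least 3 points.",
          class = "arsbind_insufficient_data")
  }
  seg <- select_linear_segment(data$sphere_conc_uM, data$protein_bound_uM,
                               min_len = min_len, r2_min = r2_min)
  d <- data[seg$indices, , drop = FALSE]
  fit <- lm(protein_bound_uM ~ sphere_conc_uM, data = d)
  slope <- unname(coef(fit)[2])
  sm <- suppressWarnings(summary(fit)) # exact fits are expected on clean data
  structure(
    list(
      capacity = slope,
      capacity_sd = sm$coefficients["sphere_conc_uM", "Std. Error"],
      intercept = unname(coef(fit)[1]),
      r_squared = sm$r.squared,
      segment = seg,
      n_points_used = length(seg$indices),
      n_points_total = nrow(data),
      fit = fit
    ),
    class = "loading_fit"
  )
}

#' @export
print.loading_fit <- function(x, ...) {
  cat("<loading_fit>\n")
  cat(sprintf("  capacity = %.4g +/- %.2g molecules/particle (R^2 = %.4f)\n",
              x$capacity, x$capacity_sd, x$r_squared))
  cat(sprintf("  linear segment: %d of %d points; intercept %.3g uM\n",
              x$n_points_used, x$n_points_total, x$intercept))
  invisible(x)
}

#' Protein release fraction of a conjugate over time
#'
#' Conjugate stability is scored as the percentage of initially bound
#' protein released by a time horizon:
#' `100 * (bound(0) - bound(t)) / bound(0)`. Bound amounts at the
#' horizon are interpolated linearly between measured times when needed.
#' A covalently immobilized preparation is expected to stay below a few
#' percent over days.
#'
#' @param data A stability series with columns `t_h` and `bound`.
#' @param horizon_h Time at which release is evaluated (default 60 h).
#' @param threshold_pct Pass threshold on released percentage (default
#'   4).
#' @return A one-row tibble: `horizon_h`, `bound_initial`,
#'   `bound_at_horizon`, `release_pct`, `passes`.
#' @export
#' @examples
#' d <- tibble::tibble(t_h = c(0, 30, 60), bound = c(100, 98.5, 97))
#' release_fraction(d)
release_fraction <- function(data, horizon_h = 60, threshold_pct = 4) {
  data <- require_columns(data, c("t_h", "bound"), "stability series")
  if (!any(data$t_h == 0)) {
    abort("Stability series must contain a t = 0 measurement.",
          class = "arsbind_invalid_argument")
  }
  b0 <- data$bound[data$t_h == 0][[1]]
  if (b0 <= 0) {
    abort("Bound amount at t = 0 must be positive.",
          class = "arsbind_invalid_argument")
  }
  if (horizon_h > max(data$t_h)) {
    abort(sprintf("Horizon %g h lies beyond the series (max %g h).",
                  horizon_h, max(data$t_h)),
          class = "arsbind_invalid_argument")
  }
  bt <- approx(data$t_h, data$bound, xout = horizon_h, ties = "ordered")$y
  release <- 100 * (b0 - bt) / b0
  if (release < 0) {
    warn(sprintf("Bound amount increased over time (release %.2f%%).", release))
  }
  tibble(
    horizon_h = horizon_h,
    bound_initial = b0,
    bound_at_horizon = bt,
    release_pct = release,
    passes = release <= threshold_pct
  )
}

#' Retention of As(III) adsorption under competing metals
#'
#' Selectivity metric: adsorption in the presence of a competing heavy
#' metal divided by the metal-free control, as a percentage. An
#' adsorbent-metal pair is classified as retained when retention is at
#' or above the threshold (inclusive at exactly 95%, so the boundary is
#' deterministic). The metric is a ratio, so any consistent adsorption
#' unit (ug/g, % removal, uM bound) cancels.
#'
#' @param data An interference table with columns `adsorbent`, `metal`,
#'   `Q_with`, `Q_without`.
#' @param threshold_pct Retention threshold, percent (default 95).
#' @return The input with `retention_pct`, `retained` and
#'   `threshold_pct` columns appended.
#' @export
#' @examples
#' d <- tibble::tibble(adsorbent = "S", metal = "Cu2+",
#'                     Q_with = 78.7, Q_without = 100)
#' retention(d)
retention <- function(data, threshold_pct = 95) {
  data <- require_columns(data, c("adsorbent", "metal", "Q_with", "Q_without"),
                          "interference table",
                          numeric_cols = c("Q_with", "Q_without"))
  if (any(data$Q_without <= 0)) {
    abort("Metal-free control adsorption must be positive for every row.",
          class = "arsbind_invalid_argument")
  }
  data |>
    mutate(
      retention_pct = 100 * .data$Q_with / .data$Q_without,
      threshold_pct = threshold_pct,
      retained = .data$retention_pct >= threshold_pct
    )
}
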