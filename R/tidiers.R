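#' Tidy a Scatchard fit
#'
#' Coefficient-level summary in broom layout: the regression slope and
#' intercept with their standard errors, plus the derived binding
#' parameters (association constant in 1e6 M^-1, site number in 1e7
#' sites/particle) with delta-method standard errors.
#'
#' @param x A `scatchard_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy scatchard_fit
#' @export
tidy.scatchard_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "slope", "K_A_e6_per_M", "n_e7"),
    estimate = c(x$intercept, x$slope, x$K_A_e6_per_M, x$n_e7),
    std.error = c(s["(Intercept)", "Std. Error"], s["M_free_uM", "Std. Error"],
                  x$K_A_sd, x$n_e7_sd)
  )
}

#' Glance at a Scatchard fit
#'
#' @param x A `scatchard_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `adsorbent`, `equation`, `K_A_e6_per_M`,
#'   `K_D_uM`, `n_e7`, `r.squared`, `n_points`.
#' @method glance scatchard_fit
#' @export
glance.scatchard_fit <- function(x, ...) {
  tibble(
    adsorbent = x$label,
    equation = x$equation,
    K_A_e6_per_M = x$K_A_e6_per_M,
    K_D_uM = x$K_D_uM,
    n_e7 = x$n_e7,
    r.squared = x$r_squared,
    n_points = x$n_points_used
  )
}

#' Tidy a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A tibble of regression and derived parameters with standard
#'   errors where defined.
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "slope", "k", "Q_e"),
    estimate = c(x$intercept, x$slope, x$k, x$Q_e_fitted),
    std.error = c(s[1, "Std. Error"], s[2, "Std. Error"], NA_real_, NA_real_)
  )
}

#' Glance at a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `equation`, `k`, `Q_e`,
#'   `r.squared`, `n_used`, `n_dropped` — the layout of a classical
#'   adsorption-kinetics table row.
#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(
    model = x$model,
    equation = x$equation,
    k = x$k,
    Q_e = x$Q_e_fitted,
    r.squared = x$r_squared,
    n_used = x$n_used,
    n_dropped = x$n_dropped
  )
}

#' Tidy a competitive fit
#'
#' @param x A `competitive_fit`.
#' @param ... Unused.
#' @return A tibble with the fitted K_D ratio and diagnostic intercept.
#' @method tidy competitive_fit
#' @export
tidy.competitive_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "KD1_over_KD2"),
    estimate = c(x$intercept, x$ratio),
    std.error = c(s["(Intercept)", "Std. Error"], x$ratio_sd)
  )
}

#' Glance at a competitive fit
#'
#' @param x A `competitive_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `ratio`, `intercept`, `r.squared`,
#'   `n_points_used`, plus the derived free affinity and deviation when
#'   a reference was supplied.
#' @method glance competitive_fit
#' @export
glance.competitive_fit <- function(x, ...) {
  out <- tibble(
    ratio = x$ratio,
    intercept = x$intercept,
    r.squared = x$r_squared,
    n_points_used = x$n_points_used
  )
  if (!is.null(x$free_affinity)) {
    out$K_A_free_e6_per_M <- x$free_affinity$K_A_free_e6_per_M
    out$deviation_pct <- x$free_affinity$deviation_pct
  }
  out
}

#' Tidy a loading fit
#'
#' @param x A `loading_fit`.
#' @param ... Unused.
#' @return A tibble with the capacity (molecules per particle) and
#'   intercept.
#' @method tidy loading_fit
#' @export
tidy.loading_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "capacity"),
    estimate = c(x$intercept, x$capacity),
    std.error = c(s["(Intercept)", "Std. Error"], x$capacity_sd)
  )
}

#' Glance at a loading fit
#'
#' @param x A `loading_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `capacity`, `capacity_sd`, `r.squared`,
#'   `n_points_used`, `n_points_total`.
#' @method glance loading_fit
#' @export
glance.loading_fit <- function(x, ...) {
  tibble(
    capacity = x$capacity,
    capacity_sd = x$capacity_sd,
    r.squared = x$r_squared,
    n_points_used = x$n_points_used,
    n_points_total = x$n_points_total
  )
}
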