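#' Transform an isotherm into Scatchard coordinates
#'
#' For a 1:1 system on independent, identical sites the equilibrium
#' isotherm obeys
#' \deqn{[M]_f/\mu = K_D/n + [M]_f/n}
#' where the occupancy \eqn{\mu = [M]_b / [S]_t} counts bound ligand per
#' particle. Because per-particle site numbers here are of order 1e7, the
#' occupancy is carried in units of 1e7 (`mu_e7`), so that the fitted
#' slope is \eqn{10^7/n} and site numbers read directly in units of 1e7
#' sites per particle. The ordinate is `y_uM = M_free / mu_e7`.
#'
#' Points with zero bound ligand have no defined occupancy ratio and are
#' skipped with a warning.
#'
#' @param data An isotherm table with columns `As_free_uM`, `As_bound_uM`
#'   (and optionally `As_total_uM`, `label`).
#' @param suspension An [adsorbent_suspension()] row giving the total
#'   particle molarity; taken from the data's `"params"` attribute when
#'   present and not supplied.
#' @return A tibble of Scatchard points: `M_free_uM`, `mu`, `mu_e7`,
#'   `y_uM`.
#' @export
#' @examples
#' s <- adsorbent_suspension(1.00, 1.657e11)
#' iso <- simulate_isotherm(binding_params(30, 2.8e7, s), seq(0.5, 5, 0.5))
#' scatchard_transform(iso)
scatchard_transform <- function(data, suspension = NULL) {
  data <- require_columns(data, c("As_free_uM", "As_bound_uM"),
                          "isotherm table")
  if (is.null(suspension)) {
    p <- attr(data, "params")
    if (!is.null(p) && inherits(p, "binding_params")) suspension <- p$suspension
  }
  if (is.null(suspension)) {
    abort("Supply `suspension` (or a dataset carrying binding parameters).",
          class = "arsbind_invalid_argument")
  }
  St <- suspension$molar_conc_uM[[1]]
  check_number(St, "suspension molar_conc_uM", min = 0, allow_zero = FALSE)

  zero <- data$As_bound_uM <= 0
  if (all(zero)) {
    abort("All points have zero bound ligand; Scatchard transform undefined.",
          class = "arsbind_insufficient_data")
  }
  if (any(zero)) {
    warn(sprintf("Skipping %d zero-bound point(s) in Scatchard transform.",
                 sum(zero)))
  }
  d <- data[!zero, , drop = FALSE]
  mu <- d$As_bound_uM / St
  mu_e7 <- mu / 1e7
  tibble(
    M_free_uM = d$As_free_uM,
    mu = mu,
    mu_e7 = mu_e7,
    y_uM = d$As_free_uM / mu_e7
  )
}

#' Affinity and site number from Scatchard regression coefficients
#'
#' Converts a Scatchard line `y = slope * x + intercept` (x = free ligand
#' in uM, y = free ligand over occupancy-in-1e7-units) into binding
#' parameters: \eqn{K_A = slope/intercept} (uM^-1, numerically equal to
#' the value expressed in 1e6 M^-1), \eqn{K_D = 1/K_A}, and
#' \eqn{n = 10^7/slope} sites per particle (`n_e7 = 1/slope` in 1e7
#' units). This is the single code path used by [scatchard_fit()] and is
#' exported so published regression lines can be converted directly.
#'
#' @param slope Scatchard slope (dimensionless in the scaled convention).
#' @param intercept Scatchard intercept, uM; must be positive for a
#'   defined affinity.
#' @return A tibble with columns `slope`, `intercept`, `K_A_per_uM`,
#'   `K_A_e6_per_M`, `K_D_uM`, `n_sites`, `n_e7`.
#' @export
#' @examples
#' scatchard_params(0.3567, 0.0117)  # K_A 30.49e6 M^-1, n 2.80e7
scatchard_params <- function(slope, intercept) {
  check_number(slope, "slope", min = 0, allow_zero = FALSE)
  if (!is.numeric(intercept) || anyNA(intercept)) {
    abort("`intercept` must be numeric.", class = "arsbind_invalid_argument")
  }
  if (any(intercept <= 0)) {
    abort(
      sprintf("Non-positive Scatchard intercept (%s): affinity undefined (slope %s).",
              paste(format(intercept), collapse = ", "),
              paste(format(slope), collapse = ", ")),
      class = "arsbind_affinity_undefined"
    )
  }
  KA <- slope / intercept # uM^-1 == 1e6 M^-1 numerically
  tibble(
    slope = slope,
    intercept = intercept,
    K_A_per_uM = KA,
    K_A_e6_per_M = KA,
    K_D_uM = intercept / slope,
    n_sites = 1e7 / slope,
    n_e7 = 1 / slope
  )
}

#' Fit a Scatchard line and derive binding parameters
#'
#' Ordinary least squares of the Scatchard ordinate on free ligand over
#' the chosen segment, followed by [scatchard_params()] on the fitted
#' coefficients. Standard errors of \eqn{K_A = slope/intercept} and
#' \eqn{n = 10^7/slope} are propagated from the regression covariance by
#' the delta method.
#'
#' @param points Scatchard points from [scatchard_transform()].
#' @param segment A `linear_segment` (or integer index vector) selecting
#'   the points to fit; defaults to all points.
#' @param label Adsorbent label carried into reports.
#' @return A `scatchard_fit` object: `slope`, `intercept`, `r_squared`,
#'   `K_A_per_uM` (= `K_A_e6_per_M`), `K_D_uM`, `n_sites`, `n_e7`,
#'   delta-method `K_A_sd`/`n_e7_sd`, the `segment`, an `equation`
#'   string, and the underlying `lm`.
#' @export
scatchard_fit <- function(points, segment = NULL, label = "adsorbent") {
  points <- require_columns(points, c("M_free_uM", "y_uM"), "Scatchard points")
  idx <- if (is.null(segment)) {
    seq_len(nrow(points))
  } else if (inherits(segment, "linear_segment")) {
    segment$indices
  } else {
    as.integer(segment)
  }
  if (length(idx) < 3L) {
    abort("Scatchard fit needs a segment of at least 3 points.",
          class = "arsbind_insufficient_data")
  }
  d <- points[idx, , drop = FALSE]
  fit <- lm(y_uM ~ M_free_uM, data = d)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  r2 <- suppressWarnings(summary(fit))$r.squared # noiseless data fit exactly
  V <- suppressWarnings(vcov(fit)) # rows/cols: (Intercept), M_free_uM

  if (intercept <= 0) {
    abort(
      sprintf("Scatchard intercept %.4g <= 0: affinity undefined (slope %.4g, R^2 %.4f).",
              intercept, slope, r2),
      class = "arsbind_affinity_undefined"
    )
  }
  par <- scatchard_params(slope, intercept)

  # delta method: K_A = s/i -> grad (d/di, d/ds) = (-s/i^2, 1/i)
  grad_KA <- c(-slope / intercept^2, 1 / intercept)
  K_A_sd <- sqrt(drop(t(grad_KA) %*% V %*% grad_KA))
  # n_e7 = 1/s -> var = (1/s^2)^2 var(s)
  n_e7_sd <- sqrt(V[2, 2]) / slope^2

  structure(
    list(
      label = label,
      slope = slope, intercept = intercept, r_squared = r2,
      K_A_per_uM = par$K_A_per_uM, K_A_e6_per_M = par$K_A_e6_per_M,
      K_D_uM = par$K_D_uM, n_sites = par$n_sites, n_e7 = par$n_e7,
      K_A_sd = K_A_sd, n_e7_sd = n_e7_sd,
      segment = idx,
      equation = sprintf("y = %.4fx + %.4f", slope, intercept),
      n_points_used = length(idx),
      points = points,
      fit = fit
    ),
    class = "scatchard_fit"
  )
}

#' @export
print.scatchard_fit <- function(x, ...) {
  cat(sprintf("<scatchard_fit: %s>\n", x$label))
  cat(sprintf("  %s  (R^2 = %.4f, %d points)\n",
              x$equation, x$r_squared, x$n_points_used))
  cat(sprintf("  K_A = %.3f +/- %.3f x 1e6 M^-1   (K_D = %.4g uM)\n",
              x$K_A_e6_per_M, x$K_A_sd, x$K_D_uM))
  cat(sprintf("  n   = %.3f +/- %.3f x 1e7 sites/particle\n",
              x$n_e7, x$n_e7_sd))
  invisible(x)
}

#' Full Scatchard analysis of an equilibrium isotherm
#'
#' Composes the three analysis steps: transform the isotherm to
#' Scatchard coordinates, select the linear segment, and fit. Replicate
#' measurements at the same total-ligand level are averaged before the
#' transform.
#'
#' @param data An isotherm table (`As_total_uM`, `As_free_uM`,
#'   `As_bound_uM`, optional `label`).
#' @param suspension An [adsorbent_suspension()] row (or `NULL` to use
#'   the simulation parameters attached to `data`).
#' @param min_len,r2_min Segment-selection controls, see
#'   [select_linear_segment()].
#' @param average_replicates Average replicate rows sharing a total
#'   level before transforming (default `TRUE`).
#' @param label Adsorbent label; defaults to the table's `label` column.
#' @return A `scatchard_fit`.
#' @export
#' @examples
#' s <- adsorbent_suspension(1.00, 1.657e11)
#' iso <- simulate_isotherm(binding_params(30.49, 2.80e7, s), seq(0.5, 6, 0.5))
#' affinity_from_isotherm(iso)
affinity_from_isotherm <- function(data, suspension = NULL, min_len = 4L,
                                   r2_min = 0.99, average_replicates = TRUE,
                                   label = NULL) {
  data <- require_columns(data, c("As_total_uM", "As_free_uM", "As_bound_uM"),
                          "isotherm table")
  if (nrow(data) == 0L) {
    abort("Empty isotherm dataset.", class = "arsbind_insufficient_data")
  }
  if (is.null(label)) {
    label <- if ("label" %in% names(data)) as.character(data$label[[1]]) else "adsorbent"
  }
  attrs <- attr(data, "params")
  if (average_replicates && anyDuplicated(data$As_total_uM)) {
    data <- data |>
      group_by(.data$As_total_uM) |>
      summarise(
        As_free_uM = mean(.data$As_free_uM),
        As_bound_uM = mean(.data$As_bound_uM),
        .groups = "drop"
      ) |>
      arrange(.data$As_total_uM)
    attr(data, "params") <- attrs
  }
  pts <- scatchard_transform(data, suspension)
  seg <- select_linear_segment(pts$M_free_uM, pts$y_uM,
                               min_len = min(min_len, nrow(pts)),
                               r2_min = r2_min)
  scatchard_fit(pts, seg, label = label)
}

#' Table-style report of one or more Scatchard fits
#'
#' Lays out fits the way solid-phase affinity tables are printed:
#' adsorbent, fitted equation, K_A in 1e6 M^-1, n in 1e7 sites/particle,
#' and R-squared.
#'
#' @param ... `scatchard_fit` objects, or a single list of them.
#' @return A tibble with columns `adsorbent`, `scatchard_equation`,
#'   `K_A_e6_per_M`, `K_A_sd`, `n_e7`, `n_e7_sd`, `R2`.
#' @export
scatchard_report <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "scatchard_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(all(vapply(fits, inherits, TRUE, "scatchard_fit")))
  purrr::map_dfr(fits, function(f) {
    tibble(
      adsorbent = f$label,
      scatchard_equation = f$equation,
      K_A_e6_per_M = f$K_A_e6_per_M,
      K_A_sd = f$K_A_sd,
      n_e7 = f$n_e7,
      n_e7_sd = f$n_e7_sd,
      R2 = f$r_squared
    )
  })
}
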