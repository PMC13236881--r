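#' Close the competitive-binding mass balance
#'
#' In a two-receptor competition (immobilized receptor R on particles vs
#' free competitor protein P), only the ligand bound to the solid phase
#' (`R_bound_uM`) is measured directly. Under 1:1 stoichiometry and the
#' high-affinity closure that free ligand is negligible when ligand is
#' not in excess, the remaining species follow by mass balance:
#' \deqn{R_f = R_t - R_b, \quad P_b = As_t - R_b, \quad P_f = P_t - P_b}
#' yielding one point `(x, y) = (P_f/P_b, R_f/R_b)` per ligand level.
#' Points where the closure degenerates (`P_b <= 0`, `R_b <= 0`,
#' `R_b > R_t`, or `P_b > P_t`) are flagged and excluded, never imputed.
#'
#' When the table carries an exact simulated free-ligand column
#' (`As_free_exact_uM`), each point is additionally flagged when free
#' ligand exceeds 1% of total — outside that regime the closure is known
#' to bias the fitted ratio.
#'
#' @param data A competition table with columns `As_total_uM`,
#'   `R_bound_uM`.
#' @param R_total_uM Total immobilized site concentration, uM (typically
#'   the Scatchard-fitted n times the particle molarity); defaults to the
#'   table's attribute when present.
#' @param P_total_uM Total competitor site concentration, uM.
#' @return A tibble with the balance columns `R_f`, `P_b`, `P_f`, the
#'   regression coordinates `x`, `y`, `usable`, and an `exclusion_reason`
#'   plus `free_ligand_ok` flag.
#' @export
competitive_mass_balance <- function(data, R_total_uM = NULL, P_total_uM = NULL) {
  data <- require_columns(data, c("As_total_uM", "R_bound_uM"),
                          "competition table")
  R_total_uM <- R_total_uM %||% attr(data, "R_total_uM")
  P_total_uM <- P_total_uM %||% attr(data, "P_total_uM")
  if (is.null(R_total_uM) || is.null(P_total_uM)) {
    abort("Supply `R_total_uM` and `P_total_uM` (or a table carrying them).",
          class = "arsbind_invalid_argument")
  }
  check_number(R_total_uM, "R_total_uM", min = 0, allow_zero = FALSE)
  check_number(P_total_uM, "P_total_uM", min = 0, allow_zero = FALSE)

  out <- data |>
    mutate(
      R_f = R_total_uM - .data$R_bound_uM,
      P_b = .data$As_total_uM - .data$R_bound_uM, # free ligand set to 0
      P_f = P_total_uM - .data$P_b,
      exclusion_reason = dplyr::case_when(
        .data$As_total_uM <= 0 ~ "zero total ligand",
        .data$R_bound_uM <= 0 ~ "zero solid-phase binding",
        .data$R_bound_uM > R_total_uM ~ "bound exceeds R_total",
        .data$P_b <= 0 ~ "competitor bound nothing",
        .data$P_b > P_total_uM ~ "implied P_b exceeds P_total",
        TRUE ~ NA_character_
      ),
      usable = is.na(.data$exclusion_reason),
      x = ifelse(.data$usable, .data$P_f / .data$P_b, NA_real_),
      y = ifelse(.data$usable, .data$R_f / .data$R_bound_uM, NA_real_)
    )
  if ("As_free_exact_uM" %in% names(data)) {
    out$free_ligand_ok <- data$As_free_exact_uM < 0.01 * data$As_total_uM
  } else {
    out$free_ligand_ok <- NA
  }
  n_dropped <- sum(!out$usable)
  if (n_dropped > 0) {
    inform(sprintf("Competitive mass balance: excluded %d point(s) (%s).",
                   n_dropped,
                   paste(unique(stats::na.omit(out$exclusion_reason)),
                         collapse = "; ")))
  }
  if (all(!out$usable)) {
    abort("Every competition point was excluded by the mass-balance checks.",
          class = "arsbind_insufficient_data")
  }
  out
}

#' Fit the dissociation-constant ratio from competition points
#'
#' The closed mass balance linearizes the competition as
#' \deqn{\frac{R_f}{R_b} = \frac{P_f}{P_b} \cdot \frac{K_{D1}}{K_{D2}}}
#' so the slope of `y` on `x` estimates the ratio of dissociation
#' constants K_D1/K_D2. The intercept (theoretically zero) is retained
#' as a diagnostic rather than forced through the origin; its deviation
#' from zero is reported.
#'
#' @param points Output of [competitive_mass_balance()] (columns `x`,
#'   `y`, `usable`).
#' @return A `competitive_fit`: `ratio` (= K_D1/K_D2), `intercept`,
#'   `r_squared`, `n_points_used`, per-point flags, and the `lm`.
#' @export
fit_affinity_ratio <- function(points) {
  points <- require_columns(points, c("x", "y"), "competition points")
  if (!"usable" %in% names(points)) points$usable <- TRUE
  d <- points[points$usable & is.finite(points$x) & is.finite(points$y), ,
              drop = FALSE]
  if (nrow(d) < 3L) {
    abort("Affinity-ratio fit needs at least 3 usable points.",
          class = "arsbind_insufficient_data")
  }
  if (length(unique(d$x)) < 2L) {
    abort("All competition points share one x value; slope undefined.",
          class = "arsbind_fit_failure")
  }
  fit <- lm(y ~ x, data = d)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope <= 0) {
    abort(sprintf("Fitted K_D ratio %.4g is non-positive; check the design.",
                  slope),
          class = "arsbind_fit_failure")
  }
  structure(
    list(
      ratio = slope,
      ratio_sd = summary(fit)$coefficients["x", "Std. Error"],
      intercept = intercept,
      r_squared = summary(fit)$r.squared,
      n_points_used = nrow(d),
      points = points,
      fit = fit
    ),
    class = "competitive_fit"
  )
}

#' @export
print.competitive_fit <- function(x, ...) {
  cat("<competitive_fit>\n")
  cat(sprintf("  K_D1/K_D2 = %.4f +/- %.4f  (R^2 = %.4f, %d points)\n",
              x$ratio, x$ratio_sd, x$r_squared, x$n_points_used))
  cat(sprintf("  intercept (expected ~0): %.4g\n", x$intercept))
  invisible(x)
}

#' Affinity of the free protein from a competition fit
#'
#' Since the fitted slope is \eqn{K_{D1}/K_{D2} = K_{A,P}/K_{A,R}}, the
#' free competitor's association constant follows from the immobilized
#' reference's: \eqn{K_{A,free} = ratio \times K_{A,immobilized}}. The
#' relative deviation between the two is reported — when R and P are the
#' same protein in immobilized and free form, this deviation measures
#' whether immobilization changed the affinity.
#'
#' @param fit A `competitive_fit`, or a bare positive ratio.
#' @param K_A_immobilized_per_uM Association constant of the immobilized
#'   reference, uM^-1 (numerically 1e6 M^-1).
#' @return A tibble: `ratio`, `K_A_free_per_uM`, `K_A_free_e6_per_M`,
#'   `K_A_immobilized_e6_per_M`, `deviation_pct`.
#' @export
#' @examples
#' free_affinity(1.0259, 30.49)  # ~31.28e6 M^-1, deviation ~2.5%
free_affinity <- function(fit, K_A_immobilized_per_uM) {
  ratio <- if (inherits(fit, "competitive_fit")) fit$ratio else fit
  check_number(ratio, "ratio", min = 0, allow_zero = FALSE)
  check_number(K_A_immobilized_per_uM, "K_A_immobilized_per_uM", min = 0,
               allow_zero = FALSE)
  KA_free <- ratio * K_A_immobilized_per_uM
  tibble(
    ratio = ratio,
    K_A_free_per_uM = KA_free,
    K_A_free_e6_per_M = KA_free,
    K_A_immobilized_e6_per_M = K_A_immobilized_per_uM,
    deviation_pct = 100 * abs(KA_free - K_A_immobilized_per_uM) / KA_free
  )
}

#' End-to-end competitive affinity inference
#'
#' Convenience composition: mass-balance closure, ratio fit, and free
#' affinity derivation, with `R_total_uM` computed as the Scatchard
#' site number times the particle molarity when a `scatchard_fit` for
#' the immobilized reference is supplied.
#'
#' @param data Competition table (`As_total_uM`, `R_bound_uM`).
#' @param reference A `scatchard_fit` of the immobilized reference, used
#'   for both `R_total_uM` (= n x particle molarity) and the reference
#'   affinity; alternatively supply `R_total_uM` and
#'   `K_A_immobilized_per_uM` directly.
#' @param suspension Suspension of the immobilized phase (needed with
#'   `reference` to form n x molarity).
#' @param P_total_uM Competitor site concentration, uM.
#' @param R_total_uM,K_A_immobilized_per_uM Direct overrides.
#' @return A `competitive_fit` with a `free_affinity` element attached.
#' @export
compete_affinity <- function(data, reference = NULL, suspension = NULL,
                             P_total_uM = NULL, R_total_uM = NULL,
                             K_A_immobilized_per_uM = NULL) {
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "scatchard_fit"))
    if (is.null(R_total_uM)) {
      if (is.null(suspension)) {
        abort("Supply `suspension` so R_total can be formed as n x molarity.",
              class = "arsbind_invalid_argument")
      }
      R_total_uM <- reference$n_sites * suspension$molar_conc_uM[[1]]
    }
    K_A_immobilized_per_uM <- K_A_immobilized_per_uM %||% reference$K_A_per_uM
  }
  bal <- competitive_mass_balance(data, R_total_uM = R_total_uM,
                                  P_total_uM = P_total_uM)
  fit <- fit_affinity_ratio(bal)
  if (!is.null(K_A_immobilized_per_uM)) {
    fit$free_affinity <- free_affinity(fit, K_A_immobilized_per_uM)
  }
  fit
}
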