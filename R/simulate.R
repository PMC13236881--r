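#' Measurement-noise model for simulated experiments
#'
#' Simulated measurements can be left exact (`"none"`) or perturbed by
#' multiplicative Gaussian noise applied to bound amounts,
#' `x * N(1, cv)`. Triplicate standard deviations in solid-phase binding
#' assays of this kind are typically 1-3% of the mean, hence the default
#' coefficient of variation of 0.03. A seed is mandatory for the noisy
#' model; all draws happen inside [withr::with_seed()], so the global RNG
#' state is never touched.
#'
#' @param kind `"none"` or `"multiplicative-gaussian"`.
#' @param cv Coefficient of variation (dimensionless, >= 0).
#' @param seed Integer seed; required unless `kind = "none"`.
#' @return A list of class `noise_model`.
#' @export
#' @examples
#' noise_model()                                  # exact
#' noise_model("multiplicative-gaussian", seed = 1)
noise_model <- function(kind = c("none", "multiplicative-gaussian"),
                        cv = 0.03, seed = NULL) {
  kind <- match.arg(kind)
  check_number(cv, "cv", min = 0)
  if (kind != "none" && is.null(seed)) {
    abort("A `seed` is required for any stochastic noise model.",
          class = "arsbind_invalid_argument")
  }
  structure(list(kind = kind, cv = cv, seed = seed), class = "noise_model")
}

# Applies the noise model to a non-negative measurement vector.
# Negative perturbed values are clamped to 0 with a warning (physical support).
apply_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$kind == "none" || noise$cv == 0) {
    return(x)
  }
  y <- withr::with_seed(noise$seed, x * rnorm(length(x), mean = 1, sd = noise$cv))
  if (any(y < 0)) {
    warn(sprintf("%d noisy value(s) fell below zero and were clamped to 0.",
                 sum(y < 0)))
    y[y < 0] <- 0
  }
  y
}

#' Simulate an equilibrium binding isotherm
#'
#' Forward-simulates a single-receptor isotherm: for each total ligand
#' level the exact 1:1 Langmuir equilibrium is solved
#' ([solve_single_equilibrium()]), optional noise is applied to the bound
#' amount, and the free amount is recomputed as total minus bound so the
#' reported mass balance always closes. The generating parameters are
#' attached as the `"params"` attribute for recovery tests.
#'
#' @param params A [binding_params()] object.
#' @param As_totals_uM Strictly positive total-ligand levels, uM.
#' @param noise A [noise_model()].
#' @param label Dataset label.
#' @return A tibble with columns `label`, `As_total_uM`, `As_free_uM`,
#'   `As_bound_uM` (the isotherm table schema).
#' @export
#' @examples
#' s <- adsorbent_suspension(1.00, 1.657e11)
#' p <- binding_params(30.49, 2.80e7, s)
#' simulate_isotherm(p, seq(0.2, 2, by = 0.2))
simulate_isotherm <- function(params, As_totals_uM, noise = noise_model(),
                              label = params$suspension$label[[1]]) {
  stopifnot(inherits(params, "binding_params"))
  check_number(As_totals_uM, "As_totals_uM", min = 0, allow_zero = FALSE)
  eq <- solve_single_equilibrium(As_totals_uM, params$capacity_uM,
                                 params$K_A_per_uM)
  bound <- apply_noise(eq$M_bound_uM, noise)
  out <- tibble(
    label = label,
    As_total_uM = As_totals_uM,
    As_free_uM = As_totals_uM - bound,
    As_bound_uM = bound
  )
  attr(out, "params") <- params
  attr(out, "noise") <- noise
  out
}

#' Simulate an adsorption kinetics time course
#'
#' Generates uptake curves from the closed forms of the two classical
#' empirical rate laws: pseudo-first-order
#' \eqn{Q_t = Q_e (1 - e^{-kt})} and pseudo-second-order
#' \eqn{Q_t = Q_e^2 k t / (1 + Q_e k t)}.
#'
#' @param model `"PFO"` or `"PSO"`.
#' @param Q_e Equilibrium adsorption amount, ug adsorbate per g adsorbent.
#' @param k Rate constant: 1/h for PFO, g/(ug h) for PSO.
#' @param times_h Sampling times, h (non-negative).
#' @param noise A [noise_model()] applied to `Q_t`.
#' @return A tibble with columns `t_h`, `Q_ug_per_g` (the kinetics table
#'   schema), with the generating parameters in the `"params"` attribute.
#' @export
#' @examples
#' simulate_kinetics("PSO", Q_e = 100, k = 0.001, times_h = c(1, 5, 10))
simulate_kinetics <- function(model, Q_e, k, times_h, noise = noise_model()) {
  if (!is.character(model) || length(model) != 1L ||
      !toupper(model) %in% c("PFO", "PSO")) {
    abort("`model` must be \"PFO\" or \"PSO\".",
          class = "arsbind_invalid_argument")
  }
  model <- toupper(model)
  check_number(Q_e, "Q_e", min = 0, allow_zero = FALSE)
  check_number(k, "k", min = 0, allow_zero = FALSE)
  check_number(times_h, "times_h", min = 0)
  Qt <- switch(model,
    PFO = Q_e * (1 - exp(-k * times_h)),
    PSO = Q_e^2 * k * times_h / (1 + Q_e * k * times_h)
  )
  out <- tibble(t_h = times_h, Q_ug_per_g = apply_noise(Qt, noise))
  attr(out, "params") <- list(model = model, Q_e = Q_e, k = k)
  out
}

#' Simulate a competitive adsorption series
#'
#' For each total ligand level the exact two-receptor equilibrium is
#' solved ([solve_competitive_equilibrium()]); the recorded observable is
#' the ligand bound to the immobilized receptor (the pellet fraction an
#' assay actually measures), optionally with noise. The exact free-ligand
#' and competitor-bound columns are kept so the validity of the
#' negligible-free-ligand closure can be audited downstream.
#'
#' @param params A [competitive_params()] object.
#' @param As_totals_uM Strictly positive total-ligand levels, uM.
#' @param noise A [noise_model()] applied to the bound-to-solid amounts.
#' @return A tibble with columns `As_total_uM`, `R_bound_uM` (observed),
#'   plus exact-simulation columns `As_free_exact_uM`, `P_bound_exact_uM`;
#'   `R_total_uM`, `P_total_uM` and the generating parameters travel as
#'   attributes.
#' @export
#' @examples
#' cp <- competitive_params(0.033, 0.032, R_total_uM = 7.7, P_total_uM = 7.85)
#' simulate_competitive_series(cp, seq(1, 7, by = 1))
simulate_competitive_series <- function(params, As_totals_uM,
                                        noise = noise_model()) {
  stopifnot(inherits(params, "competitive_params"))
  check_number(As_totals_uM, "As_totals_uM", min = 0, allow_zero = FALSE)
  eq <- solve_competitive_equilibrium(
    As_totals_uM, params$KD1_uM, params$KD2_uM,
    params$R_total_uM, params$P_total_uM
  )
  out <- tibble(
    As_total_uM = eq$As_total_uM,
    R_bound_uM = apply_noise(eq$R_bound_uM, noise),
    As_free_exact_uM = eq$As_free_uM,
    P_bound_exact_uM = eq$P_bound_uM
  )
  attr(out, "params") <- params
  attr(out, "R_total_uM") <- params$R_total_uM
  attr(out, "P_total_uM") <- params$P_total_uM
  out
}
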