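#' Exact 1:1 Langmuir equilibrium
#'
#' Solves the single-receptor binding equilibrium
#' \deqn{M_b = \frac{C \, K_A \, M_f}{1 + K_A M_f}, \qquad M_f + M_b = M_t}
#' for total ligand `M_total_uM`, site capacity `capacity_uM` (sites per
#' particle times particle molarity) and association constant
#' `K_A_per_uM`. The physical root of the resulting quadratic is taken in
#' a cancellation-free form, so conservation holds to machine precision
#' even in the saturation limit.
#'
#' @param M_total_uM Total ligand, uM (vectorized, non-negative).
#' @param capacity_uM Total site concentration, uM (non-negative).
#' @param K_A_per_uM Association constant, uM^-1 (positive).
#' @return A tibble with columns `M_total_uM`, `M_free_uM`, `M_bound_uM`.
#' @export
#' @examples
#' solve_single_equilibrium(1, 1, 1)  # M_free = (sqrt(5) - 1) / 2
solve_single_equilibrium <- function(M_total_uM, capacity_uM, K_A_per_uM) {
  check_number(M_total_uM, "M_total_uM", min = 0)
  check_number(capacity_uM, "capacity_uM", min = 0)
  check_number(K_A_per_uM, "K_A_per_uM", min = 0, allow_zero = FALSE)

  n <- max(length(M_total_uM), length(capacity_uM), length(K_A_per_uM))
  Mt <- rep_len(M_total_uM, n)
  C <- rep_len(capacity_uM, n)
  KA <- rep_len(K_A_per_uM, n)

  # K_A Mb^2 - (1 + K_A (Mt + C)) Mb + K_A C Mt = 0; smaller root is physical.
  b <- 1 + KA * (Mt + C)
  disc <- b^2 - 4 * KA^2 * C * Mt
  disc[disc < 0] <- 0 # guard tiny negative from roundoff
  Mb <- 2 * KA * C * Mt / (b + sqrt(disc))
  Mb <- pmin(Mb, Mt, C)
  if (any(Mb < 0 | Mb > Mt + 1e-9 * pmax(Mt, 1))) {
    abort("Langmuir solver produced a non-physical root.",
          class = "arsbind_internal_error")
  }
  tibble(M_total_uM = Mt, M_free_uM = Mt - Mb, M_bound_uM = Mb)
}

#' Exact two-receptor competitive equilibrium
#'
#' Solves the coupled equilibria of an immobilized receptor R (dissociation
#' constant `KD1_uM`, total sites `R_total_uM`) and a free competitor
#' protein P (`KD2_uM`, `P_total_uM`) for the free ligand concentration f:
#' \deqn{R_b = \frac{R_t f}{K_{D1} + f}, \quad
#'       P_b = \frac{P_t f}{K_{D2} + f}, \quad
#'       f + R_b + P_b = As_t}
#' by bisection on the bracket \[0, As_t\] (the left-hand side is strictly
#' increasing in f), refined until the mass-balance residual is below
#' 1e-12 of the total.
#'
#' @param As_total_uM Total ligand, uM (vectorized, non-negative).
#' @param KD1_uM,KD2_uM Dissociation constants of R and P, uM (positive).
#' @param R_total_uM,P_total_uM Total site concentrations, uM (non-negative;
#'   `P_total_uM = 0` reduces to the single-receptor case).
#' @return A tibble with columns `As_total_uM`, `As_free_uM`,
#'   `R_bound_uM`, `P_bound_uM`.
#' @export
#' @examples
#' # symmetric case: f satisfies f^2 + 2 f - 1 = 0
#' solve_competitive_equilibrium(1, 1, 1, 1, 1)
solve_competitive_equilibrium <- function(As_total_uM, KD1_uM, KD2_uM,
                                          R_total_uM, P_total_uM) {
  check_number(As_total_uM, "As_total_uM", min = 0)
  check_number(KD1_uM, "KD1_uM", min = 0, allow_zero = FALSE)
  check_number(KD2_uM, "KD2_uM", min = 0, allow_zero = FALSE)
  check_number(R_total_uM, "R_total_uM", min = 0)
  check_number(P_total_uM, "P_total_uM", min = 0)

  solve_one <- function(At) {
    if (At == 0) {
      return(c(f = 0, Rb = 0, Pb = 0))
    }
    g <- function(f) {
      f + R_total_uM * f / (KD1_uM + f) + P_total_uM * f / (KD2_uM + f) - At
    }
    lo <- 0
    hi <- At
    flo <- g(lo)
    for (i in seq_len(200L)) {
      mid <- (lo + hi) / 2
      gm <- g(mid)
      if (gm <= 0) lo <- mid else hi <- mid
      if ((hi - lo) < 1e-16 * At) break
    }
    f <- (lo + hi) / 2
    if (abs(g(f)) > 1e-12 * At) {
      abort(
        sprintf("Competitive equilibrium did not converge (residual %.3e at As_total = %g uM).",
                g(f), At),
        class = "arsbind_numerical_error"
      )
    }
    c(f = f,
      Rb = R_total_uM * f / (KD1_uM + f),
      Pb = P_total_uM * f / (KD2_uM + f))
  }

  out <- vapply(As_total_uM, solve_one, numeric(3))
  tibble(
    As_total_uM = As_total_uM,
    As_free_uM = unname(out["f", ]),
    R_bound_uM = unname(out["Rb", ]),
    P_bound_uM = unname(out["Pb", ])
  )
}

#' Binding parameters of an immobilized-receptor preparation
#'
#' Bundles the association constant, the per-particle site number and the
#' suspension metadata that define a 1:1 Langmuir system; the total site
#' capacity (uM) is derived as sites per particle times particle molarity.
#'
#' @param K_A_per_uM Association constant, uM^-1 (numerically equal to the
#'   value in 1e6 M^-1).
#' @param sites_per_particle Binding sites per particle (order 1e7 for
#'   protein-saturated biosilica spheres).
#' @param suspension An [adsorbent_suspension()] row.
#' @return A list of class `binding_params` with elements `K_A_per_uM`,
#'   `K_D_uM`, `sites_per_particle`, `suspension`, `capacity_uM`.
#' @export
#' @examples
#' s <- adsorbent_suspension(1.00, 1.657e11)
#' binding_params(30.49, 2.80e7, s)
binding_params <- function(K_A_per_uM, sites_per_particle, suspension) {
  check_number(K_A_per_uM, "K_A_per_uM", min = 0, allow_zero = FALSE)
  check_number(sites_per_particle, "sites_per_particle", min = 0,
               allow_zero = FALSE)
  stopifnot(is.data.frame(suspension), "molar_conc_uM" %in% names(suspension))
  capacity <- sites_per_particle * suspension$molar_conc_uM[[1]]
  if (capacity <= 0) {
    abort("Derived site capacity must be positive; check the suspension molarity.",
          class = "arsbind_invalid_argument")
  }
  structure(
    list(
      K_A_per_uM = K_A_per_uM,
      K_D_uM = 1 / K_A_per_uM,
      sites_per_particle = sites_per_particle,
      suspension = suspension,
      capacity_uM = capacity
    ),
    class = "binding_params"
  )
}

#' @export
print.binding_params <- function(x, ...) {
  cat("<binding_params>\n")
  cat(sprintf("  K_A: %.4g uM^-1 (K_D %.4g uM)\n", x$K_A_per_uM, x$K_D_uM))
  cat(sprintf("  sites/particle: %.4g; capacity: %.4g uM\n",
              x$sites_per_particle, x$capacity_uM))
  invisible(x)
}

#' Competitive-binding parameters
#'
#' @param KD1_uM Dissociation constant of the immobilized receptor R, uM.
#' @param KD2_uM Dissociation constant of the free competitor P, uM.
#' @param R_total_uM,P_total_uM Total site concentrations, uM (positive).
#' @return A list of class `competitive_params`.
#' @export
competitive_params <- function(KD1_uM, KD2_uM, R_total_uM, P_total_uM) {
  for (nm in c("KD1_uM", "KD2_uM", "R_total_uM", "P_total_uM")) {
    check_number(get(nm), nm, min = 0, allow_zero = FALSE)
  }
  structure(
    list(KD1_uM = KD1_uM, KD2_uM = KD2_uM,
         R_total_uM = R_total_uM, P_total_uM = P_total_uM),
    class = "competitive_params"
  )
}

#' @export
print.competitive_params <- function(x, ...) {
  cat("<competitive_params>\n")
  cat(sprintf("  KD1: %.4g uM, KD2: %.4g uM (ratio %.4g)\n",
              x$KD1_uM, x$KD2_uM, x$KD1_uM / x$KD2_uM))
  cat(sprintf("  R_total: %.4g uM, P_total: %.4g uM\n",
              x$R_total_uM, x$P_total_uM))
  invisible(x)
}
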