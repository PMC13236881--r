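#' Avogadro's constant
#'
#' The exact SI value of Avogadro's constant, used for every
#' particle-count / molar conversion in the package.
#'
#' @return A length-one numeric, 6.02214076e23 mol^-1.
#' @export
#' @examples
#' avogadro()
avogadro <- function() AVOGADRO

#' Molar concentration of a particle suspension
#'
#' Converts a mass concentration of adsorbent particles (e.g. biosilica
#' spheres) and a per-gram particle count into a molar particle
#' concentration, treating each particle as one "molecule". A 1.00 g/L
#' suspension counted at 1.657e11 particles per gram is 2.753e-7 uM.
#'
#' @param mass_conc_g_per_L Mass concentration of the suspension, g/L.
#' @param particles_per_gram Particle count per gram of adsorbent.
#' @return Molar particle concentration in uM (numeric, vectorized).
#' @seealso [particle_molar_mass()], [adsorbent_suspension()]
#' @export
#' @examples
#' suspension_molarity(1.00, 1.657e11)  # ~2.75e-7 uM
suspension_molarity <- function(mass_conc_g_per_L, particles_per_gram) {
  check_number(mass_conc_g_per_L, "mass_conc_g_per_L", min = 0)
  check_number(particles_per_gram, "particles_per_gram", min = 0)
  # mol/L = (g/L * particles/g) / N_A; * 1e6 -> uM
  mass_conc_g_per_L * particles_per_gram / AVOGADRO * 1e6
}

#' Molar mass of a particle preparation
#'
#' The gram mass of one mole of particles, N_A divided by the per-gram
#' particle count. A preparation counted at 1.657e11 particles per gram
#' has a molar mass of ~3.63e12 g/mol.
#'
#' @param particles_per_gram Particle count per gram; must be positive.
#' @return Molar mass in g/mol.
#' @export
#' @examples
#' particle_molar_mass(1.657e11)
particle_molar_mass <- function(particles_per_gram) {
  check_number(particles_per_gram, "particles_per_gram", min = 0,
               allow_zero = FALSE)
  AVOGADRO / particles_per_gram
}

#' Ligand specification
#'
#' A one-row tibble naming a ligand and its atomic or molecular mass,
#' used for mass/molar interconversion of ligand concentrations.
#' Defaults to arsenic (74.92 g/mol), for which 100 ug/L As(III) is
#' 1.33 uM.
#'
#' @param name Ligand name.
#' @param molar_mass_g_per_mol Atomic or molecular mass, g/mol; positive.
#' @return A tibble with columns `name`, `molar_mass_g_per_mol`.
#' @export
#' @examples
#' ligand_spec()
#' ligand_spec("Sb(III)", 121.76)
ligand_spec <- function(name = "As(III)", molar_mass_g_per_mol = 74.92) {
  check_number(molar_mass_g_per_mol, "molar_mass_g_per_mol", min = 0,
               allow_zero = FALSE)
  tibble(name = name, molar_mass_g_per_mol = molar_mass_g_per_mol)
}

#' Convert ligand mass concentration to molarity
#'
#' ug/L divided by g/mol gives umol/L directly, so no power-of-ten
#' factor appears.
#'
#' @param conc_ug_per_L Concentration in ug/L; non-negative.
#' @param ligand A [ligand_spec()] tibble, or a bare molar mass in g/mol.
#' @return Concentration in uM.
#' @export
#' @examples
#' ligand_mass_to_molar(100)          # 100 ug/L As -> 1.33 uM
#' ligand_mass_to_molar(200, 74.92)
ligand_mass_to_molar <- function(conc_ug_per_L, ligand = ligand_spec()) {
  check_number(conc_ug_per_L, "conc_ug_per_L", min = 0)
  mass <- ligand_mass_of(ligand)
  conc_ug_per_L / mass
}

#' Convert ligand molarity to mass concentration
#'
#' Inverse of [ligand_mass_to_molar()].
#'
#' @inheritParams ligand_mass_to_molar
#' @param conc_uM Concentration in uM; non-negative.
#' @return Concentration in ug/L.
#' @export
ligand_molar_to_mass <- function(conc_uM, ligand = ligand_spec()) {
  check_number(conc_uM, "conc_uM", min = 0)
  conc_uM * ligand_mass_of(ligand)
}

ligand_mass_of <- function(ligand) {
  mass <- if (is.data.frame(ligand)) ligand$molar_mass_g_per_mol else ligand
  check_number(mass, "molar_mass_g_per_mol", min = 0, allow_zero = FALSE)
  mass
}

#' Describe an adsorbent suspension
#'
#' Builds the mass / particle-count / molar bookkeeping record for a
#' particle suspension: the molar particle concentration and the particle
#' molar mass are derived exactly from the two measured quantities.
#'
#' @param mass_conc_g_per_L Mass concentration, g/L (non-negative).
#' @param particles_per_gram Particles per gram (positive).
#' @param label Free-text label for the preparation.
#' @return A one-row tibble with columns `label`, `mass_conc_g_per_L`,
#'   `particles_per_gram`, `molar_conc_uM`, `molar_mass_g_per_mol`.
#' @export
#' @examples
#' adsorbent_suspension(1.00, 1.657e11, label = "S")
adsorbent_suspension <- function(mass_conc_g_per_L, particles_per_gram,
                                 label = "adsorbent") {
  check_number(mass_conc_g_per_L, "mass_conc_g_per_L", min = 0)
  check_number(particles_per_gram, "particles_per_gram", min = 0,
               allow_zero = FALSE)
  tibble(
    label = label,
    mass_conc_g_per_L = mass_conc_g_per_L,
    particles_per_gram = particles_per_gram,
    molar_conc_uM = suspension_molarity(mass_conc_g_per_L, particles_per_gram),
    molar_mass_g_per_mol = particle_molar_mass(particles_per_gram)
  )
}

# shared scalar/vector argument validation
check_number <- function(x, name, min = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) < 1L) {
    abort(sprintf("`%s` must be numeric.", name), class = "arsbind_invalid_argument")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite and non-missing.", name),
          class = "arsbind_invalid_argument")
  }
  if (any(x < min)) {
    abort(sprintf("`%s` must be >= %s.", name, format(min)),
          class = "arsbind_invalid_argument")
  }
  if (!allow_zero && any(x == min)) {
    abort(sprintf("`%s` must be > %s.", name, format(min)),
          class = "arsbind_invalid_argument")
  }
  invisible(x)
}
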