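---
title: "Quantifying protein–As(III) affinity on biosilica particles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein–As(III) affinity on biosilica particles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arsbind)
```

# The measurement problem

Metalloregulator proteins of the ArsR/SmtB family bind arsenite (As(III))
through cysteine thiols. Measuring how tightly a given homolog binds is
awkward in free solution: fluorescence quenching can be too weak to
titrate, and chromatographic methods need purified protein. A practical
alternative is to immobilize the protein covalently (via a
SpyTag/SpyCatcher isopeptide bond) on biosilica microspheres and treat
the decorated particle as a solid-phase adsorbent: spike known total
As(III), pellet the particles, and measure arsenic on the solid phase.
`arsbind` implements the quantitative layer of that workflow — unit
accounting, kinetics, equilibrium thermodynamics, competition analysis
and selectivity scoring — together with a seeded simulator that
generates every experiment type from exact equilibrium solvers.

# Particle-molarity accounting

The solid phase is treated as a chemical species: a suspension counted
at $N_p$ particles per gram and dosed at $c$ g/L has particle molarity
$c \, N_p / N_A$ (mol/L) and particle molar mass $N_A / N_p$ (g/mol),
with $N_A = 6.02214076 \times 10^{23}$ held at its exact SI value. All
concentrations are carried internally in µM; report functions rescale
to the display conventions of the field ($K_A$ in $10^6\,\mathrm{M^{-1}}$,
site numbers in $10^7$ per particle). A 1.00 g/L sphere preparation
counted at $1.657 \times 10^{11}$ particles/g is
$2.75 \times 10^{-7}$ µM — eight orders of magnitude below the ligand,
which is why per-particle site numbers of order $10^7$ arise.

Ligand conversions use µg/L ÷ (g/mol) = µM directly; arsenic defaults
to 74.92 g/mol (so 100 µg/L As(III) is 1.33 µM) and any other ligand
can be supplied through `ligand_spec()`.

# Equilibrium model and Scatchard analysis

Binding is modelled as 1:1 association of ligand M with independent,
identical sites on the particle surface:

$$K_A = \frac{[M]_b}{[M]_f \,( n[S] - [M]_b )},$$

where $n$ is the number of sites per particle and $[S]$ the particle
molarity. Writing the per-particle occupancy $\mu = [M]_b/[S]_t$ gives
the Scatchard linearization

$$\frac{[M]_f}{\mu} = \frac{K_D}{n} + \frac{[M]_f}{n}.$$

Because $\mu$ is of order $10^7$ here, the package carries occupancy in
units of $10^7$ (`mu_e7`), so the fitted slope is $10^7/n$ and the
intercept $K_D$ over $n$ in the same scaled units. The derived
quantities are $K_A = \mathrm{slope}/\mathrm{intercept}$ (µM$^{-1}$,
numerically equal to the value in $10^6\,\mathrm{M^{-1}}$) and
$n = 10^7/\mathrm{slope}$. These identities hold exactly by
construction (`scatchard_params()` is the single code path used both
for fits and for converting published regression lines).

```{r}
scatchard_params(0.3567, 0.0117)[, c("K_A_e6_per_M", "n_e7", "K_D_uM")]
```

**Segment selection.** Scatchard plots curve where binding saturates,
where a second site class appears, or where single points are grossly
off. `select_linear_segment()` enumerates every contiguous run of at
least `min_len` points, and returns the longest run whose OLS
$R^2 \ge$ `r2_min`, breaking ties by higher $R^2$ and then by earlier
start. Defaults are `min_len = 4` (a two-parameter line through fewer
points is barely constrained) and `r2_min = 0.99` (the fit quality a
well-behaved 1:1 system attains). Runs with zero spread in $x$ are
skipped; exactly collinear runs score $R^2 = 1$. The enumeration is
quadratic in the number of points, which is irrelevant at the 8–30
point scale of these designs.

**Uncertainties.** Standard errors for $K_A$ and $n$ are propagated
from the regression coefficient covariance by the delta method
($K_A = s/i$, $n \propto 1/s$). Replicate measurements at the same
total-ligand level are averaged before the transform.

**Blank handling.** Bare-silica controls are analysed as their own
adsorbent rather than subtracted from conjugate isotherms by default;
the two preparations are fitted and reported side by side.

# Adsorption kinetics

Two classical empirical rate laws are fitted through their standard
linearizations, mirroring how adsorption tables are reported:

* pseudo-first-order (PFO): $\ln(Q_e - Q_t) = \ln Q_e - k t$, fitted by
  OLS of $\ln(Q_e - Q_t)$ on $t$; $k = -\mathrm{slope}$,
  $Q_e = e^{\mathrm{intercept}}$;
* pseudo-second-order (PSO): $t/Q_t = 1/(k Q_e^2) + t/Q_e$, fitted by
  OLS of $t/Q_t$ on $t$; $Q_e = 1/\mathrm{slope}$,
  $k = \mathrm{slope}^2/\mathrm{intercept}$.

Design choices worth stating:

* The $Q_e$ entering the PFO log transform defaults to the maximum
  observed uptake when not supplied — the transform needs a value, and
  the plateau is the only assumption-free candidate. Points with
  $Q_t \ge Q_e$ have no defined transform and are dropped and counted,
  never perturbed.
* Model selection is by linearized-fit $R^2$; an exact tie prefers PSO,
  whose chemisorption reading matches thiol-coordination chemistry.
* The linearized estimators are primary because they are what this
  assay family's tables report; `refit_kinetics_nonlinear()` offers a
  clearly-labelled nonlinear refit as a linearization-bias diagnostic
  (with `scaleOffset` in the convergence control so exact synthetic
  data do not defeat the relative-offset test).

# Competitive affinity inference

To ask whether immobilization changed a protein's affinity, the
immobilized receptor R competes with the free protein P for a shared
As(III) pool. Only the solid-phase bound amount $[R]_b$ is measured;
the remaining species follow from mass balance under 1:1 stoichiometry
and the closure that free As(III) is negligible when ligand is not in
excess:

$$[R]_f = [R]_t - [R]_b, \quad [P]_b = [\mathrm{As}]_T - [R]_b, \quad
  [P]_f = [P]_t - [P]_b,$$

which linearizes to

$$\frac{[R]_f}{[R]_b} = \frac{K_{D1}}{K_{D2}} \cdot \frac{[P]_f}{[P]_b}.$$

The slope of $[R]_f/[R]_b$ on $[P]_f/[P]_b$ estimates the dissociation
constant ratio, and $K_{A,\mathrm{free}} = \mathrm{ratio} \times
K_{A,\mathrm{immobilized}}$. Implementation decisions:

* $[R]_t$ is formed as the Scatchard-fitted site number times the
  particle molarity of the immobilized reference.
* The regression keeps a free intercept as a diagnostic (the model
  implies zero) instead of forcing the line through the origin;
  its deviation from zero is reported.
* Points where the closure degenerates ($[P]_b \le 0$, $[R]_b = 0$,
  implied amounts exceeding totals) are flagged with a reason and
  excluded, never imputed.
* The closure is an approximation; the simulator's exact two-receptor
  solver quantifies its error. When a dataset carries the exact free
  ligand (simulated data does), each point is flagged if free As(III)
  exceeds 1% of total — inside that regime the fitted ratio tracks the
  true $K_{D1}/K_{D2}$ to within about 2%, outside it the linearization
  is biased and the flags say so.

# Loading, stability and selectivity

* **Loading capacity**: bound protein regressed on particle molarity
  over the linear (sub-saturation) segment — the same selector as
  Scatchard, with `min_len = 3` since loading designs are short. The
  slope is mol protein per mol particle, i.e. molecules per particle.
* **Release fraction**: percent of initially bound protein released by
  a horizon (default 60 h), with a pass threshold (default 4%) for
  calling a conjugate stable. Bound amounts are interpolated linearly
  between measured times; an increasing series yields a negative
  release and a warning rather than silent clipping.
* **Retention**: adsorption with a competing metal over the metal-free
  control, × 100. Classification against the 95% threshold is
  inclusive, so the boundary case is deterministic. The metric is a
  ratio, so the adsorption unit (µg/g, % removal, µM bound) cancels —
  the tables only need to be internally consistent.

# The synthetic-data generator

`simulate_isotherm()`, `simulate_kinetics()` and
`simulate_competitive_series()` generate the three experiment types
from exact solvers, so every analysis route can be tested against known
ground truth:

* the 1:1 equilibrium is solved from the cancellation-free root of the
  Langmuir quadratic (conservation exact to machine precision, checked
  against an independent bisection oracle in the tests);
* the two-receptor equilibrium is solved by bisection on free ligand
  over $[0, \mathrm{As}_T]$ (the mass-balance function is strictly
  increasing), to a residual below $10^{-12}$ of total;
* kinetics come from the closed forms
  $Q_t = Q_e(1 - e^{-kt})$ and $Q_t = Q_e^2 k t/(1 + Q_e k t)$.

Measurement noise is multiplicative Gaussian applied to bound amounts
only, with free ligand recomputed as total minus bound so reported
tables always close their mass balance — this mirrors how a pelleting
assay actually propagates error into the "free" column. The default
coefficient of variation is 0.03, the order of triplicate standard
deviations in solid-phase binding assays of this kind. Negative noisy
values are clamped to zero with a warning (physical support). Seeds are
mandatory for any stochastic run and all draws happen inside
`withr::with_seed()`, so no global RNG state leaks.

What the generator does **not** emulate: site heterogeneity or
cooperativity (isotherms are exactly 1:1), correlated errors between
replicates, instrument drift, pH effects, or diffusion-limited uptake.
Passing recovery tests therefore demonstrate correctness of the
estimators in the model class, not robustness to model misspecification
on real data.

# Study designs used in the tests, and an identifiability caveat

Parameter-recovery tests use a conjugate-like truth
($K_A = 30.49\ \mathrm{µM^{-1}}$, $n = 2.80 \times 10^7$
sites/particle) and 8–36-point designs; the Monte-Carlo calibration
uses 100 seeded replicate experiments. Everything runs in seconds on
one core.

One caveat deserves emphasis. At the bench loading of 1.00 g/L the
total site capacity is $n[S] \approx 7.7$ µM while
$K_D \approx 0.033$ µM — a stoichiometric-titration regime, excellent
for counting sites but poor for estimating affinity: with
multiplicative noise on the bound amount and free ligand obtained by
subtraction, the absolute noise on the Scatchard ordinate
($\approx \mathrm{cv} \times n_{e7} \times [S] \times 10^7$, about
0.08 µM at cv = 0.03) dwarfs the intercept $K_D/n_{e7} \approx 0.012$ µM
for any choice of ligand levels. The Monte-Carlo calibration therefore
follows the standard affinity-assay design rule — dilute the receptor
until capacity is comparable to $K_D$ (0.005 g/L spheres here), span
0.25–3× capacity with 12 ligand levels, and average triplicates as in
the bench protocol. Under that design the median relative error of
$K_A$ across 100 seeded replicates is about 2–3%. Users fitting real
isotherms collected in the stoichiometric regime should expect $n$ to
be well determined and $K_A$ to carry large uncertainty; the
delta-method standard errors report exactly this.

# Numerical choices and degenerate inputs

* Root-finding is plain bisection with guaranteed brackets; robustness
  over speed at desk scale.
* The Langmuir quadratic uses the $2ac/(b + \sqrt{b^2 - 4ac})$ root
  form to avoid catastrophic cancellation at high $K_A$.
* Zero-bound points are skipped in the Scatchard transform (occupancy
  ratio undefined) with a warning; an all-zero isotherm is an error.
* A non-positive Scatchard intercept raises an affinity-undefined error
  that still reports the slope and intercept.
* Readers reject missing columns, non-numeric cells and negative
  concentrations by row, and isotherm tables must close their mass
  balance to 1% of total; exclusions anywhere in the pipeline are
  logged — silent dropping is forbidden.
* All report files are plain CSV with unit-bearing column names;
  `run_pipeline()` writes byte-identical machine-readable results for
  identical configurations.

# Limitations

The package analyses the binding chemistry as specified: single-site
1:1 adsorption, two competing receptors at most, and empirical (not
mechanistic) kinetics. Curved Scatchard plots from heterogeneous sites,
Hill cooperativity, Weber–Morris diffusion models, metal-specific
interference mechanisms and silicification chemistry are out of scope.
Cysteine annotation counts residues; it does not predict which cysteines
form a functional three-coordinate As(III) site.
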