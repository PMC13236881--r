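test_that("single equilibrium matches the golden-ratio case and limits", {
  eq <- solve_single_equilibrium(1, 1, 1)
  expect_equal(eq$M_free_uM, (sqrt(5) - 1) / 2, tolerance = 1e-12)
  expect_equal(eq$M_bound_uM, 1 - (sqrt(5) - 1) / 2, tolerance = 1e-12)

  expect_equal(as.numeric(solve_single_equilibrium(0, 3, 2)[, 2:3]), c(0, 0))

  # saturation limit: all capacity filled, the excess stays free
  sat <- solve_single_equilibrium(2, 1, 1e12)
  expect_equal(sat$M_bound_uM, 1, tolerance = 1e-9)
  expect_equal(sat$M_free_uM, 1, tolerance = 1e-9)
})

test_that("closed-form root agrees with bisection across a K_A log-grid", {
  for (KA in 10^seq(-3, 3, by = 1)) {
    for (Mt in c(0.1, 1, 10)) {
      eq <- solve_single_equilibrium(Mt, 2.5, KA)
      oracle <- langmuir_bisection_oracle(Mt, 2.5, KA)
      expect_equal(eq$M_free_uM, unname(oracle["M_free"]),
                   tolerance = 1e-10)
      # conservation is exact by construction
      expect_identical(eq$M_free_uM + eq$M_bound_uM, Mt)
    }
  }
})

test_that("bound ligand is monotone in total, affinity and capacity", {
  grid <- seq(0.1, 10, length.out = 30)
  b_tot <- solve_single_equilibrium(grid, 2, 5)$M_bound_uM
  expect_true(all(diff(b_tot) > 0))
  b_ka <- vapply(10^seq(-2, 2, 0.25),
                 function(KA) solve_single_equilibrium(3, 2, KA)$M_bound_uM,
                 numeric(1))
  expect_true(all(diff(b_ka) > 0))
  b_cap <- vapply(seq(0.5, 5, 0.5),
                  function(C) solve_single_equilibrium(3, C, 5)$M_bound_uM,
                  numeric(1))
  expect_true(all(diff(b_cap) > 0))
})

test_that("competitive equilibrium solves the symmetric case exactly", {
  eq <- solve_competitive_equilibrium(1, 1, 1, 1, 1)
  expect_equal(eq$As_free_uM, sqrt(2) - 1, tolerance = 1e-10)
  expect_equal(eq$R_bound_uM, (1 - (sqrt(2) - 1)) / 2, tolerance = 1e-10)
  expect_equal(eq$R_bound_uM, eq$P_bound_uM, tolerance = 1e-12)
})

test_that("competitive equilibrium degenerates to the single-receptor case", {
  # vanishing competitor: same root as the Langmuir solver with K_A = 1/KD1
  eq2 <- solve_competitive_equilibrium(1.7, 0.5, 1, 2.2, 1e-14)
  eq1 <- solve_single_equilibrium(1.7, 2.2, 1 / 0.5)
  expect_equal(eq2$As_free_uM, eq1$M_free_uM, tolerance = 1e-8)
  expect_equal(eq2$R_bound_uM, eq1$M_bound_uM, tolerance = 1e-8)

  z <- solve_competitive_equilibrium(0, 1, 1, 1, 1)
  expect_equal(as.numeric(z[, 2:4]), c(0, 0, 0))
})

test_that("competitive mass balance closes to the stated residual", {
  withr::with_seed(7, {
    for (i in 1:25) {
      At <- stats::runif(1, 0.01, 20)
      KD1 <- 10^stats::runif(1, -3, 1)
      KD2 <- 10^stats::runif(1, -3, 1)
      Rt <- stats::runif(1, 0.1, 10)
      Pt <- stats::runif(1, 0.1, 10)
      eq <- solve_competitive_equilibrium(At, KD1, KD2, Rt, Pt)
      resid <- eq$As_free_uM + eq$R_bound_uM + eq$P_bound_uM - At
      expect_lt(abs(resid), 1e-10 * At)
    }
  })
})

test_that("equal dissociation constants split bound ligand as R_t : P_t", {
  eq <- solve_competitive_equilibrium(2, 0.3, 0.3, 4, 1.5)
  expect_equal(eq$R_bound_uM / eq$P_bound_uM, 4 / 1.5, tolerance = 1e-10)
})

test_that("binding_params derives the site capacity from the suspension", {
  p <- conjugate_params()
  expect_equal(p$capacity_uM,
               2.80e7 * suspension_molarity(1.00, 1.657e11),
               tolerance = 1e-12)
  expect_equal(p$K_D_uM * p$K_A_per_uM, 1)
  expect_error(binding_params(-1, 1e7, sphere_suspension()),
               class = "arsbind_invalid_argument")
})
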