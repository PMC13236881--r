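test_that("mass-balance closure matches hand arithmetic", {
  d <- tibble::tibble(As_total_uM = 0.7, R_bound_uM = 0.4)
  bal <- competitive_mass_balance(d, R_total_uM = 1, P_total_uM = 1)
  expect_equal(bal$y, 1.5)          # (1 - 0.4) / 0.4
  expect_equal(bal$P_b, 0.3)
  expect_equal(bal$x, 0.7 / 0.3)    # (1 - 0.3) / 0.3
  expect_true(bal$usable)
})

test_that("degenerate points are flagged and excluded, not imputed", {
  d <- tibble::tibble(
    As_total_uM = c(0.5, 0.5, 0, 1.0),
    R_bound_uM = c(0.3, 0.5, 0, 0.2) # row 2: competitor bound nothing
  )
  expect_message(
    bal <- competitive_mass_balance(d, R_total_uM = 1, P_total_uM = 1),
    "excluded"
  )
  expect_identical(bal$usable, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(bal$exclusion_reason[2], "competitor bound nothing")

  all_bad <- tibble::tibble(As_total_uM = c(1, 2), R_bound_uM = c(1, 2))
  expect_error(
    suppressMessages(competitive_mass_balance(all_bad, 3, 3)),
    class = "arsbind_insufficient_data"
  )
})

test_that("identical affinities give unit slope and <1% deviation", {
  cp <- competitive_params(KD1_uM = 1 / 30.49, KD2_uM = 1 / 30.49,
                           R_total_uM = 7.71, P_total_uM = 7.85)
  ser <- simulate_competitive_series(cp, seq(1, 7, by = 0.5))
  bal <- competitive_mass_balance(ser)
  fit <- fit_affinity_ratio(bal)
  expect_equal(fit$ratio, 1, tolerance = 0.01)
  fa <- free_affinity(fit, 30.49)
  expect_lt(fa$deviation_pct, 1)
})

test_that("linearized ratio matches the exact oracle when free ligand is negligible", {
  # KD1/KD2 = 2 with tight binding: equilibrium free As stays below 1% of total
  cp <- competitive_params(KD1_uM = 0.04, KD2_uM = 0.02,
                           R_total_uM = 8, P_total_uM = 8)
  ser <- simulate_competitive_series(cp, seq(1, 8, by = 0.5))
  expect_true(all(ser$As_free_exact_uM < 0.01 * ser$As_total_uM))
  bal <- competitive_mass_balance(ser)
  expect_true(all(bal$free_ligand_ok))
  fit <- fit_affinity_ratio(bal)
  expect_equal(fit$ratio, 2, tolerance = 0.02)
  # diagnostic intercept should sit near the origin
  expect_lt(abs(fit$intercept), 0.05)
})

test_that("fitted ratio increases with the true ratio across a grid", {
  ratios <- c(0.1, 0.3, 1, 3, 10)
  fitted <- vapply(ratios, function(r) {
    cp <- competitive_params(KD1_uM = 0.02 * r, KD2_uM = 0.02,
                             R_total_uM = 8, P_total_uM = 8)
    ser <- simulate_competitive_series(cp, seq(1, 8, by = 0.5))
    suppressMessages(fit_affinity_ratio(competitive_mass_balance(ser)))$ratio
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("degenerate regressions fail loudly", {
  pts <- tibble::tibble(x = c(1, 1, 1), y = c(1, 2, 3), usable = TRUE)
  expect_error(fit_affinity_ratio(pts), class = "arsbind_fit_failure")
  expect_error(fit_affinity_ratio(pts[1:2, ]),
               class = "arsbind_insufficient_data")
})

test_that("free affinity scales the immobilized reference by the fitted ratio", {
  # ratio back-computed from two published-style affinities: 31.28/30.49
  fa <- free_affinity(1.0259, 30.49)
  expect_equal(fa$K_A_free_e6_per_M, 31.28, tolerance = 1e-3)
  expect_lt(fa$deviation_pct, 3)
  expect_equal(free_affinity(1, 12.3)$deviation_pct, 0)
  expect_equal(free_affinity(0.5, 10)$K_A_free_per_uM, 5)
  expect_error(free_affinity(-2, 10), class = "arsbind_invalid_argument")
})

test_that("compete_affinity composes the pipeline with a Scatchard reference", {
  p <- conjugate_params()
  iso <- simulate_isotherm(p, seq(0.5, 6, by = 0.5))
  ref <- affinity_from_isotherm(iso)

  R_total <- ref$n_sites * p$suspension$molar_conc_uM
  cp <- competitive_params(KD1_uM = 1 / ref$K_A_per_uM,
                           KD2_uM = 1 / ref$K_A_per_uM,
                           R_total_uM = R_total, P_total_uM = 7.85)
  ser <- simulate_competitive_series(cp, seq(1, 7, by = 0.5))
  fit <- compete_affinity(ser, reference = ref, suspension = p$suspension,
                          P_total_uM = 7.85)
  expect_s3_class(fit, "competitive_fit")
  expect_lt(fit$free_affinity$deviation_pct, 1)
  gl <- glance(fit)
  expect_true(all(c("ratio", "K_A_free_e6_per_M", "deviation_pct") %in% names(gl)))
})
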