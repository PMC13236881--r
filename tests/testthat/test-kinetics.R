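test_that("PFO fit recovers the rate constant of a known log-linear course", {
  # uptake constructed so that ln(Qe - Qt) = 4.38 - 0.254 t exactly
  t <- as.numeric(1:12)
  Qe <- exp(4.38)
  ds <- tibble::tibble(t_h = t, Q_ug_per_g = Qe - exp(4.38 - 0.254 * t))
  fit <- fit_pseudo_first_order(ds, Q_e = Qe)
  expect_equal(fit$k, 0.254, tolerance = 1e-10)
  expect_equal(fit$Q_e_fitted, Qe, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("PFO fit on its own generative model is exact", {
  ds <- simulate_kinetics("PFO", Q_e = 100, k = 0.2, times_h = as.numeric(1:10))
  fit <- fit_pseudo_first_order(ds, Q_e = 100)
  expect_equal(fit$k, 0.2, tolerance = 1e-8)
  expect_equal(fit$Q_e_fitted, 100, tolerance = 1e-8)
})

test_that("PFO fit drops unusable points and errors when too few remain", {
  ds <- simulate_kinetics("PFO", Q_e = 50, k = 0.5, times_h = as.numeric(1:6))
  # default Q_e is the max observed uptake, which itself must be dropped
  expect_message(fit <- fit_pseudo_first_order(ds), "dropped 1 point")
  expect_equal(fit$n_dropped, 1L)

  flat <- tibble::tibble(t_h = as.numeric(1:4), Q_ug_per_g = rep(80, 4))
  expect_error(suppressMessages(fit_pseudo_first_order(flat, Q_e = 80)),
               class = "arsbind_insufficient_data")
})

test_that("PSO fit recovers slope, intercept and parameters exactly", {
  ds <- simulate_kinetics("PSO", Q_e = 60, k = 0.02, times_h = as.numeric(1:10))
  fit <- fit_pseudo_second_order(ds)
  expect_equal(fit$slope, 1 / 60, tolerance = 1e-8)
  expect_equal(fit$intercept, 1 / (0.02 * 3600), tolerance = 1e-8)
  expect_equal(fit$Q_e_fitted, 60, tolerance = 1e-8)
  expect_equal(fit$k, 0.02, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # Q_e is the reciprocal slope by construction
  expect_identical(fit$Q_e_fitted, 1 / fit$slope)
})

test_that("a t = 0 point is excluded without changing the PSO fit", {
  t <- as.numeric(0:10)
  ds_with <- simulate_kinetics("PSO", 60, 0.02, t)
  ds_without <- simulate_kinetics("PSO", 60, 0.02, t[-1])
  expect_message(fit_w <- fit_pseudo_second_order(ds_with), "dropped 1 point")
  fit_o <- fit_pseudo_second_order(ds_without)
  expect_equal(fit_w$k, fit_o$k, tolerance = 1e-12)
  expect_equal(fit_w$Q_e_fitted, fit_o$Q_e_fitted, tolerance = 1e-12)
})

test_that("the generating model wins model selection on clean data", {
  t <- as.numeric(1:12)
  pso_ds <- simulate_kinetics("PSO", 100, 0.005, t)
  pfo_ds <- simulate_kinetics("PFO", 100, 0.25, t)

  suppressMessages({
    best_pso <- select_kinetic_model(fit_pseudo_first_order(pso_ds),
                                     fit_pseudo_second_order(pso_ds))
    best_pfo <- select_kinetic_model(fit_pseudo_first_order(pfo_ds, Q_e = 100),
                                     fit_pseudo_second_order(pfo_ds))
  })
  expect_identical(best_pso$model, "PSO")
  expect_identical(best_pfo$model, "PFO")
  expect_gt(attr(best_pso, "margin"), 0)
})

test_that("selection prefers PSO on an exact tie and handles single fits", {
  t <- as.numeric(1:10)
  pso_fit <- fit_pseudo_second_order(simulate_kinetics("PSO", 60, 0.02, t))
  pfo_fit <- fit_pseudo_first_order(simulate_kinetics("PFO", 60, 0.2, t),
                                    Q_e = 60)
  # both perfect fits: R^2 ties at 1, the chemisorption-consistent model wins
  expect_equal(pso_fit$r_squared, pfo_fit$r_squared, tolerance = 1e-12)
  expect_identical(select_kinetic_model(pfo_fit, pso_fit)$model, "PSO")
  expect_identical(select_kinetic_model(pfo_fit)$model, "PFO")
  expect_error(select_kinetic_model(), class = "arsbind_invalid_argument")
})

test_that("nonlinear refit agrees with the linearization on clean data", {
  ds <- simulate_kinetics("PSO", 80, 0.01, as.numeric(1:10))
  fit <- fit_pseudo_second_order(ds)
  diag <- refit_kinetics_nonlinear(ds, fit)
  expect_true(all(diag$rel_difference < 1e-6))
})

test_that("kinetics tables are validated", {
  expect_error(fit_pseudo_second_order(tibble::tibble(t_h = c(1, 1, 2),
                                                      Q_ug_per_g = 1:3)),
               class = "arsbind_parse_error")
  expect_error(fit_pseudo_second_order(tibble::tibble(t_h = 1:3,
                                                      Q_ug_per_g = c(-1, 1, 2))),
               class = "arsbind_parse_error")
})
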