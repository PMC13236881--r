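test_that("the Scatchard transform matches hand arithmetic", {
  # particle molarity pinned exactly so the arithmetic is checkable by hand
  s <- tibble::tibble(label = "S", molar_conc_uM = 2.753e-7)
  d <- tibble::tibble(As_free_uM = 0.5, As_bound_uM = 2.753)
  pt <- scatchard_transform(d, suspension = s)
  expect_equal(pt$mu, 1e7)
  expect_equal(pt$mu_e7, 1)
  expect_equal(pt$y_uM, 0.5)

  # doubling the particle molarity halves the occupancy
  s2 <- tibble::tibble(label = "S", molar_conc_uM = 2 * 2.753e-7)
  expect_equal(scatchard_transform(d, s2)$mu, 0.5e7)
})

test_that("zero-bound points are skipped; all-zero input errors", {
  s <- tibble::tibble(molar_conc_uM = 2.753e-7)
  d <- tibble::tibble(As_free_uM = c(0.5, 1), As_bound_uM = c(0, 1))
  expect_warning(pt <- scatchard_transform(d, s), "zero-bound")
  expect_identical(nrow(pt), 1L)
  expect_error(
    scatchard_transform(tibble::tibble(As_free_uM = 1, As_bound_uM = 0), s),
    class = "arsbind_insufficient_data"
  )
})

test_that("regression coefficients map to published-style K_A and n", {
  # exact-arithmetic worked rows: K_A = slope/intercept, n = 1e7/slope
  p1 <- scatchard_params(0.3567, 0.0117)
  expect_equal(round(p1$K_A_e6_per_M, 2), 30.49)
  expect_equal(round(p1$n_e7, 2), 2.80)
  p2 <- scatchard_params(1.2027, 1.4811)
  expect_equal(round(p2$K_A_e6_per_M, 3), 0.812)
  p3 <- scatchard_params(1, 1)
  expect_equal(p3$K_A_per_uM, 1)
  expect_equal(p3$n_sites, 1e7)
  expect_equal(p1$K_A_per_uM * p1$K_D_uM, 1)
  expect_error(scatchard_params(0.5, -0.1),
               class = "arsbind_affinity_undefined")
})

test_that("noiseless Langmuir isotherms are exactly linear in Scatchard space", {
  p <- conjugate_params()
  iso <- simulate_isotherm(p, seq(0.5, 6, by = 0.5))
  pts <- scatchard_transform(iso)
  seg <- select_linear_segment(pts$M_free_uM, pts$y_uM)
  expect_identical(seg$indices, seq_len(nrow(pts)))
  fit <- scatchard_fit(pts, seg, label = "sim")
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$K_A_per_uM, 30.49, tolerance = 1e-6)
  expect_equal(fit$n_sites, 2.80e7, tolerance = 1e-6)
})

test_that("end-to-end recovery and replicate averaging work", {
  p <- conjugate_params()
  iso <- simulate_isotherm(p, rep(seq(0.5, 6, by = 0.5), each = 2))
  fit <- affinity_from_isotherm(iso)
  expect_equal(fit$K_A_per_uM, 30.49, tolerance = 1e-6)
  expect_equal(fit$n_e7, 2.80, tolerance = 1e-6)
  expect_error(affinity_from_isotherm(iso[0, ]),
               class = "arsbind_insufficient_data")
})

test_that("the linearized estimate agrees with a direct nonlinear fit", {
  p <- conjugate_params()
  iso <- simulate_isotherm(p, seq(0.4, 8, length.out = 8))
  scat <- affinity_from_isotherm(iso)
  # independent route: nonlinear Langmuir fit of bound on free ligand
  nl <- stats::nls(
    As_bound_uM ~ C * KA * As_free_uM / (1 + KA * As_free_uM),
    data = iso, start = list(C = max(iso$As_bound_uM) * 2, KA = 1),
    control = stats::nls.control(maxiter = 500, scaleOffset = 1)
  )
  KA_nl <- unname(stats::coef(nl)["KA"])
  expect_equal(scat$K_A_per_uM, KA_nl, tolerance = 5e-3)
})

test_that("fitted parameters transform correctly under unit rescaling", {
  p <- conjugate_params()
  iso <- simulate_isotherm(p, seq(0.5, 6, by = 0.5))
  fit <- affinity_from_isotherm(iso)

  c_scale <- 10
  iso_scaled <- iso
  iso_scaled$As_total_uM <- iso$As_total_uM * c_scale
  iso_scaled$As_free_uM <- iso$As_free_uM * c_scale
  iso_scaled$As_bound_uM <- iso$As_bound_uM * c_scale
  s_scaled <- tibble::tibble(
    label = "scaled",
    molar_conc_uM = p$suspension$molar_conc_uM * c_scale
  )
  fit_scaled <- affinity_from_isotherm(iso_scaled, suspension = s_scaled)
  expect_equal(fit_scaled$n_sites, fit$n_sites, tolerance = 1e-8)
  expect_equal(fit_scaled$K_A_per_uM, fit$K_A_per_uM / c_scale,
               tolerance = 1e-8)
})

test_that("fitted capacity bounds the observed binding on clean data", {
  p <- conjugate_params()
  iso <- simulate_isotherm(p, seq(0.5, 10, by = 0.5))
  fit <- affinity_from_isotherm(iso)
  cap <- fit$n_sites * p$suspension$molar_conc_uM
  expect_gte(cap * (1 + 1e-9), max(iso$As_bound_uM))
})

test_that("seeded noisy replicates recover K_A with small median error", {
  # affinity-estimation design: capacity ~ K_D, triplicates averaged
  p <- diluted_params()
  levels <- affinity_design(p, replicates = 3)
  errs <- vapply(1:50, function(i) {
    nz <- noise_model("multiplicative-gaussian", cv = 0.03, seed = 1000 + i)
    iso <- simulate_isotherm(p, levels, noise = nz)
    fit <- tryCatch(suppressWarnings(affinity_from_isotherm(iso, r2_min = 0.9)),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    abs(fit$K_A_per_uM - 30.49) / 30.49
  }, numeric(1))
  expect_lt(stats::median(errs, na.rm = TRUE), 0.05)
})

test_that("report rows mirror the published table layout", {
  p <- conjugate_params()
  iso <- simulate_isotherm(p, seq(0.5, 6, by = 0.5))
  fit <- affinity_from_isotherm(iso, label = "S-sim")
  rep <- scatchard_report(fit)
  expect_named(rep, c("adsorbent", "scatchard_equation", "K_A_e6_per_M",
                      "K_A_sd", "n_e7", "n_e7_sd", "R2"))
  expect_match(rep$scatchard_equation, "^y = ")
  td <- tidy(fit)
  expect_identical(td$term, c("intercept", "slope", "K_A_e6_per_M", "n_e7"))
  gl <- glance(fit)
  expect_equal(gl$K_A_e6_per_M, fit$K_A_e6_per_M)
})
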