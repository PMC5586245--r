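test_that("Porod volume identity and sphere pipeline accuracy", {
  expect_equal(porod_volume(1, 2 * pi^2), 1)
  expect_equal(porod_volume(3, 2 * pi^2 * 3 / 5000), 5000)

  p <- sphere_profile(R = 30)
  pr <- ift(p, 60)
  Vp <- porod_volume(pr$I0, porod_invariant(p, pr))
  expect_equal(Vp, 4 / 3 * pi * 30^3, tolerance = 0.05)
  expect_equal(porod_invariant(p, pr), 2 * pi^2 * pr$I0 / (4 / 3 * pi * 30^3),
               tolerance = 0.02)
})

test_that("invariant integrals match the quadrature oracle on a Guinier law", {
  Rg <- 25
  q <- seq(0.004, 0.2, length.out = 300)
  I <- 2 * exp(-q^2 * Rg^2 / 3)
  p <- sas_profile(q, I, pmax(1e-4 * I, 1e-12))
  pr <- ift(p, 90)
  Qi_oracle <- stats::integrate(function(x) x^2 * 2 * exp(-x^2 * Rg^2 / 3),
                                0, 2)$value
  Vc_oracle <- 2 / stats::integrate(function(x) x * 2 * exp(-x^2 * Rg^2 / 3),
                                    0, 2)$value
  expect_equal(porod_invariant(p, pr), Qi_oracle, tolerance = 0.005)
  expect_equal(volume_of_correlation(p, pr)$Vc, Vc_oracle, tolerance = 0.005)
})

test_that("truncating q_max by half changes Qi by less than 5 percent", {
  full <- sphere_profile(R = 30)
  half <- sphere_profile(R = 30, q = seq(0.007, 0.155, length.out = 200))
  Qi_full <- porod_invariant(full, ift(full, 60))
  Qi_half <- porod_invariant(half, ift(half, 60))
  expect_lt(abs(Qi_half / Qi_full - 1), 0.05)
})

test_that("Vp error stays below 5 percent and degrades as q_max R shrinks", {
  errs <- vapply(c(60, 30, 15), function(R) {
    p <- sphere_profile(R = R)
    pr <- ift(p, 2 * R)
    abs(porod_volume(pr$I0, porod_invariant(p, pr)) / (4 / 3 * pi * R^3) - 1)
  }, numeric(1))
  expect_true(all(errs < 0.05))
  expect_gte(errs[3], max(errs[1:2]))   # shortest q_max R degrades most
})

test_that("Vp and Vc are scale invariant; mass from I(0) is not", {
  p <- sphere_profile(R = 30, noise = 1e6, seed = 5)
  pr <- ift(p, 60)
  p2 <- rescale(p, 7)
  pr2 <- ift(p2, 60)
  expect_equal(porod_volume(pr2$I0, porod_invariant(p2, pr2)),
               porod_volume(pr$I0, porod_invariant(p, pr)), tolerance = 1e-3)
  expect_equal(volume_of_correlation(p2, pr2)$Vc,
               volume_of_correlation(p, pr)$Vc, tolerance = 1e-3)
  drm <- 2.1e10
  expect_equal(mass_from_i0(7 * pr$I0, 1, drm) / mass_from_i0(pr$I0, 1, drm), 7)
})

test_that("mass from I(0) inverts exactly and requires absolute scale", {
  N_A <- 6.02214076e23
  M <- 123456
  drm <- 2.1e10
  C <- 1.5e-3                       # g/ml
  I0 <- C * drm^2 * M / N_A
  expect_equal(mass_from_i0(I0, 1.5, drm), M, tolerance = 1e-12)
  expect_error(mass_from_i0(I0, 1.5, drm, scale = "arbitrary"), "scale error")
})

test_that("truncation-corrected mass maps a sphere to V/1.5 within 10 percent", {
  p <- sphere_profile(R = 30)
  pr <- ift(p, 60)
  fm <- fischer_mass(p, pr)
  expect_equal(fm$M, (4 / 3 * pi * 30^3) / 1.5, tolerance = 0.10)
  # outside the calibration domain: nearest endpoint with a warning
  tiny <- sphere_profile(R = 30, q = seq(0.002, 0.04, length.out = 120))
  prt <- suppressWarnings(ift(tiny, 60))
  expect_warning(fischer_mass(tiny, prt), "calibration domain")
})

test_that("volume-of-correlation mass uses the class calibration", {
  p <- sphere_profile(R = 30, noise = 1e6, seed = 6)
  pr <- ift(p, 60)
  vc <- volume_of_correlation(p, pr, "protein")
  expect_equal(vc$M, (vc$Vc^2 / pr$Rg) / 0.1231, tolerance = 1e-12)
  vcn <- volume_of_correlation(p, pr, "nucleic_acid")
  expect_equal(vcn$M, (vcn$Vc^2 / pr$Rg / 0.00934)^0.808, tolerance = 1e-12)
})

test_that("mass consistency report flags Vp/M outside 1.3-1.7", {
  p <- sphere_profile(R = 30)
  pr <- ift(p, 60)
  V <- 4 / 3 * pi * 30^3
  inv_ok <- invariants_mass(p, pr, M_expected = V / 1.5)
  mc <- mass_consistency(inv_ok)
  expect_false(mc$flag_vp_over_m)
  expect_true(mc$vp_over_m >= 1.3 && mc$vp_over_m <= 1.7)
  inv_bad <- invariants_mass(p, pr, M_expected = V / 3)
  expect_true(mass_consistency(inv_bad)$flag_vp_over_m)
  # ratios equal 1 when every estimate equals the expectation
  inv_ok$M_fischer <- inv_ok$M_expected
  inv_ok$M_vc <- inv_ok$M_expected
  inv_ok$M_i0 <- inv_ok$M_expected
  mc2 <- mass_consistency(inv_ok)
  expect_equal(mc2$estimates$ratio_to_expected, rep(1, 3))
})
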