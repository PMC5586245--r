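test_that("composition arithmetic: glycine, termini, deuteration, copies", {
  g <- composition_from_sequence("G", "protein")
  expect_equal(g$mass, 75.07, tolerance = 1e-3)     # C2H5NO2 free amino acid
  expect_equal(unname(g$counts[c("C", "H", "N", "O")]), c(2, 5, 1, 2))

  # full deuteration adds 1.00628 Da per non-exchangeable H
  p0 <- composition_from_sequence(CAM_SEQ, "protein")
  p1 <- composition_from_sequence(CAM_SEQ, "protein", deuteration = 1)
  expect_equal(p1$mass - p0$mass, p0$nonexchangeable_H * 1.00628,
               tolerance = 1e-9)
  # oligomer multiplies everything
  p4 <- composition_from_sequence(CAM_SEQ, "protein", n_copies = 4)
  expect_equal(p4$mass, 4 * p0$mass)
  expect_equal(p4$labile_H, 4 * p0$labile_H)

  expect_error(composition_from_sequence("AXZ", "protein"), "unknown residue")
})

test_that("calmodulin composition reproduces the tabulated benchmarks", {
  comp <- composition_from_sequence(CAM_SEQ, "protein")
  expect_equal(comp$mass, 16842, tolerance = 0.01)      # reference tools
  expect_true(comp$vbar > 0.70 && comp$vbar < 0.74)
  expect_equal(comp$vbar, 0.716, tolerance = 0.01)
  ec <- extinction_coefficient(CAM_SEQ)
  expect_identical(c(ec$n_trp, ec$n_tyr, ec$n_cystine), c(0L, 2L, 0L))
  expect_equal(round(ec$a280_01pc, 3), 0.178)
  # poly-glycine absorbs nothing at 280 nm
  expect_equal(extinction_coefficient(strrep("G", 50))$eps_molar, 0)
})

test_that("solvent and particle scattering-length densities are sensible", {
  w <- solvent_recipe()
  expect_equal(w$rho_xray, 9.42e10, tolerance = 0.005)   # 0.334 e/A^3 * r0
  d2o <- solvent_recipe(f_d2o = 1)
  expect_equal(d2o$rho_neutron, 6.36e10, tolerance = 0.01)
  expect_equal(solvent_recipe(f_d2o = 0)$rho_neutron, -0.56e10,
               tolerance = 0.02)

  buf <- solvent_recipe(list(list(name = "MOPS", molarity = 0.025),
                             list(name = "NaCl", molarity = 0.25),
                             list(name = "KCl", molarity = 0.05),
                             list(name = "TCEP", molarity = 0.002)))
  expect_equal(buf$rho_xray, 9.52e10, tolerance = 0.005)

  comp <- composition_from_sequence(CAM_SEQ, "protein")
  ctx <- contrast_context(comp, buf, "xray")
  expect_equal(ctx$rho_particle, 12.61e10, tolerance = 0.02)
  expect_equal(ctx$delta_rho, 3.09e10, tolerance = 0.05)
  # the defining identity holds to machine precision
  expect_identical(ctx$delta_rho_M, ctx$delta_rho * ctx$vbar)
  expect_error(solvent_recipe(list(list(name = "unobtainium", molarity = 1))),
               "unknown chemical")
})

test_that("a particle matching its solvent has zero contrast", {
  comp <- composition_from_sequence(CAM_SEQ, "protein")
  # solve for the D2O fraction where the neutron contrast crosses zero,
  # then confirm the context reports (near) zero contrast there
  f_at <- function(f) {
    s <- solvent_recipe(f_d2o = f)
    contrast_context(comp, s, "neutron")$delta_rho
  }
  root <- stats::uniroot(f_at, c(0, 1))$root
  expect_lt(abs(f_at(root)) / 1e10, 1e-6)
  expect_true(root > 0.3 && root < 0.6)   # protein match point ~40-45% D2O
})

test_that("match point is recovered from a synthetic contrast series", {
  set.seed(31)
  f <- c(0, 0.2, 0.4, 0.6, 0.8, 1.0)
  drho <- 3.0 - 7.143 * f                 # zero at f = 0.42
  C <- rep(2, length(f))
  I0 <- C * drho^2 * 1e-3
  mp <- match_point(f, I0, C)
  expect_equal(mp$match_point, 0.42, tolerance = 1e-3)
  expect_false(mp$extrapolated)

  # two points symmetric about the root give the exact midpoint
  mp2 <- match_point(c(0.2, 0.6), c(1, 1), c(1, 1), sign = c(1, -1))
  expect_equal(mp2$match_point, 0.4, tolerance = 1e-12)

  # all same sign, no crossing in range: extrapolation flagged
  mp3 <- match_point(c(0, 0.2, 0.4), (3 - f[1:3])^2, rep(1, 3),
                     sign = c(1, 1, 1))
  expect_true(mp3$extrapolated)
})

test_that("Stuhrmann analysis recovers homogeneous and two-density cases", {
  # homogeneous particle: Rg independent of contrast
  drho <- c(1, 2, 4, -2, -4)
  s0 <- stuhrmann(drho, rep(25, 5))
  expect_equal(s0$Rm2, 625, tolerance = 1e-9)
  expect_equal(s0$alpha, 0, tolerance = 1e-9)
  expect_equal(s0$beta, 0, tolerance = 1e-9)

  # forward model with known coefficients
  Rm2 <- 600; al <- 40; be <- 5
  Rg2 <- Rm2 + al / drho - be / drho^2
  sf <- stuhrmann(drho, sqrt(Rg2))
  expect_equal(sf$Rm2, Rm2, tolerance = 1e-6)
  expect_equal(sf$alpha, al, tolerance = 1e-6)
  expect_equal(sf$beta, be, tolerance = 1e-6)

  # three points in beta = 0 mode interpolate exactly
  s3 <- stuhrmann(drho[1:3], sqrt(600 + 40 / drho[1:3]), beta_zero = TRUE)
  expect_equal(max(abs(s3$residuals)), 0, tolerance = 1e-9)
})

test_that("parallel-axis theorem: forward identities and inversion", {
  expect_equal(parallel_axis(20, 20, 0.5, 0), 20)
  Rs <- 15; D <- 40
  expect_equal(parallel_axis(Rs, Rs, 0.5, D)^2, Rs^2 + D^2 / 4)

  # round trip across a 5-point contrast series
  R1 <- 18; R2 <- 24; Dt <- 35
  f1 <- c(0.15, 0.3, 0.5, 0.7, 0.85)
  Rg <- vapply(f1, function(f) parallel_axis(R1, R2, f, Dt), numeric(1))
  dec <- decompose_parallel_axis(f1, Rg)
  expect_equal(dec$R1, R1, tolerance = 1e-6)
  expect_equal(dec$R2, R2, tolerance = 1e-6)
  expect_equal(dec$D, Dt, tolerance = 0.03)
})

test_that("component extraction recovers known profiles within errors", {
  set.seed(77)
  q <- seq(0.01, 0.25, length.out = 60)
  I11 <- .02 * exp(-q^2 * 18^2 / 3)
  I22 <- .03 * exp(-q^2 * 24^2 / 3)
  I12 <- 0.8 * sqrt(I11 * I22)
  drho1 <- c(3, 1.5, -0.5, -2, 2.5)
  drho2 <- c(-1, 1.2, 2.5, 0.5, -2)
  Imat <- t(vapply(seq_along(drho1), function(k)
    drho1[k]^2 * I11 + drho1[k] * drho2[k] * I12 + drho2[k]^2 * I22,
    numeric(length(q))))
  sig <- 0.01 * abs(Imat) + 1e-6
  Iobs <- Imat + rnorm(length(Imat), 0, sig)
  ex <- extract_components(Iobs, sig, drho1, drho2)
  cover <- mean(abs(ex$I11 - I11) <= 2 * ex$I11_err)
  expect_gt(cover, 0.90)
  expect_lt(ex$condition, 100)

  # one component at zero contrast throughout: its pure term is recovered
  # exactly from the reduced system, the unconstrained terms come back NA
  Iz <- t(vapply(seq_along(drho1), function(k) drho1[k]^2 * I11,
                 numeric(length(q))))
  exz <- extract_components(Iz, matrix(1e-6, 5, length(q)), drho1, rep(0, 5))
  expect_equal(exz$I11, I11, tolerance = 1e-9)
  expect_true(all(is.na(exz$I22)))

  # rank-deficient design errors out
  expect_error(extract_components(Imat, sig, rep(1, 5), rep(2, 5)),
               "rank-deficient")
  # duplicated contrast points warn but do not change the solution
  expect_warning(
    ex2 <- extract_components(rbind(Iobs, Iobs[1, ]), rbind(sig, sig[1, ]),
                              c(drho1, drho1[1]), c(drho2, drho2[1])),
    "duplicated")
})

test_that("I(0) scales with contrast squared across a series", {
  comp <- composition_from_sequence(CAM_SEQ, "protein")
  M <- comp$mass
  N_A <- 6.02214076e23
  C <- 2e-3
  fs <- c(0, 0.2, 0.8, 1)
  I0s <- vapply(fs, function(f) {
    ctx <- contrast_context(comp, solvent_recipe(f_d2o = f), "neutron")
    C * ctx$delta_rho_M^2 * M / N_A    # forward Eq. 1
  }, numeric(1))
  for (i in seq_along(fs)) {
    ctx <- contrast_context(comp, solvent_recipe(f_d2o = fs[i]), "neutron")
    expect_equal(mass_from_i0(I0s[i], C * 1000, ctx), M, tolerance = 1e-9)
  }
})
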