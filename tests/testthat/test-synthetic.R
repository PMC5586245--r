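test_that("truth records carry exact closed-form parameters", {
  sp <- synth_spec("sphere", R = 30)
  t1 <- synth_truth(synth_generate(sp))
  expect_equal(t1$Rg, sqrt(3 / 5) * 30)
  expect_equal(t1$dmax, 60)
  expect_equal(t1$volume, 4 / 3 * pi * 30^3)

  db <- synth_truth(synth_generate(synth_spec("two_sphere_dumbbell",
                                              R = 10, D = 40)))
  expect_equal(db$Rg^2, 3 / 5 * 10^2 + 40^2 / 4)   # parallel axis
  expect_equal(db$Rg, 21.448, tolerance = 1e-4)
  expect_equal(db$dmax, 60)

  el <- synth_truth(synth_generate(synth_spec("ellipsoid_of_revolution",
                                              a = 20, c = 40)))
  expect_equal(el$Rg, sqrt((2 * 400 + 1600) / 5))
  expect_equal(el$dmax, 80)
})

test_that("identical spec and seed give bit-identical output", {
  s <- synth_spec("sphere", R = 25, counts_at_qmin = 1e5, seed = 99)
  p1 <- synth_generate(s)
  p2 <- synth_generate(s)
  expect_identical(p1$intensity, p2$intensity)
  expect_identical(p1$sigma, p2$sigma)
  p3 <- synth_generate(synth_spec("sphere", R = 25, counts_at_qmin = 1e5,
                                  seed = 100))
  expect_false(identical(p1$intensity, p3$intensity))
})

test_that("noise-free output recovers truth parameters to high accuracy", {
  for (shape in c("sphere", "two_sphere_dumbbell", "debye_coil")) {
    spec <- synth_spec(shape, R = 30, D = 40, Rg = 28,
                       q = seq(0.002, 0.31, length.out = 600))
    p <- synth_generate(spec)
    t <- synth_truth(p)
    g <- guinier_fit(p, c(0, 0.5 / t$Rg))     # strict qRg <= 0.5 window
    # residual curvature beyond the Guinier term bounds the accuracy;
    # the Debye coil deviates fastest (~1%), compact shapes much less
    expect_equal(g$Rg, t$Rg, tolerance = 0.01)
    expect_equal(g$I0, t$I0, tolerance = 1e-3)
  }
})

test_that("the generated sphere obeys the Porod volume relation", {
  p <- sphere_profile(R = 30, q = seq(0.004, 0.4, length.out = 600))
  pr <- ift(p, 60)
  V <- porod_volume(pr$I0, porod_invariant(p, pr))
  expect_equal(V, synth_truth(p)$volume, tolerance = 0.02)
})

test_that("the sigma column matches the empirical replicate spread", {
  q <- seq(0.01, 0.1, length.out = 30)
  one <- synth_generate(synth_spec("sphere", R = 30, q = q,
                                   counts_at_qmin = 1e4, seed = 1))
  reps <- vapply(1:800, function(s)
    synth_generate(synth_spec("sphere", R = 30, q = q, counts_at_qmin = 1e4,
                              seed = s))$intensity[10], numeric(1))
  expect_equal(stats::sd(reps), one$sigma[10], tolerance = 0.05)
})

test_that("corruptions act as advertised", {
  q <- default_q()
  base <- synth_generate(synth_spec("sphere", R = 30, q = q))
  # solvent mismatch shifts intensities by a constant
  mm <- synth_generate(synth_spec("sphere", R = 30, q = q,
                                  mismatch_constant = 5e-4))
  expect_equal(mm$intensity - base$intensity, rep(5e-4, length(q)),
               tolerance = 1e-9)
  # hard-sphere structure factor suppresses low q
  hs <- synth_generate(synth_spec("sphere", R = 30, q = q,
                                  hard_sphere = list(phi = 0.1, Rhs = 34)))
  expect_lt(hs$intensity[1] / base$intensity[1], 0.9)
  # aggregates steepen the lowest-q region
  ag <- synth_generate(synth_spec("sphere", R = 30, q = q,
                                  aggregate = list(fraction = 0.05,
                                                   size_mult = 4)))
  expect_gt(ag$intensity[1] / ag$intensity[20],
            base$intensity[1] / base$intensity[20])
})

test_that("SEC simulation produces a consistent series and UV trace", {
  q <- seq(0.007, 0.2, length.out = 80)
  comp <- synth_spec("sphere", R = 30, I0_abs = 0.04, q = q)
  ser <- simulate_sec_run(list(comp),
                          list(list(center = 60, width = 8, peak_c = 1.5)),
                          times = seq(0, 119, 1), counts_at_qmin = 1e5,
                          epsilon = 0.8, path_cm = 0.31, delay_s = 3,
                          seed = 2)
  expect_s3_class(ser, "sas_frame_series")
  expect_length(ser, 120L)
  truth <- synth_truth(ser)
  expect_equal(max(truth$concentration), 1.5, tolerance = 1e-9)
  # A280 = eps * C * path at the shifted times
  expect_equal(max(ser$a280$values), 0.8 * 1.5 * 0.31, tolerance = 1e-9)
  expect_equal(ser$a280$times, ser$times - 3)
})
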