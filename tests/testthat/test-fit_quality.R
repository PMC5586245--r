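test_that("chi2 fit: scale closure, constants and the residual contract", {
  p <- sphere_profile(R = 30, noise = 1e6, seed = 14)
  self <- chi2_fit(p, p$intensity)
  expect_equal(self$c, 1, tolerance = 1e-12)
  expect_equal(self$chi2, 0, tolerance = 1e-12)

  double <- chi2_fit(p, 2 * p$intensity)
  expect_equal(double$c, 0.5, tolerance = 1e-12)
  expect_equal(double$chi2, 0, tolerance = 1e-12)

  # residuals are exactly [I_exp - c I_mod - b] / sigma
  model <- p$intensity * 1.3 + 2e-4
  fit <- chi2_fit(p, model, fit_constant = TRUE)
  expect_equal(fit$residuals,
               (p$intensity - fit$c * model - fit$constant) / p$sigma)
  expect_equal(fit$chi2, mean(fit$residuals^2))
  expect_identical(fit$n_par, 2L)

  # rescaling the model is absorbed by c
  f1 <- chi2_fit(p, model)
  f2 <- chi2_fit(p, 100 * model)
  expect_equal(f2$chi2, f1$chi2, tolerance = 1e-12)
  expect_equal(f2$c, f1$c / 100, tolerance = 1e-12)

  expect_error(chi2_fit(p, rep(0, length(p))), "degenerate scale")
  expect_error(chi2_fit(p, model[-1]), "grid error")
})

test_that("correctly propagated errors give reduced chi2 near one", {
  set.seed(15)
  q <- seq(0.01, 0.3, length.out = 300)
  Imod <- exp(-q^2 * 22^2 / 3)
  s <- 0.02 * Imod
  ch <- replicate(60, {
    p <- sas_profile(q, Imod + rnorm(300, 0, s), s)
    chi2_fit(p, Imod)$chi2
  })
  expect_equal(mean(ch), 1, tolerance = 0.02)
})

test_that("CORMAP statistic and exact null probabilities", {
  # all differences positive: L = n, p = 2^(1-n)
  ct <- cormap_test(2:6, rep(1, 5))
  expect_identical(ct$L, 5L)
  expect_equal(ct$p_value, 0.0625)
  expect_equal(cormap_test(1, 2)$p_value, 1)

  expect_equal(longest_run_pvalue(7, 1), 1)
  expect_equal(longest_run_pvalue(9, 9), 2^(1 - 9))

  # monotone nonincreasing in L at fixed n
  for (n in c(6, 11)) {
    ps <- vapply(1:n, function(L) longest_run_pvalue(n, L), numeric(1))
    expect_true(all(diff(ps) <= 0))
  }

  # exact agreement with exhaustive enumeration at small n
  for (n in c(3, 7, 10)) {
    expect_equal(vapply(1:n, function(L) longest_run_pvalue(n, L), numeric(1)),
                 brute_longest_run_tail(n), tolerance = 1e-12)
  }

  # ties inherit the previous sign; a leading tie counts positive
  a <- c(1, 1, 3, 3); b <- c(1, 2, 3, 1)    # signs: +(tie) - -(tie->-) +
  expect_identical(cormap_test(a, b)$L, 2L)
})

test_that("mixture weights: exact closure, boundaries, noisy recovery", {
  q <- seq(0.007, 0.31, length.out = 300)
  I1 <- synth_generate(synth_spec("sphere", R = 20, q = q))$intensity
  I2 <- synth_generate(synth_spec("sphere", R = 20 * 2^(1 / 3), q = q))$intensity

  exact <- sas_profile(q, 0.5 * I1 + 0.5 * I2, rep(1e-4, 300))
  fx <- fit_mixture(exact, cbind(I1, I2))
  expect_equal(unname(fx$weights), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(fx$chi2, 0, tolerance = 1e-8)

  pure <- sas_profile(q, I1, rep(1e-4, 300))
  fp <- fit_mixture(pure, cbind(I1, I2))
  expect_equal(unname(fp$fractions), c(1, 0), tolerance = 1e-6)

  set.seed(16)
  fr <- replicate(100, {
    I <- 0.7 * I1 + 0.3 * I2
    s <- 0.02 * I
    fit_mixture(sas_profile(q, I + rnorm(300, 0, s), s),
                cbind(I1, I2))$fractions
  })
  expect_lt(max(abs(rowMeans(fr) - c(0.7, 0.3))), 0.03)

  expect_warning(fit_mixture(pure, cbind(I1, I1 * (1 + 1e-12))),
                 "collinear")
})

test_that("model smearing: identity, width, forward-scatter conservation", {
  q <- seq(0.005, 0.3, length.out = 600)
  I <- synth_generate(synth_spec("sphere", R = 30, q = q))$intensity
  expect_identical(smear_model(q, I, sigma_q = 0), I)

  # a narrow Gaussian feature broadens to the kernel width in quadrature
  feat <- exp(-(q - 0.15)^2 / (2 * 0.004^2))
  sm <- smear_model(q, feat, sigma_q = 0.006)
  fwhm <- function(y) {
    above <- which(y >= max(y) / 2)
    diff(range(q[above]))
  }
  expected <- sqrt(0.004^2 + 0.006^2) * sqrt(8 * log(2))
  expect_equal(fwhm(sm), expected, tolerance = 0.02)

  # smearing a monotone curve preserves the forward-scatter region
  g <- exp(-q^2 * 20^2 / 3)
  gs <- smear_model(q, g, dlambda_over_lambda = 0.1)
  expect_equal(gs[1], g[1], tolerance = 0.005)
})
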