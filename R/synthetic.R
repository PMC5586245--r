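# Synthetic-data generator: orientationally averaged analytic form factors
# with realistic corruptions, plus SEC-run simulation. Provides exact ground
# truth (Rg, dmax, volume) for validating every analysis module.

# -- analytic form-factor amplitudes / intensities (normalized to 1 at q=0) --

.ff_sphere_amp <- function(q, R) {
  x <- q * R
  a <- ifelse(x < 1e-6, 1 - x^2 / 10, 3 * (sin(x) - x * cos(x)) / x^3)
  a
}

.ff_sphere <- function(q, R) .ff_sphere_amp(q, R)^2

.ff_dumbbell <- function(q, R, D) {
  # two identical spheres, centre separation D (Debye two-centre formula)
  s <- ifelse(q * D < 1e-8, 1, sin(q * D) / (q * D))
  .ff_sphere(q, R) * (1 + s) / 2
}

.ff_debye_coil <- function(q, Rg) {
  x <- (q * Rg)^2
  ifelse(x < 1e-8, 1 - x / 3, 2 * (exp(-x) + x - 1) / x^2)
}

.ff_guinier <- function(q, Rg) exp(-q^2 * Rg^2 / 3)

.ff_ellipsoid <- function(q, a, c, n_quad = 64) {
  # ellipsoid of revolution, semi-axes (a, a, c); Gauss-Legendre over cos(angle)
  gl <- .gauss_legendre(n_quad, 0, 1)
  I <- numeric(length(q))
  for (k in seq_along(gl$x)) {
    u <- gl$x[k]
    r <- sqrt(a^2 * (1 - u^2) + c^2 * u^2)
    I <- I + gl$w[k] * .ff_sphere(q, r)
  }
  I
}

.gauss_legendre <- function(n, lo, hi) {
  g <- pracma::gaussLegendre(n, lo, hi)
  list(x = g$x, w = g$w)
}

# Percus-Yevick hard-sphere structure factor (volume fraction phi, radius Rhs)
.sq_hard_sphere <- function(q, phi, Rhs) {
  x <- 2 * q * Rhs
  a <- (1 + 2 * phi)^2 / (1 - phi)^4
  b <- -6 * phi * (1 + phi / 2)^2 / (1 - phi)^4
  cc <- phi * a / 2
  small <- x < 1e-4
  G <- numeric(length(x))
  xs <- x[!small]
  G[!small] <- a * (sin(xs) - xs * cos(xs)) / xs^2 +
    b * (2 * xs * sin(xs) + (2 - xs^2) * cos(xs) - 2) / xs^3 +
    cc * (-xs^4 * cos(xs) + 4 * ((3 * xs^2 - 6) * cos(xs) +
                                 (xs^3 - 6 * xs) * sin(xs) + 6)) / xs^5
  # q -> 0 limit of the PY compressibility
  G[small] <- (a / 3 + b / 4 + cc / 6) * x[small]
  S <- 1 / (1 + 24 * phi * G / x)
  S[small] <- 1 / (1 + 24 * phi * (a / 3 + b / 4 + cc / 6))
  S
}

#' Specification of a synthetic scattering profile
#'
#' Describes an analytic monodisperse particle, its absolute-scale forward
#' scattering, the q-grid, a Poisson-derived counting-noise model and
#' optional corruptions emulating common experimental pathologies:
#' inter-particle interference (Percus-Yevick hard-sphere structure factor),
#' an additive solvent-mismatch constant, and a minor aggregate admixture.
#'
#' @param shape one of \code{"sphere"}, \code{"ellipsoid_of_revolution"},
#'   \code{"two_sphere_dumbbell"}, \code{"debye_coil"}, \code{"guinier_law"}.
#' @param R sphere / dumbbell-lobe radius, Angstrom.
#' @param a,c ellipsoid semi-axes (a, a, c), Angstrom.
#' @param D dumbbell centre-centre separation, Angstrom.
#' @param Rg radius of gyration for \code{debye_coil} / \code{guinier_law}.
#' @param I0_abs forward scattering in cm^-1 (absolute scale).
#' @param q q-grid, inverse Angstrom (default 0.007..0.31, mirroring a
#'   typical synchrotron BioSAXS range).
#' @param counts_at_qmin mean detector counts at the first q point for the
#'   Poisson-derived noise model; \code{Inf} disables noise.
#' @param seed integer; identical spec plus seed gives identical output.
#' @param hard_sphere optional list \code{(phi, Rhs)}: volume fraction and
#'   interaction radius of the Percus-Yevick structure factor.
#' @param mismatch_constant additive solvent-mismatch constant (intensity units).
#' @param aggregate optional list \code{(fraction, size_mult)}: mass fraction
#'   of an aggregate modelled as a sphere scaled in radius by
#'   \code{size_mult}; its forward scattering scales with mass.
#' @param resolution optional list \code{(sigma_q, dlambda_over_lambda)} for
#'   Gaussian smearing via \code{\link{smear_model}}.
#' @return An object of class \code{sas_synth_spec}.
#' @export
synth_spec <- function(shape = c("sphere", "ellipsoid_of_revolution",
                                 "two_sphere_dumbbell", "debye_coil",
                                 "guinier_law"),
                       R = 30, a = 20, c = 40, D = 40, Rg = 25,
                       I0_abs = 0.05,
                       q = seq(0.007, 0.31, length.out = 400),
                       counts_at_qmin = Inf, seed = 1L,
                       hard_sphere = NULL, mismatch_constant = 0,
                       aggregate = NULL, resolution = NULL) {
  shape <- match.arg(shape)
  if (!is.null(hard_sphere))
    stopifnot(hard_sphere$phi >= 0, hard_sphere$phi < 1, hard_sphere$Rhs > 0)
  if (!is.null(aggregate))
    stopifnot(aggregate$fraction >= 0, aggregate$fraction < 1,
              aggregate$size_mult > 0)
  structure(list(shape = shape, R = R, a = a, c = c, D = D, Rg = Rg,
                 I0_abs = I0_abs, q = q, counts_at_qmin = counts_at_qmin,
                 seed = as.integer(seed), hard_sphere = hard_sphere,
                 mismatch_constant = mismatch_constant,
                 aggregate = aggregate, resolution = resolution),
            class = "sas_synth_spec")
}

# exact truth record for a spec
.synth_truth <- function(spec) {
  with(spec, switch(shape,
    sphere = list(Rg = sqrt(3 / 5) * R, dmax = 2 * R,
                  volume = 4 / 3 * pi * R^3),
    ellipsoid_of_revolution = list(Rg = sqrt((2 * a^2 + c^2) / 5),
                                   dmax = 2 * max(a, c),
                                   volume = 4 / 3 * pi * a^2 * c),
    two_sphere_dumbbell = list(Rg = sqrt(3 / 5 * R^2 + D^2 / 4),
                               dmax = 2 * R + D,
                               volume = 2 * (4 / 3 * pi * R^3)),
    debye_coil = list(Rg = Rg, dmax = NA_real_, volume = NA_real_),
    guinier_law = list(Rg = Rg, dmax = NA_real_, volume = NA_real_)))
}

.synth_form <- function(spec, q) {
  with(spec, switch(spec$shape,
    sphere = .ff_sphere(q, R),
    ellipsoid_of_revolution = .ff_ellipsoid(q, a, c),
    two_sphere_dumbbell = .ff_dumbbell(q, R, D),
    debye_coil = .ff_debye_coil(q, Rg),
    guinier_law = .ff_guinier(q, Rg)))
}

#' Generate a synthetic profile with known ground truth
#'
#' Evaluates the orientationally averaged analytic intensity of the spec's
#' shape, applies the optional structure factor, aggregate admixture,
#' solvent-mismatch constant and smearing, then adds Gaussian noise with a
#' Poisson-derived standard deviation \code{sigma(q) = I(q)/sqrt(counts(q))},
#' where counts scale with intensity from \code{counts_at_qmin}. The sigma
#' column is exact (it reports the noise model, not an estimate from data).
#'
#' @param spec a \code{\link{synth_spec}}.
#' @return A \code{\link{sas_profile}} with the truth record (exact Rg, dmax,
#'   volume, I0 and the corruption settings) in \code{attr(, "truth")}.
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "sas_synth_spec"))
  q <- spec$q
  I <- spec$I0_abs * .synth_form(spec, q)
  truth <- .synth_truth(spec)
  truth$I0 <- spec$I0_abs
  if (!is.null(spec$aggregate)) {
    ag <- spec$aggregate
    R_base <- switch(spec$shape, sphere = spec$R, spec$Rg / sqrt(3 / 5))
    R_ag <- R_base * ag$size_mult
    # on a mass-concentration basis I(0) per species scales with w * M
    I0_main <- spec$I0_abs * (1 - ag$fraction)
    I0_ag <- spec$I0_abs * ag$fraction * ag$size_mult^3
    I <- I0_main * .synth_form(spec, q) + I0_ag * .ff_sphere(q, R_ag)
    truth$I0 <- I0_main + I0_ag
  }
  if (!is.null(spec$hard_sphere))
    I <- I * .sq_hard_sphere(q, spec$hard_sphere$phi, spec$hard_sphere$Rhs)
  I <- I + spec$mismatch_constant
  if (!is.null(spec$resolution)) {
    I <- smear_model(q, I,
                     sigma_q = spec$resolution$sigma_q,
                     dlambda_over_lambda = spec$resolution$dlambda_over_lambda)
  }
  if (is.finite(spec$counts_at_qmin)) {
    if (spec$counts_at_qmin <= 0) stop("counts_at_qmin must be positive")
    counts <- spec$counts_at_qmin * pmax(I, 1e-12) / max(I[1], 1e-12)
    sigma <- abs(I) / sqrt(counts)
    set.seed(spec$seed)
    I <- I + stats::rnorm(length(q), 0, sigma)
  } else {
    # noise-free: nominal 1 percent errors so weighted fits stay defined
    sigma <- pmax(abs(I) * 0.01, .Machine$double.eps)
  }
  out <- sas_profile(q, I, sigma, scale = "absolute",
                     calibration = "synthetic absolute scale")
  attr(out, "truth") <- truth
  out
}

#' Ground-truth record of a synthetic profile or SEC run
#' @param x object returned by \code{\link{synth_generate}} or
#'   \code{\link{simulate_sec_run}}.
#' @export
synth_truth <- function(x) attr(x, "truth")

#' Simulate a SEC-SAS run
#'
#' Builds a time-ordered frame series: per-frame concentrations follow
#' Gaussian elution profiles, each frame is the solvent baseline plus the
#' concentration-scaled component intensities with counting noise, and a UV
#' absorbance trace is produced from the extinction coefficients with a
#' transit delay between the UV cell and the scattering cell.
#'
#' @param components list of \code{\link{synth_spec}} objects; \code{I0_abs}
#'   is interpreted as forward scattering per 1 mg/ml of the component.
#' @param elution list (one per component) of \code{(center, width, peak_c)}:
#'   elution-peak centre and Gaussian width in seconds, peak concentration
#'   in mg/ml.
#' @param times frame acquisition times, seconds (strictly increasing).
#' @param baseline_level flat solvent scattering level (intensity units).
#' @param baseline_drift linear drift of the solvent level per second
#'   (emulates an unstable solvent background).
#' @param drift_window time window \code{c(start, end)} in seconds over
#'   which the drift accumulates (default the whole run); lets a drift be
#'   injected only after (or only before) the elution peak.
#' @param counts_at_qmin noise level as in \code{\link{synth_generate}},
#'   referenced to the peak-frame intensity.
#' @param epsilon extinction coefficients (A280, 0.1 percent w/v) per component.
#' @param path_cm UV cell path length, cm.
#' @param delay_s UV-to-SAS transit delay, seconds.
#' @param seed integer seed.
#' @return A \code{\link{sas_frame_series}} with the truth record (per-frame
#'   concentrations, baseline profiles, component parameters) attached.
#' @export
simulate_sec_run <- function(components, elution,
                             times = seq(0, 119, by = 1),
                             baseline_level = 0.02, baseline_drift = 0,
                             drift_window = c(-Inf, Inf),
                             counts_at_qmin = 1e5,
                             epsilon = rep(1, length(components)),
                             path_cm = 0.31, delay_s = 0, seed = 1L) {
  stopifnot(length(components) == length(elution),
            length(epsilon) == length(components))
  q <- components[[1]]$q
  for (cmp in components) stopifnot(identical(cmp$q, q))
  nf <- length(times)
  conc <- sapply(seq_along(components), function(k) {
    e <- elution[[k]]
    e$peak_c * exp(-(times - e$center)^2 / (2 * e$width^2))
  })
  conc <- matrix(conc, nrow = nf)
  t_eff <- pmin(pmax(times, drift_window[1]), drift_window[2])
  base_levels <- baseline_level +
    baseline_drift * (t_eff - max(drift_window[1], min(times)))
  forms <- lapply(components, function(cmp) {
    I <- cmp$I0_abs * .synth_form(cmp, q)
    if (!is.null(cmp$hard_sphere)) {
      # structure-factor strength scales with concentration at generation time
      attr(I, "hs") <- cmp$hard_sphere
    }
    I
  })
  I_peak <- max(base_levels) + max(rowSums(conc)) * max(vapply(forms, max, 0))
  set.seed(seed)
  frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    I <- rep(base_levels[i], length(q))
    for (k in seq_along(forms)) {
      Ik <- conc[i, k] * forms[[k]]
      hs <- attr(forms[[k]], "hs")
      if (!is.null(hs) && conc[i, k] > 0) {
        phi_i <- hs$phi * conc[i, k] / max(conc[, k])
        Ik <- Ik * .sq_hard_sphere(q, phi_i, hs$Rhs)
      }
      I <- I + Ik
    }
    counts <- counts_at_qmin * pmax(I, 1e-12) / I_peak
    sigma <- abs(I) / sqrt(counts)
    In <- I + stats::rnorm(length(q), 0, sigma)
    frames[[i]] <- sas_profile(q, In, sigma, scale = "absolute",
                               calibration = "synthetic absolute scale")
  }
  a280_times <- times
  a280 <- as.numeric(conc %*% (epsilon)) * path_cm
  series <- sas_frame_series(frames, times,
                             a280 = list(times = a280_times - delay_s,
                                         values = a280),
                             alignment = delay_s)
  attr(series, "truth") <- list(concentration = conc, times = times,
                                baseline = base_levels,
                                epsilon = epsilon, path_cm = path_cm,
                                delay_s = delay_s)
  series
}
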