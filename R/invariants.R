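# Scattering invariants (Porod invariant Q_i, Porod volume V_P, volume of
# correlation V_c) and the battery of molecular-mass estimates.
#
# All semi-infinite q-integrals use the same extrapolation scheme: the
# Guinier curve (from the P(r)-derived Rg and I0) from 0 to the first
# measured point, the regularized back-transform I_reg over the measured
# range, and a high-q completion chosen by the local decay of the
# regularized curve at q_max:
#   - when the curve there falls faster than q^-6 (a band-complete profile
#     such as the Guinier law, where the truncated mass is negligible), an
#     analytic tail continuing the power law fitted to the last 10 percent
#     of the curve;
#   - otherwise (a compact particle measured to moderate q_max * R, where
#     a tail fitted on form-factor fringes is badly biased), the integral
#     is divided by the sphere-calibrated truncation completeness at
#     x = q_max * Rg / sqrt(3/5), the same correction philosophy as
#     forcing the high-q data to the expected q^-4 dependence.

.q_integral <- function(q, I_reg, Rg, I0, power, use_tail = TRUE) {
  # low-q extension: Guinier law on a fine grid from 0 to q[1]
  ql <- seq(0, q[1], length.out = 200)
  Il <- I0 * exp(-ql^2 * Rg^2 / 3)
  low <- .trapz(ql, ql^power * Il)
  mid <- .trapz(q, q^power * I_reg)
  if (!use_tail) return(low + mid)
  n <- length(q)
  win <- q >= 0.85 * q[n]
  Iw <- I_reg[win]
  # fringes of a compact particle: the regularized curve oscillates (or
  # crosses zero) near q_max, so a fitted q^-4 tail would be phase-biased
  dI <- diff(Iw)
  dI[abs(dI) < 1e-3 * max(abs(Iw))] <- 0
  ds <- sign(dI)[sign(dI) != 0]
  oscillatory <- any(Iw <= 0) || (length(ds) > 1 && any(diff(ds) != 0))
  sel <- win & I_reg > 0
  # local log-slope of the regularized curve near q_max
  s_loc <- if (sum(sel) >= 3)
    stats::coef(stats::lm(log(I_reg[sel]) ~ log(q[sel])))[[2]]
  else -Inf
  if (!oscillatory && s_loc < -6) {
    # band-complete curve: extend by the locally fitted power law
    # int_{qmax}^inf q^p I(qmax) (q/qmax)^s dq, convergent since s < -6
    Iq <- I_reg[n]
    if (Iq < 0) {
      warning("negative tail intensity; tail contribution set to 0")
      tail <- 0
    } else {
      tail <- Iq * q[n]^(power + 1) / (-s_loc - power - 1)
    }
    return(low + mid + tail)
  }
  tab <- .read_table_file("porod_truncation_synthetic.csv")
  col <- if (power == 2) "completeness_q2" else "completeness_q1"
  x <- q[n] * Rg / sqrt(3 / 5)
  x <- min(max(x, min(tab$x_trunc)), max(tab$x_trunc))
  compl <- stats::approx(tab$x_trunc, tab[[col]], xout = x)$y
  (low + mid) / compl
}

#' Porod invariant
#'
#' \eqn{Q_i = \int_0^\infty q^2 I(q) dq}, estimated from the regularized
#' scattering curve with Guinier extrapolation below the measured range and
#' an analytic \code{K/q^4} tail above it (fitted to the last 10 percent of
#' the regularized curve; a negative tail coefficient raises a warning and
#' the tail is set to zero).
#'
#' @param profile a \code{\link{sas_profile}} (supplies the raw data when
#'   \code{use_raw = TRUE}).
#' @param pr the \code{\link{ift}} result for the same profile (supplies the
#'   regularized curve and the derived Rg and I0).
#' @param use_raw integrate the raw data instead of the regularized curve
#'   (sensitivity check; default \code{FALSE}).
#' @return Q_i in intensity units times inverse cubic Angstrom.
#' @export
porod_invariant <- function(profile, pr, use_raw = FALSE) {
  stopifnot(inherits(pr, "sas_pr"))
  I_use <- if (use_raw) profile$intensity else pr$I_reg
  .q_integral(pr$q, I_use, pr$Rg, pr$I0, power = 2)
}

#' Porod volume
#'
#' \eqn{V_P = 2\pi^2 I(0) / Q_i}: the particle volume of a uniform-density
#' scatterer with a well-defined boundary.
#'
#' @param I0 forward scattering.
#' @param Qi Porod invariant in matching units.
#' @export
porod_volume <- function(I0, Qi) {
  stopifnot(I0 > 0, Qi > 0)
  2 * pi^2 * I0 / Qi
}

#' Truncation-corrected Porod volume and mass
#'
#' Molecular-mass estimate from the Porod volume computed over the finite
#' measured q range, in the spirit of Fischer et al. (2010): the apparent
#' volume (Guinier-extended integral up to \code{q_max}, no tail term) is
#' corrected for the known truncation bias and mapped to mass. The packaged
#' correction table is a synthetic calibration computed from the closed-form
#' sphere form factor (see \code{inst/extdata/porod_truncation_synthetic.csv});
#' the mapping to mass uses the dry protein volume (partial specific volume
#' 0.73 cm^3/g, i.e. mass density 1.37 g/cm^3).
#'
#' @param profile a \code{\link{sas_profile}}.
#' @param pr the matching \code{\link{ift}} result.
#' @param qmax upper integration limit (default: last measured q).
#' @return list with \code{V_apparent}, \code{V_corrected} (both cubic
#'   Angstrom), \code{M} (Da) and the truncation coordinate \code{x_trunc}.
#' @export
fischer_mass <- function(profile, pr, qmax = max(profile$q)) {
  stopifnot(inherits(pr, "sas_pr"))
  sel <- pr$q <= qmax + 1e-12
  Qi_trunc <- .q_integral(pr$q[sel], pr$I_reg[sel], pr$Rg, pr$I0,
                          power = 2, use_tail = FALSE)
  V_app <- porod_volume(pr$I0, Qi_trunc)
  tab <- .read_table_file("porod_truncation_synthetic.csv")
  R_equiv <- pr$Rg / sqrt(3 / 5)
  x <- qmax * R_equiv
  if (x < min(tab$x_trunc) || x > max(tab$x_trunc)) {
    warning("q_max * R outside the calibration domain; using nearest endpoint")
    x <- min(max(x, min(tab$x_trunc)), max(tab$x_trunc))
  }
  completeness <- stats::approx(tab$x_trunc, tab$completeness_q2, xout = x)$y
  # dry-volume over Porod rule-of-thumb volume: (0.73 / 0.6022) / 1.50
  porod_to_dry <- (0.73 / 0.60221) / 1.50
  V_corr <- V_app * completeness * porod_to_dry
  M <- V_corr / (0.73 / 0.60221)   # dry volume (A^3) to Da at vbar 0.73
  list(V_apparent = V_app, V_corrected = V_corr, M = M, x_trunc = x,
       completeness = completeness)
}

#' Volume of correlation and derived mass
#'
#' \eqn{V_c = I(0) / \int_0^\infty q I(q) dq}, an invariant that does not
#' rest on the Porod \code{q^-4} assumption and therefore applies to both
#' compact and flexible particles. Mass follows from the empirical power law
#' \code{M = (V_c^2 / Rg / coefficient)^exponent} with class-specific
#' constants (packaged with their citation).
#'
#' @param profile a \code{\link{sas_profile}}.
#' @param pr the matching \code{\link{ift}} result.
#' @param molecule_class \code{"protein"} or \code{"nucleic_acid"}.
#' @param use_raw integrate the raw data instead of the regularized curve.
#' @return list with \code{Vc} (square Angstrom), \code{QR = Vc^2/Rg} and
#'   \code{M} (Da).
#' @export
volume_of_correlation <- function(profile, pr,
                                  molecule_class = c("protein", "nucleic_acid"),
                                  use_raw = FALSE) {
  molecule_class <- match.arg(molecule_class)
  stopifnot(inherits(pr, "sas_pr"))
  I_use <- if (use_raw) profile$intensity else pr$I_reg
  denom <- .q_integral(pr$q, I_use, pr$Rg, pr$I0, power = 1)
  Vc <- pr$I0 / denom
  tab <- .read_table_file("vc_mass_calibration.csv")
  row <- tab[tab$class == molecule_class, ]
  QR <- Vc^2 / pr$Rg
  M <- (QR / row$coefficient)^row$exponent
  list(Vc = Vc, QR = QR, M = M, molecule_class = molecule_class)
}

#' Molecular mass from absolute-scale forward scattering
#'
#' \eqn{M = I(0) N_A / (C \Delta\rho_M^2)} with \code{I(0)} in cm^-1 on an
#' absolute scale, concentration in g/ml and the scattering mass contrast
#' \eqn{\Delta\rho_M = \Delta\bar\rho \, \bar v} in cm/g from the particle
#' composition and solvent (see \code{\link{contrast_context}}).
#'
#' @param I0 forward scattering, cm^-1 (absolute scale).
#' @param conc_mg_ml concentration in mg/ml (converted to g/ml internally).
#' @param contrast a \code{\link{contrast_context}} (supplies
#'   \code{delta_rho_M}), or a bare numeric \code{delta_rho_M} in cm/g.
#' @param scale declared intensity scale; anything other than
#'   \code{"absolute"} is an error, since the formula is meaningless on an
#'   arbitrary scale.
#' @return mass in Da.
#' @export
mass_from_i0 <- function(I0, conc_mg_ml, contrast, scale = "absolute") {
  if (!identical(scale, "absolute"))
    stop("scale error: mass from I(0) requires absolute-scaled intensities")
  stopifnot(I0 > 0, conc_mg_ml > 0)
  drm <- if (inherits(contrast, "sas_contrast")) contrast$delta_rho_M
         else as.numeric(contrast)
  N_A <- 6.02214076e23
  C <- conc_mg_ml / 1000   # g/ml
  I0 * N_A / (C * drm^2)
}

#' Assemble the invariant battery for one profile
#'
#' Convenience wrapper computing Q_i, V_P, the truncation-corrected volume
#' and mass, V_c and its mass, and (when concentration and contrast are
#' available) the absolute-scale mass from I(0), plus ratios to the expected
#' composition mass.
#'
#' @param profile a \code{\link{sas_profile}}.
#' @param pr the matching \code{\link{ift}} result.
#' @param conc_mg_ml optional concentration (mg/ml) for the I(0) mass.
#' @param contrast optional \code{\link{contrast_context}}.
#' @param M_expected optional expected mass from composition, Da.
#' @param molecule_class passed to \code{\link{volume_of_correlation}}.
#' @return An object of class \code{sas_invariants}.
#' @export
invariants_mass <- function(profile, pr, conc_mg_ml = NULL, contrast = NULL,
                            M_expected = NULL,
                            molecule_class = "protein") {
  Qi <- porod_invariant(profile, pr)
  Vp <- porod_volume(pr$I0, Qi)
  fis <- fischer_mass(profile, pr)
  vc <- volume_of_correlation(profile, pr, molecule_class)
  M_i0 <- if (!is.null(conc_mg_ml) && !is.null(contrast) &&
              profile$scale == "absolute")
    mass_from_i0(pr$I0, conc_mg_ml, contrast) else NA_real_
  out <- list(Qi = Qi, Vp = Vp,
              Vp_fischer = fis$V_corrected, M_fischer = fis$M,
              Vc = vc$Vc, M_vc = vc$M, M_i0 = M_i0,
              M_expected = if (is.null(M_expected)) NA_real_ else M_expected)
  if (is.finite(out$M_expected)) {
    out$ratios <- c(fischer = out$M_fischer, vc = out$M_vc,
                    i0 = out$M_i0) / out$M_expected
    out$vp_over_m <- out$Vp / out$M_expected
  } else {
    out$ratios <- NULL
    out$vp_over_m <- NA_real_
  }
  structure(out, class = "sas_invariants")
}

#' Cross-method mass consistency report
#'
#' Tabulates every available mass estimate with its ratio to the expected
#' composition mass and checks the rule of thumb that the Porod volume to
#' mass ratio for folded proteins is about 1.45-1.50 cubic Angstrom per Da,
#' flagging values outside \code{[1.3, 1.7]}.
#'
#' @param inv a \code{\link{invariants_mass}} result.
#' @param vp_over_m_window acceptance window for V_P/M (default
#'   \code{c(1.3, 1.7)}).
#' @return list with the estimates table and flags.
#' @export
mass_consistency <- function(inv, vp_over_m_window = c(1.3, 1.7)) {
  stopifnot(inherits(inv, "sas_invariants"))
  est <- data.frame(
    method = c("I(0), absolute scale", "truncation-corrected Porod",
               "volume of correlation"),
    M = c(inv$M_i0, inv$M_fischer, inv$M_vc))
  est$ratio_to_expected <- if (is.finite(inv$M_expected))
    est$M / inv$M_expected else NA_real_
  flag <- is.finite(inv$vp_over_m) &&
    (inv$vp_over_m < vp_over_m_window[1] || inv$vp_over_m > vp_over_m_window[2])
  list(estimates = est, vp_over_m = inv$vp_over_m,
       flag_vp_over_m = flag, window = vp_over_m_window)
}

#' @export
print.sas_invariants <- function(x, ...) {
  cat(sprintf("Qi = %.4g, Vp = %.5g A^3, Vc = %.5g A^2\n", x$Qi, x$Vp, x$Vc))
  cat(sprintf("M estimates (Da): Fischer %.4g, Vc %.4g, I(0) %.4g; expected %.4g\n",
              x$M_fischer, x$M_vc, x$M_i0, x$M_expected))
  if (is.finite(x$vp_over_m))
    cat(sprintf("Vp/M = %.3g A^3/Da\n", x$vp_over_m))
  invisible(x)
}
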