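# Composition-based scattering-length densities, contrasts and SANS
# contrast-variation analysis (match point, Stuhrmann plot, parallel-axis
# decomposition, component extraction).
#
# r0 is the scattering length of an electron, 2.8179e-13 cm.

.R0_CM <- 2.8179e-13
.N_A <- 6.02214076e23
.D_MINUS_H <- 1.00628   # isotope mass increment per exchanged H -> 2H

.atoms_table <- function() .read_table_file("atoms.csv")

# parse a chemical formula like "C7H15NO4S" into a named count vector
.parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula))
    stop("cannot parse chemical formula: ", formula)
  counts <- c()
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

.formula_props <- function(counts) {
  at <- .atoms_table()
  unknown <- setdiff(names(counts), at$element)
  if (length(unknown)) stop("unknown element(s): ", paste(unknown, collapse = ", "))
  idx <- match(names(counts), at$element)
  list(mass = sum(counts * at$mass[idx]),
       electrons = sum(counts * at$electrons[idx]),
       b_fm = sum(counts * at$b_coh_fm[idx]),
       n_H = sum(counts[names(counts) == "H"]))
}

#' Elemental composition from a biomolecular sequence
#'
#' Tallies elements, exchangeable (labile) hydrogens, mass, electrons and
#' volume for a protein or nucleic-acid chain from per-residue tables, with
#' optional oligomeric copies, deuteration of non-exchangeable hydrogens and
#' extra formula units (tags, ligands, cofactors). One water is added per
#' chain for the termini.
#'
#' @param sequence one-letter residue string (whitespace ignored).
#' @param kind \code{"protein"}, \code{"dna"} or \code{"rna"}.
#' @param n_copies oligomeric multiplier (default 1).
#' @param deuteration fraction of non-exchangeable hydrogens replaced by 2H,
#'   in [0, 1].
#' @param mods optional list of extra units, each
#'   \code{list(formula =, count =, volume_A3 =)}.
#' @return An object of class \code{sas_composition} with fields
#'   \code{counts} (elements), \code{mass} (Da), \code{electrons},
#'   \code{b_fm} (coherent neutron scattering length at 0 percent exchange,
#'   fm), \code{labile_H}, \code{nonexchangeable_H}, \code{volume_A3},
#'   \code{vbar} (cm^3/g), \code{deuteration}, \code{n_residues}.
#' @export
composition_from_sequence <- function(sequence,
                                      kind = c("protein", "dna", "rna"),
                                      n_copies = 1L, deuteration = 0,
                                      mods = NULL) {
  kind <- match.arg(kind)
  stopifnot(deuteration >= 0, deuteration <= 1, n_copies >= 1)
  seqc <- strsplit(gsub("\\s", "", toupper(sequence)), "")[[1]]
  if (kind == "protein") {
    tab <- .read_table_file("residues_protein.csv")
    elems <- c("C", "H", "N", "O", "S")
  } else {
    tabn <- .read_table_file("residues_nucleic.csv")
    tab <- tabn[tabn$kind == kind, ]
    elems <- c("C", "H", "N", "O", "P")
  }
  idx <- match(seqc, tab$letter)
  if (anyNA(idx))
    stop("unknown residue letter(s): ",
         paste(unique(seqc[is.na(idx)]), collapse = ", "))
  counts <- vapply(elems, function(e) sum(tab[[e]][idx]), numeric(1))
  # chain termini: one water per chain; its two H plus the extra N-terminal
  # amine H (protein) are exchangeable
  counts["H"] <- counts["H"] + 2
  counts["O"] <- counts["O"] + 1
  labile <- sum(tab$labile_h[idx]) + 2
  volume <- sum(tab$volume_A3[idx]) + 29.9
  counts <- counts * n_copies
  labile <- labile * n_copies
  volume <- volume * n_copies
  if (!is.null(mods)) {
    for (md in mods) {
      cnt <- if (is.null(md$count)) 1L else md$count
      fc <- .parse_formula(md$formula) * cnt
      for (el in names(fc))
        counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) + fc[[el]]
      if (!is.null(md$volume_A3)) volume <- volume + md$volume_A3 * cnt
    }
  }
  props <- .formula_props(counts)
  nonexch <- props$n_H - labile
  mass <- props$mass + deuteration * nonexch * .D_MINUS_H
  at <- .atoms_table()
  b_D <- at$b_coh_fm[at$element == "D"]
  b_H <- at$b_coh_fm[at$element == "H"]
  b_fm <- props$b_fm + deuteration * nonexch * (b_D - b_H)
  structure(list(counts = counts, mass = mass, electrons = props$electrons,
                 b_fm = b_fm, labile_H = labile,
                 nonexchangeable_H = nonexch, volume_A3 = volume,
                 vbar = volume * 0.60221 / mass,
                 deuteration = deuteration, n_residues = length(seqc),
                 n_copies = n_copies, kind = kind),
            class = "sas_composition")
}

#' @export
print.sas_composition <- function(x, ...) {
  cat(sprintf("<sas_composition> %s, %d residues x %d copies\n",
              x$kind, x$n_residues, x$n_copies))
  cat(sprintf("  M = %.1f Da, volume = %.0f A^3, vbar = %.3f cm^3/g\n",
              x$mass, x$volume_A3, x$vbar))
  cat(sprintf("  labile H = %d of %d; deuteration of non-exchangeable H = %.2f\n",
              as.integer(x$labile_H), as.integer(x$labile_H + x$nonexchangeable_H),
              x$deuteration))
  invisible(x)
}

#' Solvent scattering-length densities from a molar recipe
#'
#' Computes X-ray and neutron scattering-length densities of an aqueous
#' solvent described as molarities of named chemicals (built-in table, or
#' user-supplied formula and partial molar volume). Water fills the volume
#' not occupied by solutes; the 2H2O fraction \code{f_d2o} substitutes water
#' hydrogens for the neutron density.
#'
#' @param chemicals list of components, each \code{list(name =, molarity =)}
#'   optionally with \code{formula} and \code{molar_volume_cm3} overriding
#'   the built-in table.
#' @param f_d2o solvent 2H2O fraction in [0, 1] (neutron probe).
#' @return An object of class \code{sas_solvent} with \code{rho_xray} and
#'   \code{rho_neutron} in cm^-2 and the electron density in e/A^3.
#' @export
solvent_recipe <- function(chemicals = list(), f_d2o = 0) {
  stopifnot(f_d2o >= 0, f_d2o <= 1)
  builtin <- .read_table_file("solvent_chemicals.csv")
  at <- .atoms_table()
  bH <- at$b_coh_fm[at$element == "H"]; bD <- at$b_coh_fm[at$element == "D"]
  bO <- at$b_coh_fm[at$element == "O"]
  vol_solutes <- 0; e_solutes <- 0; b_solutes <- 0   # per litre (mol-scaled)
  for (ch in chemicals) {
    row <- builtin[builtin$name == ch$name, ]
    formula <- if (!is.null(ch$formula)) ch$formula
               else if (nrow(row)) row$formula
               else stop("unknown chemical '", ch$name,
                         "': supply formula and molar_volume_cm3")
    vmol <- if (!is.null(ch$molar_volume_cm3)) ch$molar_volume_cm3
            else row$molar_volume_cm3
    props <- .formula_props(.parse_formula(formula))
    vol_solutes <- vol_solutes + ch$molarity * vmol
    e_solutes <- e_solutes + ch$molarity * props$electrons
    b_solutes <- b_solutes + ch$molarity * props$b_fm
  }
  water_cm3 <- 1000 - vol_solutes            # per litre
  water_mol <- water_cm3 * 0.99705 / 18.0153
  e_per_l <- water_mol * 10 + e_solutes
  b_water <- bO + 2 * ((1 - f_d2o) * bH + f_d2o * bD)   # fm per molecule
  b_per_l <- water_mol * b_water + b_solutes            # mol fm / l
  e_density_A3 <- e_per_l * .N_A / 1e27                 # e per A^3
  rho_xray <- e_per_l * .N_A / 1000 * .R0_CM            # cm^-2
  rho_neutron <- b_per_l * .N_A / 1000 * 1e-13          # fm->cm, per cm^3
  structure(list(rho_xray = rho_xray, rho_neutron = rho_neutron,
                 e_density_A3 = e_density_A3, f_d2o = f_d2o,
                 chemicals = chemicals),
            class = "sas_solvent")
}

#' Contrast context for a particle in a solvent
#'
#' Derives particle and solvent scattering-length densities, the mean
#' contrast \eqn{\Delta\bar\rho}, the partial specific volume \eqn{\bar v}
#' and the scattering mass contrast \eqn{\Delta\rho_M = \Delta\bar\rho\,\bar v}
#' used in the absolute-scale mass formula. For X-rays the particle density
#' is \code{r0} times electrons per dry volume; for neutrons labile
#' hydrogens exchange with the solvent in proportion to \code{f_d2o} times
#' an exchange-completeness factor.
#'
#' @param comp a \code{\link{composition_from_sequence}} result.
#' @param solvent a \code{\link{solvent_recipe}} result.
#' @param probe \code{"xray"} or \code{"neutron"}.
#' @param exchange_completeness fraction of labile hydrogens that actually
#'   exchange (default 0.9; buried amides exchange slowly).
#' @param vbar optional override of the composition-derived partial
#'   specific volume, cm^3/g (for proteins typically 0.70-0.74).
#' @return An object of class \code{sas_contrast} with \code{rho_particle},
#'   \code{rho_solvent}, \code{delta_rho} (all cm^-2), \code{vbar}
#'   (cm^3/g) and \code{delta_rho_M} (cm/g, equal to
#'   \code{delta_rho * vbar} by construction).
#' @export
contrast_context <- function(comp, solvent, probe = c("xray", "neutron"),
                             exchange_completeness = 0.9, vbar = NULL) {
  probe <- match.arg(probe)
  stopifnot(inherits(comp, "sas_composition"), inherits(solvent, "sas_solvent"))
  V_cm3 <- comp$volume_A3 * 1e-24
  if (probe == "xray") {
    rho_p <- comp$electrons * .R0_CM / V_cm3
  } else {
    at <- .atoms_table()
    bD <- at$b_coh_fm[at$element == "D"]; bH <- at$b_coh_fm[at$element == "H"]
    n_exch <- comp$labile_H * exchange_completeness * solvent$f_d2o
    b <- comp$b_fm + n_exch * (bD - bH)
    rho_p <- b * 1e-13 / V_cm3
  }
  rho_s <- if (probe == "xray") solvent$rho_xray else solvent$rho_neutron
  vb <- if (is.null(vbar)) comp$vbar else vbar
  if (comp$kind == "protein" && (vb < 0.70 || vb > 0.74))
    warning(sprintf("vbar = %.3f cm^3/g outside the usual protein range 0.70-0.74", vb))
  delta <- rho_p - rho_s
  structure(list(rho_particle = rho_p, rho_solvent = rho_s,
                 delta_rho = delta, vbar = vb,
                 delta_rho_M = delta * vb, probe = probe,
                 f_d2o = solvent$f_d2o,
                 exchange_completeness = exchange_completeness),
            class = "sas_contrast")
}

#' @export
print.sas_contrast <- function(x, ...) {
  cat(sprintf("<sas_contrast> %s: rho_p = %.4g, rho_s = %.4g, delta_rho = %.4g (1e10 cm^-2)\n",
              x$probe, x$rho_particle / 1e10, x$rho_solvent / 1e10,
              x$delta_rho / 1e10))
  cat(sprintf("  vbar = %.3f cm^3/g, delta_rho_M = %.4g cm/g\n",
              x$vbar, x$delta_rho_M))
  invisible(x)
}

#' Extinction coefficient at 280 nm from sequence
#'
#' Gill & von Hippel style estimate:
#' \code{eps = 5500 nW + 1490 nY + 125 n_cystine} (per M per cm), also
#' expressed per 0.1 percent w/v (1 mg/ml), the convention of UV-based
#' concentration determination.
#'
#' @param sequence protein one-letter sequence.
#' @param cys \code{"oxidized"} (all Cys paired as cystines, default) or
#'   \code{"reduced"} (no cystine contribution).
#' @return list with \code{eps_molar} (M^-1 cm^-1), \code{a280_01pc}
#'   (absorbance of a 1 mg/ml solution, 1 cm path) and \code{mass}.
#' @export
extinction_coefficient <- function(sequence, cys = c("oxidized", "reduced")) {
  cys <- match.arg(cys)
  seqc <- strsplit(gsub("\\s", "", toupper(sequence)), "")[[1]]
  nW <- sum(seqc == "W"); nY <- sum(seqc == "Y"); nC <- sum(seqc == "C")
  n_cystine <- if (cys == "oxidized") floor(nC / 2) else 0
  n_cystine <- as.integer(n_cystine)
  eps <- 5500 * nW + 1490 * nY + 125 * n_cystine
  M <- composition_from_sequence(sequence, "protein")$mass
  list(eps_molar = eps, a280_01pc = eps / M, mass = M,
       n_trp = nW, n_tyr = nY, n_cystine = n_cystine)
}

#' Solvent match point from a contrast series
#'
#' Fits signed square roots of \code{I(0)/C} linearly against the solvent
#' 2H2O fraction (or solvent scattering density); the root of the line is
#' the match point where the mean particle contrast vanishes. Signs are
#' taken from the supplied contrasts when available, otherwise the split
#' maximizing the linear fit is chosen.
#'
#' @param x abscissa per contrast point: f_d2o (or solvent density).
#' @param I0 forward scattering per point.
#' @param C concentration per point (same units throughout).
#' @param sign optional +/-1 vector assigning the branch of the square root
#'   (e.g. \code{sign(delta_rho)}).
#' @return list with \code{match_point}, \code{match_point_err}, the fit and
#'   a flag when the root lies outside the measured range (extrapolation).
#' @export
match_point <- function(x, I0, C, sign = NULL) {
  stopifnot(length(x) == length(I0), length(I0) == length(C), length(x) >= 2)
  ord <- order(x)
  x <- x[ord]; I0 <- I0[ord]; C <- C[ord]
  y_abs <- sqrt(I0 / C)
  if (is.null(sign)) {
    best <- NULL
    for (k in 0:length(x)) {     # sign flips after position k
      s <- c(rep(1, k), rep(-1, length(x) - k))
      f <- stats::lm(I(s * y_abs) ~ x)
      r2 <- suppressWarnings(summary(f)$r.squared)   # exact fits are fine
      if (is.null(best) || r2 > best$r2) best <- list(fit = f, r2 = r2, s = s)
    }
    fit <- best$fit; sgn <- best$s
  } else {
    sgn <- sign[ord]
    fit <- stats::lm(I(sgn * y_abs) ~ x)
  }
  co <- stats::coef(fit)
  mp <- -co[[1]] / co[[2]]
  V <- suppressWarnings(stats::vcov(fit))   # exact fits give zero residuals
  g <- c(-1 / co[[2]], co[[1]] / co[[2]]^2)
  mp_err <- sqrt(drop(t(g) %*% V %*% g))
  list(match_point = mp, match_point_err = mp_err,
       extrapolated = mp < min(x) || mp > max(x),
       signs = sgn, fit = fit)
}

#' Stuhrmann analysis
#'
#' Weighted fit of \eqn{R_g^2 = R_m^2 + \alpha/\Delta\rho - \beta/\Delta\rho^2}
#' across a contrast series. \code{Rm} is the radius of gyration at infinite
#' contrast, \code{alpha} reports the radial distribution of internal
#' density fluctuations and \code{beta} the displacement of their centre.
#'
#' @param delta_rho mean contrast per point (any consistent unit, e.g.
#'   1e10 cm^-2); must be nonzero.
#' @param Rg,Rg_err radii of gyration (Angstrom) and their errors (errors
#'   optional; equal weights when absent).
#' @param beta_zero pin beta to 0 (two-parameter mode).
#' @return list with \code{Rm2}, \code{alpha}, \code{beta}, their standard
#'   errors and the fit residuals.
#' @export
stuhrmann <- function(delta_rho, Rg, Rg_err = NULL, beta_zero = FALSE) {
  stopifnot(length(delta_rho) == length(Rg), all(delta_rho != 0))
  n_par <- if (beta_zero) 2L else 3L
  if (length(Rg) < n_par) stop("need at least ", n_par, " contrast points")
  y <- Rg^2
  w <- if (is.null(Rg_err)) rep(1, length(Rg)) else 1 / (2 * Rg * Rg_err)^2
  X <- cbind(1, 1 / delta_rho)
  if (!beta_zero) X <- cbind(X, -1 / delta_rho^2)
  fit <- stats::lm.wfit(X, y, w)
  co <- fit$coefficients
  dof <- length(y) - n_par
  s2 <- if (dof > 0) sum(w * fit$residuals^2) / dof else 1
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(XtWX) * s2, error = function(e) matrix(NA, n_par, n_par))
  se <- sqrt(diag(cov))
  list(Rm2 = co[[1]], alpha = co[[2]],
       beta = if (beta_zero) 0 else co[[3]],
       Rm2_err = se[1], alpha_err = se[2],
       beta_err = if (beta_zero) 0 else se[3],
       residuals = fit$residuals)
}

#' Parallel-axis theorem for a two-component particle
#'
#' \eqn{R_g^2 = f_1 R_1^2 + f_2 R_2^2 + f_1 f_2 D^2} with \code{f2 = 1 - f1},
#' where \code{f1} is the contrast-weighted scattering fraction of component
#' 1 and \code{D} the distance between the component centres of scattering.
#'
#' @param R1,R2 component radii of gyration, Angstrom.
#' @param f1 contrast-weighted fraction of component 1 in [0, 1].
#' @param D centre-centre distance, Angstrom.
#' @return whole-particle Rg, Angstrom.
#' @export
parallel_axis <- function(R1, R2, f1, D) {
  stopifnot(f1 >= 0, f1 <= 1)
  sqrt(f1 * R1^2 + (1 - f1) * R2^2 + f1 * (1 - f1) * D^2)
}

#' Decompose a contrast series into component radii and separation
#'
#' Solves the overdetermined linear system
#' \eqn{R_{g,i}^2 = f_{1,i} R_1^2 + (1-f_{1,i}) R_2^2 + f_{1,i}(1-f_{1,i}) D^2}
#' across contrast points (the inverse of \code{\link{parallel_axis}}).
#'
#' @param f1 contrast-weighted fraction of component 1 per point (must vary
#'   across the series).
#' @param Rg,Rg_err whole-particle radii of gyration and optional errors.
#' @return list with \code{R1}, \code{R2}, \code{D} and their standard errors.
#' @export
decompose_parallel_axis <- function(f1, Rg, Rg_err = NULL) {
  stopifnot(length(f1) == length(Rg), length(Rg) >= 3)
  X <- cbind(f1, 1 - f1, f1 * (1 - f1))
  y <- Rg^2
  w <- if (is.null(Rg_err)) rep(1, length(Rg)) else 1 / (2 * Rg * Rg_err)^2
  fit <- stats::lm.wfit(X, y, w)
  co <- fit$coefficients
  if (any(co < 0)) warning("negative squared parameter in parallel-axis solve")
  dof <- length(y) - 3
  s2 <- if (dof > 0) sum(w * fit$residuals^2) / dof else 1
  cov <- tryCatch(solve(crossprod(X * sqrt(w))) * s2,
                  error = function(e) matrix(NA, 3, 3))
  se_sq <- sqrt(diag(cov))
  vals <- sqrt(pmax(co, 0))
  se <- ifelse(vals > 0, se_sq / (2 * vals), NA)
  list(R1 = vals[[1]], R2 = vals[[2]], D = vals[[3]],
       R1_err = se[[1]], R2_err = se[[2]], D_err = se[[3]])
}

#' Extract component scattering functions from a contrast series
#'
#' Per-q weighted least squares of
#' \eqn{I_k(q) = \Delta\rho_{1k}^2 I_{11}(q) + \Delta\rho_{1k}\Delta\rho_{2k}
#' I_{12}(q) + \Delta\rho_{2k}^2 I_{22}(q)} across contrast points k,
#' yielding the two component profiles and the cross-term with propagated
#' errors and the condition number of the contrast design.
#'
#' @param I matrix (contrast points x q) of measured intensities.
#' @param sigma matching matrix of standard errors.
#' @param drho1,drho2 component contrasts per contrast point (length =
#'   number of rows of \code{I}); any consistent unit.
#' @return list with \code{I11}, \code{I12}, \code{I22} and matching
#'   \code{*_err} vectors, plus \code{condition} of the design.
#' @export
extract_components <- function(I, sigma, drho1, drho2) {
  I <- as.matrix(I); sigma <- as.matrix(sigma)
  K <- nrow(I)
  stopifnot(length(drho1) == K, length(drho2) == K, K >= 3)
  X <- cbind(drho1^2, drho1 * drho2, drho2^2)
  # a component held at zero contrast throughout leaves its terms
  # unconstrained: drop those columns and solve the reduced system
  active <- apply(abs(X), 2, max) > 1e-12 * max(abs(X))
  Xa <- X[, active, drop = FALSE]
  sv <- svd(Xa)$d
  if (sv[length(sv)] < 1e-10 * sv[1]) {
    v <- svd(X)$v[, 3]
    stop("rank-deficient contrast design: the direction (",
         paste(round(v, 3), collapse = ", "),
         ") of (I11, I12, I22) is unconstrained")
  }
  if (any(duplicated(cbind(drho1, drho2))))
    warning("duplicated contrast points; solution equals dropping duplicates ",
            "with averaged data")
  nq <- ncol(I)
  out <- matrix(NA_real_, 3, nq)
  err <- matrix(NA_real_, 3, nq)
  for (j in seq_len(nq)) {
    w <- 1 / sigma[, j]^2
    XtWX <- crossprod(Xa * sqrt(w))
    cov <- solve(XtWX)
    beta <- cov %*% crossprod(Xa * w, I[, j])
    out[active, j] <- beta
    err[active, j] <- sqrt(diag(cov))
  }
  list(I11 = out[1, ], I12 = out[2, ], I22 = out[3, ],
       I11_err = err[1, ], I12_err = err[2, ], I22_err = err[3, ],
       condition = sv[1] / sv[length(sv)], active_terms = active)
}
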