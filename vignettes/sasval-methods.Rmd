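---
title: "Methods: validation analyses for solution small-angle scattering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validation analyses for solution small-angle scattering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasval)
```

sasval implements the quantitative checks that establish whether a
biomolecular solution scattering profile represents the form factor of a
monodisperse particle and is fit for structural modelling: Guinier
analysis, the indirect Fourier transform to P(r), invariant-based volume
and mass estimation, absolute-scale mass from I(0), flexibility
diagnostics, model-fit statistics, contrast-variation analysis and
SEC-SAS frame processing. This vignette records the models behind each
analysis, the defaults and why they were chosen, and what the synthetic
ground-truth generator does and does not emulate.

## Data model

A profile is the triple (q, I(q), sigma(q)) with q = 4*pi*sin(theta)/lambda
in inverse Angstrom. sigma is always one standard error internally;
reduction pipelines known to emit 2-sigma errors are handled by the
`sigma_is_2x` reader dialect, and files in inverse nanometres by an
explicit unit flag (q divided by 10). Mismatched q-grids are a hard error
everywhere: the chi-square and CORMAP statistics assume exact pointwise
correspondence, and silent interpolation would invalidate both. Dropped
or masked points are counted and surfaced, never silently removed, so
that any low-q truncation can be reported and justified.

Solvent subtraction propagates errors in quadrature and records any
additive constant together with its ratio to the mean solvent level; a
constant above 1 percent of the solvent scattering is flagged as a
warning sign of an incorrect subtraction.

## Guinier analysis

`guinier_fit` performs weighted least squares of ln I versus q^2 with
weights (I/sigma)^2, the first-order propagation of sigma into log space.
Rg = sqrt(-3 slope) and I(0) = exp(intercept), with errors propagated
from the fit covariance; the weighted R^2 is reported as the fit-quality
scalar. `auto_guinier` iterates the window upper edge to the largest q
with q*Rg below the limit (default 1.3, the classical bound for globular
particles; elongated or inhomogeneous particles may need < 1.0) until the
fitted Rg reaches a fixed point within 0.1 percent. When the iteration
falls into a two-cycle between neighbouring windows - which happens on
profiles with weak interference distortions - it settles deterministically
on the smaller window, the conservative side of the limit. The adequacy
check q_min <= pi/d_max is evaluated when d_max is known.

On the exact-sphere oracle the qRg <= 1.3 window overestimates Rg by
about 2 percent; the bias shrinks monotonically with the window, which
the test suite asserts.

## Indirect Fourier transform

P(r) is represented as a sine series sum a_n sin(n pi r / d_max), which
vanishes at r = 0 and d_max by construction. Coefficients minimize the
error-weighted residual to I(q) = 4 pi int P(r) sinc(qr) dr plus
alpha times the integrated squared second derivative of P(r) (diagonal in
this basis). The ridge problem is solved by QR on the augmented system,
which remains stable at regularization levels where the normal equations
fail. The basis size defaults to the Shannon-channel count
ceil(q_max d_max / pi) plus 6; the slack keeps the basis-truncation
artifact on the closed-form sphere benchmark below the noise level of
typical data (about 1.6 percent of the P(r) peak).

When alpha is not given it is chosen at the corner of the chi2(alpha)
trade-off: the largest alpha whose fit chi-square stays within 10 percent
of the floor attained over a 57-point logarithmic sweep. The textbook
max-curvature L-curve corner was evaluated and rejected: the smoothness
branch of the L-curve is nearly flat until deep into the over-smoothed
regime, so its curvature extremum is numerically unstable and can land
several decades into over-smoothing. The chi2-floor rule is deterministic,
testable, and reduces to "the smoothest solution the data cannot
distinguish from the best fit".

Derived parameters use the moment identities I(0) = 4 pi int P dr and
Rg^2 = int r^2 P dr / (2 int P dr), with errors from the coefficient
covariance by the delta method.

### Choosing d_max

`dmax_scan` runs the transform over a user grid and suggests the smallest
d_max whose fit chi-square is within 5 percent of the grid minimum and
whose solution is physically admissible: P(r) approaches zero from above
near d_max, and the solution carries no appreciable negative mass (below
5 percent of the total absolute mass). The negative-mass criterion is
essential: because the sine-series solution is not sign-constrained, an
under-estimated d_max can reproduce the data almost perfectly by
developing large compensating negative lobes, leaving the chi-square
nearly blind to the truncation. A systematically negative approach to
d_max combined with substantial negative mass also raises the
negative-dip flag, the signature of an unmodelled inter-particle
interference (structure-factor) contribution. The full scan table is
always returned; the suggestion is a documented convention, not an
oracle, and automated d_max choices should be reviewed against the scan.

## Invariants and the mass battery

The Porod invariant Q_i = int q^2 I dq and the volume-of-correlation
denominator int q I dq are computed from the regularized back-transform,
with the Guinier curve (from the P(r)-derived Rg and I(0)) supplying
0 <= q < q_min. The high-q completion depends on the local decay of the
regularized curve at q_max:

* if the curve falls faster than q^-6 there (a band-complete profile -
  the truncated mass is negligible), the locally fitted power law is
  integrated analytically to infinity;
* otherwise - a compact particle measured to moderate q_max*R, where any
  tail fitted on form-factor fringes is phase-biased - the integral is
  divided by the truncation completeness of a uniform sphere at
  x = q_max * Rg / sqrt(3/5), tabulated in
  `inst/extdata/porod_truncation_synthetic.csv`. This is the same
  philosophy as forcing the high-q data to the expected q^-4 dependence,
  with the correction computed from the closed-form sphere rather than an
  empirical protein set.

The sphere calibration is exact for uniform spheres by construction and
appropriate for folded, globular particles; it is not meaningful for
random coils, for which the Porod volume itself is undefined and the
volume of correlation (which needs only int q I dq, convergent without a
q^-4 assumption) is the appropriate invariant.

Masses are estimated four ways and cross-tabulated by
`mass_consistency`:

* **I(0), absolute scale**: M = I(0) N_A / (C delta_rho_M^2), with the
  mass contrast delta_rho_M = delta_rho_bar * vbar from the composition
  (concentration accepted in mg/ml and converted internally).
* **Porod volume**: V_P = 2 pi^2 I(0) / Q_i, with the folded-protein rule
  of thumb V_P/M of 1.45-1.50 A^3/Da flagged outside [1.3, 1.7].
* **Truncation-corrected Porod mass**: the apparent volume integrated to
  q_max (no tail) is corrected by the sphere completeness table times the
  dry-to-Porod volume ratio (0.73/0.6022)/1.50 and converted at the
  canonical protein mass density 1.37 g/cm^3. The published empirical
  correction coefficients for this method are not redistributable, so the
  packaged table is a synthetic calibration from the closed-form sphere;
  on the sphere benchmark it reproduces M = V/1.5 to within a fraction of
  a percent.
* **Volume of correlation**: V_c = I(0) / int q I dq, converted to mass by
  the published power-law calibration (protein: QR/0.1231 with QR =
  V_c^2/Rg; nucleic acid: (QR/0.00934)^0.808), shipped as a cited data
  file. Note that this calibration is empirical for real biomolecules:
  applied to an ideal uniform sphere it returns about 0.74 of V/1.5,
  which is expected behaviour, not an implementation error.

## Composition and contrast

Compositions are tallied from one-letter sequences using packaged
per-residue tables: elemental formulas in the neutral protonation state,
exchangeable-hydrogen counts (backbone amides plus side-chain OH/NH/SH),
and residue volumes (Zamyatnin's compilation for amino acids; nucleotide
volumes chosen to reproduce the canonical polynucleotide partial specific
volume of 0.57 cm^3/g). One water is added per chain for the termini.
X-ray scattering-length densities are r0 = 2.8179e-13 cm times electrons
per dry volume; neutron densities use Sears coherent lengths, with labile
hydrogens exchanging in proportion to the solvent 2H2O fraction times an
exchange-completeness factor (default 0.9 - buried amides exchange slowly
and incompletely; the value is configurable and reported). Solvent
densities come from a molar recipe with partial molar volumes from a
small built-in table (user-extensible); water fills the remaining volume.

Derived vbar values for proteins land in the expected 0.70-0.74 cm^3/g
window (a warning fires outside it), but third-digit agreement with any
particular reference tool depends on the residue-volume compilation;
differences of 1-2 percent in delta_rho_bar are normal across
compilations.

Contrast-variation analysis follows the standard linear models: the
match point from signed sqrt(I(0)/C) versus solvent composition; the
Stuhrmann plot Rg^2 = Rm^2 + alpha/delta_rho - beta/delta_rho^2 by
weighted least squares (beta optionally pinned to zero); the parallel-axis
theorem and its overdetermined inversion across a contrast series; and
per-q weighted extraction of the two component profiles and cross-term,
with the design condition number reported and components held at zero
contrast throughout removed from the system rather than inverted.

## Flexibility diagnostics

The dimensionless Kratky transform (qRg)^2 I/I(0) versus qRg locates its
global maximum by quadratic interpolation. Folded globular particles give
a bell with maximum near 1.1 (exactly 3/e at qRg = sqrt(3) for the pure
Guinier law) at qRg about 1.75; the globular-candidate window defaults to
peak position 1.5-2.2 and height 0.9-1.3. A rising mean slope beyond
qRg = 6 sets the flexible-tail flag (the Debye coil rises toward its
asymptote of 2). Secondary maxima past the main peak are recorded - well
separated two-domain particles produce a shallow oscillation - but not
thresholded. All flags are advisory strings, never errors. The
Porod-Debye transform q^4 I versus q^4 declares a plateau when the upper
half of the range shows no monotone trend (|correlation| < 0.5): a
compact particle oscillates about its Porod level there, while q^-2 or
q^-3 decays trend upward through the whole tail.

## Fit statistics

chi2 uses the 1/N convention as printed by most analysis software, with
the multiplicative scale c (and optionally an additive constant) solved
in closed form; the fitted-parameter count is returned so a reader can
convert to 1/(N-p). The residual series is exactly
[I_exp - c I_mod - b]/sigma. The CORMAP longest-run statistic uses the
exact null distribution of the longest run among n fair coin flips,
computed by the compositions-with-bounded-parts recursion carried in
units of 2^-n for stability at large n; exact ties in the sign sequence
inherit the previous sign (a zero-probability event under continuous
noise), with a leading tie counted positive. Mixture decomposition solves
the error-weighted nonnegative least-squares problem for number-density
weights; normalization to fractions is presentation only. Model smearing
convolves with a Gaussian resolution kernel by Gauss-Hermite quadrature,
with wavelength spread mapped to sigma_q = q (dlambda/lambda)/sqrt(8 ln 2)
in quadrature with the geometric width; models are smeared forward for
comparison with data, never the data desmeared.

## SEC-SAS frame processing

Per-frame traces subtract a solvent estimate and run the automatic
Guinier fit, recording failures (baseline frames have no decay) as gaps.
Buffer windows are the longest contiguous run of baseline-level frames on
the user-chosen side of the elution peak - the side is explicit
configuration and never auto-switched; a drifting background is handled
by choosing the stable side - whose frames are pairwise statistically
indistinguishable under CORMAP. Because no significance level is canon,
the default family alpha of 0.01 with Bonferroni adjustment over the
pairs in the window is a documented convention. Buffer comparisons are
raw and unscaled so that drift is caught. Sample windows grow around the
I(0) maximum while each frame's Rg stays within twice the combined
standard errors of the window mean and pairwise CORMAP passes; these
comparisons use solvent-subtracted frames after optimal multiplicative
scaling, since concentration varies across an elution peak and a raw
comparison would flag the concentration difference itself. Selection is
fully deterministic. Concentrations come from A280/(path * epsilon)
aligned by an explicit (or correlation-estimated) UV-to-SAS delay; a
0.31 cm UV cell gives the familiar multiplier of 3.22.

## The synthetic generator

`synth_generate` produces orientationally averaged analytic intensities
(sphere, ellipsoid of revolution by orientational quadrature, two-sphere
dumbbell, Debye coil, pure Guinier law) with exact truth records (Rg,
d_max, volume, I(0)). Corruptions emulate the common pathologies:
a Percus-Yevick hard-sphere structure factor for charge-repulsion
interference, an additive solvent-mismatch constant, and a
sphere-modelled aggregate admixture whose forward scattering scales with
mass. Noise is Gaussian with a Poisson-derived standard deviation
(counts proportional to intensity, referenced to the counts at q_min), so
the sigma columns are exact by construction; this validates estimators
under correctly propagated errors, which is the study condition for the
chi-square calibration. `simulate_sec_run` composes Gaussian elutions,
a flat or drifting baseline (optionally drifting only within a time
window), per-frame counting noise, concentration-scaled interference, and
a delayed A280 trace.

What the generator does **not** emulate - and hence what passing tests do
not establish about real data: instrumental smearing beyond a Gaussian
kernel, radiation damage and inter-frame correlations, hydration-shell
contrast, incoherent background shape, detector artifacts, and
concentration-dependent oligomer equilibria. Tests on generated data
validate the estimators under their stated models; they do not certify
any particular beamline pipeline.

## Problem sizes and numerical choices

The test suite and examples run at desk scale by choice: profiles of
300-600 points on q = 0.007-0.31 (occasionally to 0.5) inverse Angstrom,
SEC runs of 120 one-second frames of 100-120 points, 60-200 replicates
for calibration checks, and exhaustive CORMAP enumeration to n = 16.
P(r) uses a 301-point r-grid; integrals are trapezoidal on these grids;
the chi-square-floor alpha sweep uses 57 logarithmic points. Degenerate
inputs fail loudly: fewer than 3 points, non-monotone q, non-positive
sigma, zero models, rank-deficient contrast designs and unknown residue
letters are all hard errors with specific messages.

## Known limitations

* The truncation-completeness correction assumes a compact, roughly
  globular particle; for strongly anisometric or flexible particles the
  Porod-branch invariants degrade (use V_c and report the scan).
* d_max selection on smooth single-peak P(r) shapes is weakly determined
  at realistic noise; the suggestion rule is honest but one grid step of
  uncertainty is inherent.
* Composition-derived contrasts depend on the residue-volume compilation
  at the 1-2 percent level.
* The Guinier fixed-point window is a local procedure; heavily
  aggregated profiles require explicit low-q masking, which is recorded
  and must be justified in reports.
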