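# Model-versus-data statistics: reduced chi-square with analytic scaling,
# error-weighted residuals, the exact longest-run (CORMAP) test, mixture
# decomposition and forward smearing of model curves.

#' Reduced chi-square fit of a model curve to data
#'
#' \deqn{\chi^2 = \frac{1}{N}\sum_q
#'   \left[\frac{I_{exp}(q) - c I_{mod}(q) - b}{\sigma(q)}\right]^2}
#' with the multiplicative scale \code{c} (and optionally an additive
#' constant \code{b}, accounting for small solvent-subtraction errors)
#' chosen to minimize chi-square in closed form. The 1/N convention is used
#' as printed by most SAS software; the number of fitted parameters is
#' returned so a reader can adjust to 1/(N-p) if preferred.
#'
#' @param exp_profile a \code{\link{sas_profile}}.
#' @param model model intensities on the same q-grid (numeric vector), or a
#'   \code{sas_profile} whose grid must match exactly.
#' @param fit_constant also fit an additive constant (default \code{FALSE}).
#' @return An object of class \code{sas_fit} with \code{chi2}, \code{c},
#'   \code{constant}, \code{n_par}, \code{N}, \code{residuals}
#'   (\code{[I_exp - c I_mod - b]/sigma}) and \code{cormap}
#'   (a \code{\link{cormap_test}} of the scaled model against the data).
#' @export
chi2_fit <- function(exp_profile, model, fit_constant = FALSE) {
  stopifnot(inherits(exp_profile, "sas_profile"))
  if (inherits(model, "sas_profile")) {
    if (length(model$q) != length(exp_profile$q) ||
        any(abs(model$q - exp_profile$q) > 1e-9 * pmax(model$q, exp_profile$q)))
      stop("grid error: model and data q-grids differ")
    model <- model$intensity
  }
  I <- exp_profile$intensity; s <- exp_profile$sigma
  if (length(model) != length(I)) stop("grid error: length mismatch")
  w <- 1 / s^2
  if (all(model == 0)) stop("degenerate scale: model is identically zero")
  if (fit_constant) {
    X <- cbind(model, 1)
    XtWX <- crossprod(X * sqrt(w))
    beta <- solve(XtWX, crossprod(X * w, I))
    cc <- beta[[1]]; b <- beta[[2]]
  } else {
    cc <- sum(w * I * model) / sum(w * model^2)
    b <- 0
  }
  res <- (I - cc * model - b) / s
  structure(list(chi2 = mean(res^2), c = cc, constant = b,
                 n_par = if (fit_constant) 2L else 1L,
                 N = length(I), residuals = res,
                 cormap = cormap_test(I, cc * model + b)),
            class = "sas_fit")
}

#' @export
print.sas_fit <- function(x, ...) {
  cat(sprintf("chi2 = %.4g (N = %d, c = %.4g, constant = %.3g)\n",
              x$chi2, x$N, x$c, x$constant))
  cat(sprintf("CORMAP: longest run %d of %d, P = %.4g\n",
              x$cormap$L, x$cormap$n, x$cormap$p_value))
  invisible(x)
}

#' Longest-run (CORMAP) comparison of two curves
#'
#' Error-model independent goodness of fit: the longest run of points for
#' which one curve lies consistently above or below the other, with the
#' exact probability of observing a run at least that long among n fair
#' coin flips. Exact zero differences inherit the previous sign (a
#' zero-probability event under continuous noise); a tie at the first point
#' counts as positive.
#'
#' @param a,b intensity vectors on the same grid.
#' @return An object of class \code{sas_cormap}: \code{n}, \code{L},
#'   \code{p_value}.
#' @export
cormap_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  d <- a - b
  s <- sign(d)
  if (s[1] == 0) s[1] <- 1
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  runs <- rle(s)
  L <- max(runs$lengths)
  structure(list(n = length(a), L = L,
                 p_value = longest_run_pvalue(length(a), L)),
            class = "sas_cormap")
}

#' Exact P-value of the longest run among fair coin flips
#'
#' Probability that the longest run of identical symbols in n independent
#' fair coin flips is at least L. Computed from the standard recursion for
#' the number of binary strings whose runs all stay below L (equivalently,
#' compositions of n into parts of size at most L-1), carried in units of
#' 2^-n for numerical stability at large n.
#'
#' @param n number of points (flips), >= 1.
#' @param L run length, 1 <= L <= n.
#' @return exact probability in (0, 1].
#' @export
longest_run_pvalue <- function(n, L) {
  n <- as.integer(n); L <- as.integer(L)
  stopifnot(n >= 1, L >= 1, L <= n)
  if (L == 1L) return(1)
  # q[k+1] = (number of compositions of k into parts <= L-1) / 2^k
  q <- numeric(n + 1)
  q[1] <- 1
  for (k in seq_len(n)) {
    j <- seq_len(min(k, L - 1L))
    q[k + 1] <- sum(q[k + 1 - j] / 2^j)
  }
  p <- 1 - 2 * q[n + 1]
  min(max(p, 2^(1 - n)), 1)
}

#' Nonnegative mixture decomposition of a scattering profile
#'
#' For a solution of K non-interacting species, the measured intensity is
#' the number-density weighted sum of the species profiles. Solves the
#' error-weighted nonnegative least-squares problem for the weights and
#' reports the combined reduced chi-square. Normalization to fractions is
#' presentation, not a constraint.
#'
#' @param exp_profile a \code{\link{sas_profile}}.
#' @param components matrix (q points x K) or list of component intensity
#'   vectors on the same grid.
#' @return An object of class \code{sas_mixture}: \code{weights} (>= 0),
#'   \code{fractions}, \code{chi2}, \code{residuals}.
#' @export
fit_mixture <- function(exp_profile, components) {
  stopifnot(inherits(exp_profile, "sas_profile"))
  A <- if (is.list(components)) do.call(cbind, components) else as.matrix(components)
  I <- exp_profile$intensity; s <- exp_profile$sigma
  if (nrow(A) != length(I)) stop("grid error: component length mismatch")
  if (ncol(A) > 1) {
    sv <- svd(A)$d
    if (sv[length(sv)] < 1e-8 * sv[1])
      warning("near-collinear components: weights are poorly conditioned")
  }
  Aw <- A / s
  bw <- I / s
  w <- pracma::lsqnonneg(Aw, bw)$x
  res <- (I - drop(A %*% w)) / s
  total <- sum(w)
  structure(list(weights = w,
                 fractions = if (total > 0) w / total else w,
                 chi2 = mean(res^2), residuals = res, K = ncol(A)),
            class = "sas_mixture")
}

#' Smear a model curve with the instrumental resolution
#'
#' Convolves a model intensity curve with a Gaussian resolution kernel in q
#' (Gauss-Hermite quadrature; the model is interpolated with a natural
#' spline and extended by Guinier-like and Porod-like behaviour outside the
#' grid). A wavelength spread contributes
#' \code{sigma_q = q (dlambda/lambda) / sqrt(8 ln 2)} added in quadrature
#' with the geometric width. The preferred way to compare a sharp model to
#' smeared data is to smear the model, never to desmear the data.
#'
#' @param q q-grid, inverse Angstrom.
#' @param I model intensities on \code{q}.
#' @param sigma_q geometric kernel width: scalar or per-q vector (1 standard
#'   deviation, inverse Angstrom). 0 disables.
#' @param dlambda_over_lambda fractional FWHM wavelength spread. 0 disables.
#' @param n_quad Gauss-Hermite order (default 21).
#' @return smeared intensities on the same grid.
#' @export
smear_model <- function(q, I, sigma_q = 0, dlambda_over_lambda = 0,
                        n_quad = 21L) {
  stopifnot(length(q) == length(I))
  sq <- sqrt(rep(sigma_q, length.out = length(q))^2 +
               (q * dlambda_over_lambda / sqrt(8 * log(2)))^2)
  if (all(sq == 0)) return(I)
  gh <- pracma::gaussHermite(n_quad)
  fint <- stats::splinefun(q, I, method = "natural")
  qmin <- q[1]; qmax <- q[length(q)]
  Iq <- function(qq) {
    out <- fint(qq)
    lo <- qq < qmin
    hi <- qq > qmax
    if (any(lo)) out[lo] <- I[1]                      # flat toward q = 0
    if (any(hi)) out[hi] <- I[length(I)] * (qmax / qq[hi])^4   # Porod tail
    out
  }
  vapply(seq_along(q), function(i) {
    if (sq[i] == 0) return(I[i])
    qq <- q[i] + sqrt(2) * sq[i] * gh$x
    qq <- pmax(qq, 1e-8)
    sum(gh$w * Iq(qq)) / sqrt(pi)
  }, numeric(1))
}
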