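#' Guinier analysis
#'
#' Weighted least-squares fit of \code{ln I} versus \code{q^2} over a stated
#' window, yielding the radius of gyration \code{Rg = sqrt(-3 slope)} and
#' forward scattering \code{I0 = exp(intercept)}. Weights are \code{(I/sigma)^2},
#' the first-order propagation of sigma into log space. For a sphere of
#' uniform density the linear approximation holds to about \code{q Rg < 1.3};
#' for elongated or inhomogeneous particles the limit can be below 1.0.
#'
#' @param profile a \code{\link{sas_profile}}.
#' @param q_range numeric length-2, the q-window (inverse Angstrom) to fit.
#' @param n_truncated_low number of low-q points deliberately excluded by the
#'   user (recorded for reporting; truncation must be reported, never silent).
#' @return An object of class \code{sas_guinier} with fields \code{Rg},
#'   \code{Rg_err}, \code{I0}, \code{I0_err}, \code{q_range} (window actually
#'   used), \code{qRg_window}, \code{r2}, \code{n}, \code{n_truncated_low}.
#' @export
guinier_fit <- function(profile, q_range = range(profile$q),
                        n_truncated_low = 0L) {
  stopifnot(inherits(profile, "sas_profile"))
  sel <- profile$q >= q_range[1] - 1e-12 & profile$q <= q_range[2] + 1e-12
  if (sum(sel) < 3L) stop("Guinier window must contain at least 3 points")
  q <- profile$q[sel]; I <- profile$intensity[sel]; s <- profile$sigma[sel]
  if (any(!is.finite(I) | I <= 0))
    stop("domain error: non-positive intensity inside the Guinier window")
  fit <- .wls(q^2, log(I), (I / s)^2)
  if (fit$b >= 0)
    stop("no Guinier decay: ln I vs q^2 slope is non-negative in this window")
  Rg <- sqrt(-3 * fit$b)
  # Rg = sqrt(-3 m): dRg/dm = -3/(2 Rg)
  Rg_err <- 3 * fit$se_b / (2 * Rg)
  I0 <- exp(fit$a)
  I0_err <- I0 * fit$se_a
  structure(list(Rg = Rg, Rg_err = Rg_err, I0 = I0, I0_err = I0_err,
                 q_range = range(q), qRg_window = range(q) * Rg,
                 r2 = fit$r2, n = length(q),
                 n_truncated_low = as.integer(n_truncated_low)),
            class = "sas_guinier")
}

#' @export
print.sas_guinier <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.4g +/- %.2g A, I(0) = %.4g +/- %.2g\n",
              x$Rg, x$Rg_err, x$I0, x$I0_err))
  cat(sprintf("  window q = %.4g..%.4g 1/A (qRg %.3g..%.3g), R^2 = %.4f, n = %d\n",
              x$q_range[1], x$q_range[2], x$qRg_window[1], x$qRg_window[2],
              x$r2, x$n))
  if (x$n_truncated_low > 0)
    cat("  NOTE:", x$n_truncated_low, "low-q point(s) excluded by user mask\n")
  invisible(x)
}

#' Self-consistent automatic Guinier window
#'
#' Iterates the Guinier fit from a fixed lower q bound to the largest q
#' satisfying \code{q Rg <= qrg_limit}, until the fitted Rg reaches a fixed
#' point (relative change below 0.1 percent). The lower bound is the first
#' measured point unless low-q points are explicitly masked by the user, in
#' which case the count of excluded points is recorded and surfaced so that
#' truncation can be reported and justified.
#'
#' @param profile a \code{\link{sas_profile}}.
#' @param qrg_limit upper \code{q Rg} limit of the window (default 1.3,
#'   appropriate for globular particles; use smaller for elongated shapes).
#' @param mask_low integer, number of leading low-q points to exclude
#'   (user-declared truncation; default 0).
#' @param dmax optional known maximum dimension in Angstrom: when supplied,
#'   the adequacy check \code{q_min <= pi/dmax} is evaluated and a flag set
#'   if the lowest usable q is too high to characterize the particle.
#' @param max_iter iteration cap for the fixed point (default 50).
#' @return A \code{sas_guinier} object with additional fields
#'   \code{converged}, \code{iterations} and \code{flag_qmin_too_high}.
#' @export
auto_guinier <- function(profile, qrg_limit = 1.3, mask_low = 0L,
                         dmax = NULL, max_iter = 50L) {
  stopifnot(inherits(profile, "sas_profile"))
  mask_low <- as.integer(mask_low)
  q <- profile$q
  i0 <- mask_low + 1L
  if (i0 > length(q) - 2L) stop("mask leaves fewer than 3 points")
  q_min <- q[i0]
  # initial window: first 10 usable points (or all below the median q)
  hi <- min(length(q), i0 + 9L)
  Rg_prev <- NA_real_
  fit <- NULL
  converged <- FALSE
  iter <- 0L
  seen <- integer(0)
  while (iter < max_iter) {
    iter <- iter + 1L
    fit <- guinier_fit(profile, c(q_min, q[hi]), n_truncated_low = mask_low)
    if (is.finite(Rg_prev) && abs(fit$Rg - Rg_prev) <= 1e-3 * Rg_prev) {
      converged <- TRUE
      break
    }
    Rg_prev <- fit$Rg
    seen <- c(seen, hi)
    hi_new <- max(which(q * fit$Rg <= qrg_limit))
    hi_new <- max(hi_new, i0 + 2L)      # keep at least 3 points
    if (hi_new %in% seen) {
      # the iteration oscillates between neighbouring windows: settle on
      # the smaller one (the conservative side of the qRg limit)
      hi <- min(hi_new, hi)
      fit <- guinier_fit(profile, c(q_min, q[hi]), n_truncated_low = mask_low)
      converged <- TRUE
      break
    }
    hi <- hi_new
  }
  if (!converged)
    stop("auto_guinier: no self-consistent window after ", max_iter, " iterations")
  fit$converged <- TRUE
  fit$iterations <- iter
  fit$qrg_limit <- qrg_limit
  fit$flag_qmin_too_high <-
    if (!is.null(dmax)) q_min > pi / dmax else NA
  fit
}
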