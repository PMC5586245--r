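# Kratky, dimensionless Kratky, Porod-Debye and log-log transforms with
# peak descriptors and qualitative flexibility flags.

#' Diagnostic transforms of a scattering profile
#'
#' Pointwise transforms used to assess folding and flexibility:
#' \itemize{
#'   \item \code{kratky}: \code{q^2 I(q)} versus \code{q};
#'   \item \code{dimensionless_kratky}: \code{(q Rg)^2 I(q)/I(0)} versus
#'     \code{q Rg} (folded proteins peak near 1.1 at about \code{q Rg} 1.75;
#'     random coils plateau at 2);
#'   \item \code{porod_debye}: \code{q^4 I(q)} versus \code{q^4} (a plateau
#'     signals Porod \code{q^-4} decay of a compact particle);
#'   \item \code{log_log}: \code{log10 I} versus \code{log10 q}.
#' }
#' For the dimensionless Kratky transform the global maximum is located by
#' quadratic interpolation through the three points bracketing the discrete
#' maximum; for Porod-Debye a plateau level is fitted over the final
#' quarter of the transformed abscissa.
#'
#' @param profile a \code{\link{sas_profile}}.
#' @param kind transform kind (see above).
#' @param Rg,I0 required for \code{dimensionless_kratky}.
#' @return An object of class \code{sas_transform} with \code{x}, \code{y},
#'   \code{kind} and, where applicable, \code{peak = c(x, y)} or
#'   \code{plateau}.
#' @export
sas_transform <- function(profile,
                          kind = c("kratky", "dimensionless_kratky",
                                   "porod_debye", "log_log"),
                          Rg = NULL, I0 = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(profile, "sas_profile"))
  q <- profile$q; I <- profile$intensity
  out <- switch(kind,
    kratky = list(x = q, y = q^2 * I),
    dimensionless_kratky = {
      if (is.null(Rg) || is.null(I0) || Rg <= 0 || I0 <= 0)
        stop("dimensionless Kratky transform requires positive Rg and I0")
      list(x = q * Rg, y = (q * Rg)^2 * I / I0)
    },
    porod_debye = list(x = q^4, y = q^4 * I),
    log_log = {
      pos <- I > 0
      list(x = log10(q[pos]), y = log10(I[pos]))
    })
  res <- list(x = out$x, y = out$y, kind = kind)
  if (kind == "dimensionless_kratky") {
    res$peak <- .quad_peak(out$x, out$y)
  }
  if (kind == "porod_debye") {
    # tail = upper half of the measured q range; a Porod q^-4 regime shows
    # q^4 I oscillating about a constant level (no monotone trend), whereas
    # flexible chains (q^-2, q^-3) trend upward through the whole tail
    sel <- out$x >= stats::quantile(out$x, 0.5)
    fit <- stats::lm(out$y[sel] ~ out$x[sel])
    res$plateau <- mean(out$y[sel])
    res$plateau_slope <- stats::coef(fit)[[2]]
    trend <- suppressWarnings(stats::cor(out$x[sel], out$y[sel]))
    res$plateau_detected <- is.finite(trend) && abs(trend) < 0.5 &&
      res$plateau > 0
  }
  structure(res, class = "sas_transform")
}

# quadratic interpolation of the maximum through its bracketing points
.quad_peak <- function(x, y) {
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(c(x = x[i], y = y[i]))
  xs <- x[(i - 1):(i + 1)]; ys <- y[(i - 1):(i + 1)]
  co <- stats::coef(stats::lm(ys ~ xs + I(xs^2)))
  if (!is.finite(co[[3]]) || co[[3]] >= 0) return(c(x = x[i], y = y[i]))
  xm <- -co[[2]] / (2 * co[[3]])
  c(x = xm, y = co[[1]] + co[[2]] * xm + co[[3]] * xm^2)
}

#' @export
print.sas_transform <- function(x, ...) {
  cat(sprintf("<sas_transform> %s, %d points\n", x$kind, length(x$x)))
  if (!is.null(x$peak))
    cat(sprintf("  peak: y = %.4g at x = %.4g\n", x$peak[["y"]], x$peak[["x"]]))
  if (!is.null(x$plateau))
    cat(sprintf("  Porod-Debye plateau %.4g (detected: %s)\n",
                x$plateau, x$plateau_detected))
  invisible(x)
}

#' @export
plot.sas_transform <- function(x, ...) {
  lab <- switch(x$kind,
    kratky = c(expression(italic(q)), expression(italic(q)^2 * italic(I))),
    dimensionless_kratky = c(expression(italic(q) * italic(R)[g]),
                             expression((italic(q) * italic(R)[g])^2 *
                                          italic(I) / italic(I)(0))),
    porod_debye = c(expression(italic(q)^4), expression(italic(q)^4 * italic(I))),
    log_log = c("log10 q", "log10 I"))
  graphics::plot(x$x, x$y, type = "l", xlab = lab[[1]], ylab = lab[[2]], ...)
  if (!is.null(x$peak)) graphics::points(x$peak[["x"]], x$peak[["y"]], pch = 4)
  invisible(x)
}

#' Qualitative flexibility flags from a dimensionless Kratky curve
#'
#' Advisory descriptors, never hard errors: a particle is a globular
#' candidate when the peak falls in the window typical of folded proteins
#' (about 1.1 at \code{q Rg} about 1.75), and a rising tail beyond
#' \code{q Rg} of 6 flags likely flexibility. A secondary oscillation past
#' the main peak (as produced by well-separated two-domain particles) is
#' recorded but not thresholded.
#'
#' @param curve a \code{dimensionless_kratky} \code{\link{sas_transform}}.
#' @param peak_x_window,peak_y_window acceptance windows for the peak
#'   position and height (defaults \code{c(1.5, 2.2)} and \code{c(0.9, 1.3)}).
#' @param tail_from q Rg value beyond which the tail slope is measured
#'   (default 6).
#' @return list of logical flags \code{globular}, \code{flexible_tail},
#'   \code{secondary_oscillation} plus the measured descriptors.
#' @export
flexibility_flags <- function(curve, peak_x_window = c(1.5, 2.2),
                              peak_y_window = c(0.9, 1.3), tail_from = 6) {
  stopifnot(inherits(curve, "sas_transform"),
            curve$kind == "dimensionless_kratky")
  px <- curve$peak[["x"]]; py <- curve$peak[["y"]]
  interior <- px > min(curve$x) && px < max(curve$x)
  globular <- interior &&
    px >= peak_x_window[1] && px <= peak_x_window[2] &&
    py >= peak_y_window[1] && py <= peak_y_window[2]
  tail_sel <- curve$x >= tail_from
  tail_slope <- NA_real_
  flexible_tail <- FALSE
  if (sum(tail_sel) >= 3) {
    fit <- stats::lm(curve$y[tail_sel] ~ curve$x[tail_sel])
    sm <- suppressWarnings(summary(fit)$coefficients)
    tail_slope <- sm[2, 1]
    # require a significantly positive rise, not a noise fluctuation
    flexible_tail <- is.finite(tail_slope) && tail_slope > 0 &&
      is.finite(sm[2, 3]) && sm[2, 3] > 2
  }
  # local maxima beyond the main peak
  after <- curve$x > px
  y_a <- curve$y[after]
  n_extra <- if (length(y_a) > 2)
    sum(diff(sign(diff(y_a))) == -2) else 0L
  list(globular = globular, flexible_tail = flexible_tail,
       secondary_oscillation = n_extra > 0,
       peak_x = px, peak_y = py, tail_slope = tail_slope,
       n_secondary_maxima = n_extra)
}
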