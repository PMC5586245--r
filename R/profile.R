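#' One-dimensional reduced scattering profile
#'
#' Container for a reduced solution scattering curve: momentum transfer
#' \code{q} (\eqn{q = 4\pi\sin\theta/\lambda}, in inverse Angstrom),
#' intensity \code{I(q)} (in cm^-1 when absolute-scaled, otherwise arbitrary
#' units) and the one-standard-error column \code{sigma}.
#'
#' @param q numeric vector, strictly increasing and positive, inverse Angstrom.
#' @param intensity numeric vector of the same length.
#' @param sigma numeric vector of 1-standard-error values; must be positive
#'   wherever \code{intensity} is finite.
#' @param scale \code{"arbitrary"} or \code{"absolute"}. Absolute scale
#'   requires a calibration provenance string (e.g. the standard measured).
#' @param calibration provenance of the absolute-scale calibration, e.g.
#'   \code{"1 mm pure H2O"}; mandatory when \code{scale = "absolute"}.
#' @param meta named list of optional acquisition metadata (wavelength in
#'   Angstrom, \code{dlambda_over_lambda}, exposure, temperature,
#'   path-length mm, instrument label).
#' @return An object of class \code{sas_profile}.
#' @export
sas_profile <- function(q, intensity, sigma,
                        scale = c("arbitrary", "absolute"),
                        calibration = NULL, meta = list()) {
  scale <- match.arg(scale)
  q <- as.numeric(q); intensity <- as.numeric(intensity); sigma <- as.numeric(sigma)
  n <- length(q)
  if (n < 3L) stop("a profile needs at least 3 points")
  if (length(intensity) != n || length(sigma) != n)
    stop("q, intensity and sigma must have equal length")
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be finite and positive")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  ok <- is.finite(intensity)
  if (any(sigma[ok] <= 0 | !is.finite(sigma[ok])))
    stop("sigma must be positive wherever intensity is finite")
  if (scale == "absolute" && (is.null(calibration) || !nzchar(calibration)))
    stop("absolute scale requires a calibration provenance string")
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 scale = scale, calibration = calibration, meta = meta),
            class = "sas_profile")
}

#' @export
print.sas_profile <- function(x, ...) {
  cat(sprintf("<sas_profile> %d points, q = %.4g..%.4g 1/A, scale: %s\n",
              length(x$q), min(x$q), max(x$q), x$scale))
  if (!is.null(x$calibration)) cat("  calibration:", x$calibration, "\n")
  invisible(x)
}

#' @export
length.sas_profile <- function(x) length(x$q)

#' @export
plot.sas_profile <- function(x, log = "y", ...) {
  pos <- x$intensity > 0 | log == ""
  graphics::plot(x$q[pos], x$intensity[pos], log = log,
                 xlab = expression(italic(q) ~ (ring(A)^-1)),
                 ylab = expression(italic(I)(italic(q))), ...)
  invisible(x)
}

#' Read a 3-column reduced scattering profile
#'
#' Parses whitespace- or comma-separated text with columns q, I(q), sigma.
#' Lines starting with \code{#} are treated as comments; \code{key: value}
#' pairs in the header are collected into profile metadata. Rows containing
#' non-finite values are dropped and counted.
#'
#' @param path file path.
#' @param dialect \code{"plain3col"} reads sigma as 1 standard error;
#'   \code{"sigma_is_2x"} halves the third column, for reduction software
#'   known to output errors at twice the standard error.
#' @param units \code{"invA"} (default) or \code{"invnm"}; the latter divides
#'   q by 10 so that all internal work is in inverse Angstrom.
#' @return A \code{\link{sas_profile}}; the number of dropped rows is stored
#'   in \code{attr(, "n_dropped")}.
#' @export
read_profile <- function(path, dialect = c("plain3col", "sigma_is_2x"),
                         units = c("invA", "invnm")) {
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_comment <- grepl("^\\s*#", lines)
  meta <- list()
  for (h in lines[is_comment]) {
    h <- sub("^\\s*#\\s*", "", h)
    m <- regmatches(h, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  body <- lines[!is_comment]
  fields <- strsplit(trimws(body), "[[:space:],]+")
  ncols <- vapply(fields, length, integer(1))
  if (length(body) == 0L || any(ncols < 3L))
    stop("format error: expected at least 3 numeric columns in ", path)
  vals <- vapply(fields, function(f) as.numeric(f[1:3]), numeric(3))
  q <- vals[1, ]; I <- vals[2, ]; s <- vals[3, ]
  keep <- is.finite(q) & is.finite(I) & is.finite(s)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("read_profile: dropped ", n_dropped, " non-finite row(s)")
  q <- q[keep]; I <- I[keep]; s <- s[keep]
  if (units == "invnm") q <- q / 10
  if (any(diff(q) <= 0)) stop("ordering error: q is not strictly increasing")
  if (dialect == "sigma_is_2x") s <- s / 2
  scale <- if (identical(meta$scale, "absolute")) "absolute" else "arbitrary"
  calibration <- meta$calibration
  p <- sas_profile(q, I, s, scale = scale, calibration = calibration, meta = meta)
  attr(p, "n_dropped") <- n_dropped
  p
}

#' Write a profile as 3-column ASCII
#'
#' Emits a \code{#}-prefixed \code{key: value} header followed by q, I(q),
#' sigma at 6 significant digits, the same format \code{\link{read_profile}}
#' accepts, so a read-write-read round trip preserves the printed values.
#'
#' @param profile a \code{\link{sas_profile}}.
#' @param path output file path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sas_profile"))
  hdr <- c(sprintf("# scale: %s", profile$scale))
  if (!is.null(profile$calibration))
    hdr <- c(hdr, sprintf("# calibration: %s", profile$calibration))
  for (k in setdiff(names(profile$meta), c("scale", "calibration")))
    hdr <- c(hdr, sprintf("# %s: %s", k, as.character(profile$meta[[k]])))
  rows <- sprintf("%.6g %.6g %.6g", profile$q, profile$intensity, profile$sigma)
  writeLines(c("# q I sigma  (1/A, intensity units, 1 standard error)",
               hdr, rows), path)
  invisible(path)
}

#' Rescale a profile
#'
#' Multiplies intensity and sigma by a positive factor, e.g. a path-length
#' correction. When \code{provenance} names a calibration standard the
#' profile is promoted to absolute scale with that provenance recorded.
#'
#' @param profile a \code{\link{sas_profile}}.
#' @param factor positive scalar.
#' @param provenance optional string naming the calibration standard that
#'   justifies an absolute scale (e.g. \code{"1 mm pure H2O"}).
#' @export
rescale <- function(profile, factor, provenance = NULL) {
  stopifnot(inherits(profile, "sas_profile"))
  if (!.is_scalar_number(factor) || factor <= 0)
    stop("rescale factor must be a positive scalar")
  scale <- profile$scale
  calibration <- profile$calibration
  if (!is.null(provenance) && nzchar(provenance)) {
    scale <- "absolute"
    calibration <- provenance
  }
  sas_profile(profile$q, profile$intensity * factor, profile$sigma * factor,
              scale = scale, calibration = calibration, meta = profile$meta)
}

#' Solvent subtraction with error propagation
#'
#' Computes \code{I = I_sample - I_solvent - constant} pointwise on an
#' identical q-grid with \code{sigma = sqrt(sigma_s^2 + sigma_b^2)}. The
#' returned profile carries a subtraction report recording the constant and
#' its ratio to the mean solvent level; a warning flag is raised when the
#' constant exceeds 1 percent of the solvent scattering level, the
#' conventional threshold for an unduly large ad hoc correction.
#'
#' @param sample,solvent profiles on the same q-grid. Mismatched grids are a
#'   hard error: no silent interpolation is performed because pointwise
#'   statistics (chi-square, CORMAP) assume exact correspondence.
#' @param constant optional additive constant subtracted together with the
#'   solvent (default 0).
#' @return The subtracted \code{\link{sas_profile}} with the report in
#'   \code{attr(, "subtraction")} (see \code{\link{subtraction_report}}).
#' @export
subtract_solvent <- function(sample, solvent, constant = 0) {
  stopifnot(inherits(sample, "sas_profile"), inherits(solvent, "sas_profile"))
  if (length(sample$q) != length(solvent$q) ||
      any(abs(sample$q - solvent$q) > 1e-9 * pmax(sample$q, solvent$q)))
    stop("grid error: sample and solvent q-grids differ (no silent interpolation)")
  if (!.is_scalar_number(constant)) stop("constant must be a finite scalar")
  I <- sample$intensity - solvent$intensity - constant
  s <- sqrt(sample$sigma^2 + solvent$sigma^2)
  solvent_level <- mean(abs(solvent$intensity))
  ratio <- if (solvent_level > 0) abs(constant) / solvent_level else NA_real_
  report <- list(constant = constant,
                 solvent_level = solvent_level,
                 constant_over_solvent = ratio,
                 flag_large_constant = is.finite(ratio) && ratio > 0.01)
  out <- sas_profile(sample$q, I, s, scale = sample$scale,
                     calibration = sample$calibration, meta = sample$meta)
  attr(out, "subtraction") <- report
  out
}

#' Retrieve the solvent-subtraction report attached to a profile
#' @param profile a profile returned by \code{\link{subtract_solvent}}.
#' @export
subtraction_report <- function(profile) attr(profile, "subtraction")
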