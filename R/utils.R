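# Internal helpers shared across modules.

# Trapezoidal integral; x must be sorted increasing.
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Weighted linear fit y ~ a + b x with weights w (= 1/var).
# Returns coefficients, their standard errors, covariance and weighted r2.
.wls <- function(x, y, w) {
  W <- sum(w)
  xb <- sum(w * x) / W
  yb <- sum(w * y) / W
  sxx <- sum(w * (x - xb)^2)
  sxy <- sum(w * (x - xb) * (y - yb))
  syy <- sum(w * (y - yb)^2)
  if (sxx <= 0) stop("degenerate abscissa in linear fit")
  b <- sxy / sxx
  a <- yb - b * xb
  res <- y - (a + b * x)
  n <- length(x)
  # error scale from weighted residuals (chi2 per dof), dof = n - 2
  s2 <- if (n > 2) sum(w * res^2) / (n - 2) else 1
  var_b <- s2 / sxx
  var_a <- s2 * (1 / W + xb^2 / sxx)
  cov_ab <- -s2 * xb / sxx
  r2 <- if (syy > 0) 1 - sum(w * res^2) / syy else 1
  list(a = a, b = b, se_a = sqrt(var_a), se_b = sqrt(var_b),
       cov_ab = cov_ab, r2 = max(0, min(1, r2)), residuals = res, s2 = s2)
}

.is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Locate a packaged data table under extdata (works installed and via pkgload).
.sasval_extdata <- function(file) {
  path <- system.file("extdata", file, package = "sasval")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

.read_table_file <- function(file) {
  utils::read.csv(.sasval_extdata(file), comment.char = "#",
                  stringsAsFactors = FALSE)
}
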