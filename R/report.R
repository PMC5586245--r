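# Guideline-structured report assembly: sample details, data acquisition,
# analysis/validation, model fits, plus a completeness checklist. Rendering
# is pure: identical inputs give byte-identical output (provenance,
# including any timestamps, lives in a separate footer supplied by the
# caller).

.fmt_val <- function(v, unit = "", err = NULL) {
  if (is.null(v) || (is.numeric(v) && !is.finite(v))) return("not determined")
  s <- if (is.numeric(v)) sprintf("%.6g", v) else as.character(v)
  if (!is.null(err) && is.numeric(err) && is.finite(err))
    s <- sprintf("%s +/- %.3g", s, err)
  if (nzchar(unit)) s <- paste(s, unit)
  s
}

.report_items <- list(
  sample = c("source", "sequence_id", "M_expected_Da",
             "extinction_a280_01pc", "vbar_cm3_g", "delta_rho_1e10_cm2",
             "concentration_mg_ml", "solvent"),
  acquisition = c("instrument", "wavelength_A", "q_range_1A",
                  "absolute_scale_method", "exposure", "temperature_C"),
  analysis = c("guinier", "pr", "mass_battery", "dimensionless_kratky",
               "solvent_subtraction_constant"),
  modelling = c("fits"))

#' Assemble a guideline-structured report
#'
#' Renders the four standard reporting sections (sample details, data
#' acquisition, data analysis and validation, model fitting) as
#' readable text plus a flat \code{key: value} export, and emits a
#' completeness checklist naming any recommended item that is absent.
#' Every numeric entry carries its units and error where known; missing
#' items are listed, never silently omitted.
#'
#' @param sample named list of sample metadata (see the checklist keys in
#'   the rendered output).
#' @param acquisition named list of acquisition metadata.
#' @param guinier optional \code{\link{guinier_fit}} result.
#' @param pr optional \code{\link{ift}} result.
#' @param invariants optional \code{\link{invariants_mass}} result.
#' @param kratky_flags optional \code{\link{flexibility_flags}} result.
#' @param subtraction optional \code{\link{subtraction_report}} list.
#' @param sec optional list from the SEC workflow (e.g. selected frame
#'   indices, buffer side).
#' @param fits optional named list of \code{\link{chi2_fit}} results (one
#'   per model).
#' @param provenance named list (toolkit version, input hashes, seeds,
#'   date); rendered verbatim in a footer.
#' @return An object of class \code{sas_report} with \code{text} (character
#'   lines), \code{keyvalues} (named character) and \code{missing}
#'   (absent checklist items).
#' @export
build_report <- function(sample = list(), acquisition = list(),
                         guinier = NULL, pr = NULL, invariants = NULL,
                         kratky_flags = NULL, subtraction = NULL,
                         sec = NULL, fits = list(), provenance = list()) {
  kv <- character(0)
  put <- function(key, val) {
    kv[[key]] <<- if (is.null(val)) "not determined" else .fmt_val(val)
  }
  lines <- c("# Small-angle scattering report", "")

  lines <- c(lines, "## 1. Sample details", "")
  for (k in .report_items$sample) {
    put(paste0("sample.", k), sample[[k]])
    lines <- c(lines, sprintf("- %s: %s", k, .fmt_val(sample[[k]])))
  }

  lines <- c(lines, "", "## 2. Data acquisition and reduction", "")
  for (k in .report_items$acquisition) {
    put(paste0("acquisition.", k), acquisition[[k]])
    lines <- c(lines, sprintf("- %s: %s", k, .fmt_val(acquisition[[k]])))
  }

  lines <- c(lines, "", "## 3. Data analysis and validation", "")
  if (!is.null(guinier)) {
    lines <- c(lines,
      sprintf("- Guinier: Rg = %s, I(0) = %s, window qRg %.3g..%.3g, R^2 = %.4f",
              .fmt_val(guinier$Rg, "A", guinier$Rg_err),
              .fmt_val(guinier$I0, "", guinier$I0_err),
              guinier$qRg_window[1], guinier$qRg_window[2], guinier$r2))
    if (guinier$n_truncated_low > 0)
      lines <- c(lines, sprintf(
        "  NOTE: %d low-q point(s) truncated; report and justify.",
        guinier$n_truncated_low))
    kv[["analysis.guinier.Rg_A"]] <- sprintf("%.6g", guinier$Rg)
    kv[["analysis.guinier.I0"]] <- sprintf("%.6g", guinier$I0)
    kv[["analysis.guinier.r2"]] <- sprintf("%.4f", guinier$r2)
  }
  if (!is.null(pr)) {
    lines <- c(lines,
      sprintf("- P(r): dmax = %s, Rg = %s, I(0) = %s, back-transform chi2 = %.3g",
              .fmt_val(pr$dmax, "A"), .fmt_val(pr$Rg, "A", pr$Rg_err),
              .fmt_val(pr$I0, "", pr$I0_err), pr$fit_chi2))
    if (pr$quality_flags$negative_dip_near_dmax)
      lines <- c(lines,
        "  WARNING: negative dip near dmax (possible structure-factor contribution).")
    kv[["analysis.pr.dmax_A"]] <- sprintf("%.6g", pr$dmax)
    kv[["analysis.pr.Rg_A"]] <- sprintf("%.6g", pr$Rg)
    kv[["analysis.pr.I0"]] <- sprintf("%.6g", pr$I0)
  }
  if (!is.null(guinier) && !is.null(pr)) {
    cons <- pr_consistency(pr, guinier)
    lines <- c(lines, sprintf(
      "- Guinier vs P(r): dRg = %.2f%%, dI0 = %.2f%%%s",
      100 * cons$rel_diff_Rg, 100 * cons$rel_diff_I0,
      if (cons$flag_Rg || cons$flag_I0) " [FLAG: inconsistent]" else ""))
  }
  if (!is.null(invariants)) {
    mc <- mass_consistency(invariants)
    lines <- c(lines, "- Mass battery (Da; ratio to expected in parentheses):")
    for (i in seq_len(nrow(mc$estimates))) {
      r <- mc$estimates[i, ]
      lines <- c(lines, sprintf("    %s: %s%s", r$method, .fmt_val(r$M),
        if (is.finite(r$ratio_to_expected))
          sprintf(" (%.2f)", r$ratio_to_expected) else ""))
    }
    lines <- c(lines, sprintf("    Porod volume: %s; Vp/M = %s%s",
      .fmt_val(invariants$Vp, "A^3"), .fmt_val(mc$vp_over_m),
      if (isTRUE(mc$flag_vp_over_m)) " [FLAG: outside 1.3-1.7]" else ""))
    kv[["analysis.Vp_A3"]] <- sprintf("%.6g", invariants$Vp)
    kv[["analysis.M_fischer_Da"]] <- sprintf("%.6g", invariants$M_fischer)
    kv[["analysis.M_vc_Da"]] <- sprintf("%.6g", invariants$M_vc)
    kv[["analysis.M_i0_Da"]] <- .fmt_val(invariants$M_i0)
  }
  if (!is.null(kratky_flags)) {
    lines <- c(lines, sprintf(
      "- Dimensionless Kratky: peak %.3g at qRg = %.3g; globular: %s; flexible tail: %s",
      kratky_flags$peak_y, kratky_flags$peak_x,
      kratky_flags$globular, kratky_flags$flexible_tail))
    kv[["analysis.kratky.peak_y"]] <- sprintf("%.4g", kratky_flags$peak_y)
    kv[["analysis.kratky.peak_x"]] <- sprintf("%.4g", kratky_flags$peak_x)
  }
  if (!is.null(subtraction)) {
    lines <- c(lines, sprintf(
      "- Solvent-subtraction constant: %s (%.3g%% of solvent level)%s",
      .fmt_val(subtraction$constant),
      100 * subtraction$constant_over_solvent,
      if (isTRUE(subtraction$flag_large_constant))
        " [FLAG: exceeds 1% of solvent scattering]" else ""))
  }
  if (!is.null(sec)) {
    lines <- c(lines, sprintf(
      "- SEC frame selection: sample frames %s; buffer frames %s (side: %s)",
      paste(range(sec$sample_indices), collapse = ".."),
      paste(range(sec$buffer_indices), collapse = ".."),
      if (is.null(sec$side)) "pre" else sec$side))
  }

  lines <- c(lines, "", "## 4. Model fitting", "")
  if (length(fits)) {
    for (nm in names(fits)) {
      f <- fits[[nm]]
      lines <- c(lines, sprintf(
        "- %s: chi2 = %.4g (c = %.4g, constant = %.3g, N = %d); CORMAP L = %d, P = %.3g",
        nm, f$chi2, f$c, f$constant, f$N, f$cormap$L, f$cormap$p_value))
      kv[[paste0("fit.", nm, ".chi2")]] <- sprintf("%.6g", f$chi2)
      kv[[paste0("fit.", nm, ".cormap_p")]] <- sprintf("%.6g", f$cormap$p_value)
    }
  } else lines <- c(lines, "- no model fits supplied")

  missing <- character(0)
  for (k in .report_items$sample)
    if (is.null(sample[[k]])) missing <- c(missing, paste0("sample.", k))
  for (k in .report_items$acquisition)
    if (is.null(acquisition[[k]])) missing <- c(missing, paste0("acquisition.", k))
  have <- list(guinier = guinier, pr = pr, mass_battery = invariants,
               dimensionless_kratky = kratky_flags,
               solvent_subtraction_constant = subtraction)
  for (k in names(have))
    if (is.null(have[[k]])) missing <- c(missing, paste0("analysis.", k))
  if (!length(fits)) missing <- c(missing, "modelling.fits")

  lines <- c(lines, "", "## Completeness checklist", "")
  lines <- c(lines,
    if (length(missing)) sprintf("- MISSING: %s", missing)
    else "- all recommended items present")
  if (length(provenance)) {
    lines <- c(lines, "", "## Provenance", "")
    for (k in names(provenance))
      lines <- c(lines, sprintf("- %s: %s", k, provenance[[k]]))
  }
  structure(list(text = lines, keyvalues = kv, missing = missing),
            class = "sas_report")
}

#' @export
print.sas_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' Write a report to disk
#'
#' @param report a \code{\link{build_report}} result.
#' @param path output path for the text report.
#' @param keyvalue_path optional path for the flat \code{key: value} export.
#' @export
write_report <- function(report, path, keyvalue_path = NULL) {
  stopifnot(inherits(report, "sas_report"))
  writeLines(report$text, path)
  if (!is.null(keyvalue_path))
    writeLines(sprintf("%s: %s", names(report$keyvalues), report$keyvalues),
               keyvalue_path)
  invisible(path)
}
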