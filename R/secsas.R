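# SEC-SAS frame-series processing: per-frame traces, buffer and sample
# frame selection by Rg stability and pairwise CORMAP compatibility,
# averaging, subtraction and UV-based concentration alignment.

#' Time-ordered series of scattering frames
#'
#' @param frames list of \code{\link{sas_profile}} objects on one shared
#'   q-grid.
#' @param times acquisition timestamps in seconds, strictly increasing.
#' @param a280 optional UV trace: \code{list(times =, values =)} with its
#'   own timestamps.
#' @param alignment time offset between the UV and SAS measurement points,
#'   seconds (UV leads SAS by this amount).
#' @return An object of class \code{sas_frame_series}.
#' @export
sas_frame_series <- function(frames, times, a280 = NULL, alignment = 0) {
  stopifnot(is.list(frames), length(frames) >= 1,
            length(times) == length(frames))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  q0 <- frames[[1]]$q
  for (f in frames) {
    stopifnot(inherits(f, "sas_profile"))
    if (length(f$q) != length(q0) || any(abs(f$q - q0) > 1e-9 * q0))
      stop("all frames must share one q-grid")
  }
  structure(list(frames = frames, times = as.numeric(times),
                 q = q0, a280 = a280, alignment = alignment),
            class = "sas_frame_series")
}

#' @export
print.sas_frame_series <- function(x, ...) {
  cat(sprintf("<sas_frame_series> %d frames, %d q-points, t = %.3g..%.3g s%s\n",
              length(x$frames), length(x$q), min(x$times), max(x$times),
              if (!is.null(x$a280)) ", with A280 trace" else ""))
  invisible(x)
}

#' @export
length.sas_frame_series <- function(x) length(x$frames)

#' Average a set of frames
#'
#' Intensities are averaged pointwise; standard errors combine as
#' \code{sqrt(sum sigma^2)/N}, so averaging N statistically compatible
#' frames reduces sigma by \code{sqrt(N)}.
#'
#' @param series a \code{\link{sas_frame_series}}.
#' @param indices frame indices to average.
#' @export
average_frames <- function(series, indices) {
  stopifnot(inherits(series, "sas_frame_series"), length(indices) >= 1)
  Im <- sapply(indices, function(i) series$frames[[i]]$intensity)
  Sm <- sapply(indices, function(i) series$frames[[i]]$sigma)
  Im <- matrix(Im, ncol = length(indices))
  Sm <- matrix(Sm, ncol = length(indices))
  f1 <- series$frames[[indices[1]]]
  sas_profile(series$q, rowMeans(Im),
              sqrt(rowSums(Sm^2)) / length(indices),
              scale = f1$scale, calibration = f1$calibration)
}

#' Per-frame I(0) and Rg traces
#'
#' Subtracts a solvent estimate from every frame and runs the automatic
#' Guinier fit; frames where the fit fails (e.g. baseline-only frames with
#' no decay) are recorded as gaps, not errors.
#'
#' @param series a \code{\link{sas_frame_series}}.
#' @param solvent_estimate a \code{\link{sas_profile}} on the same grid.
#' @param qrg_limit Guinier window limit (default 1.3).
#' @return data.frame with one row per frame: \code{frame}, \code{time},
#'   \code{I0}, \code{I0_err}, \code{Rg}, \code{Rg_err}, \code{ok}.
#' @export
frame_traces <- function(series, solvent_estimate, qrg_limit = 1.3) {
  stopifnot(inherits(series, "sas_frame_series"))
  rows <- lapply(seq_along(series$frames), function(i) {
    sub <- tryCatch(subtract_solvent(series$frames[[i]], solvent_estimate),
                    error = function(e) NULL)
    g <- if (!is.null(sub))
      tryCatch(auto_guinier(sub, qrg_limit = qrg_limit),
               error = function(e) NULL)
    else NULL
    if (is.null(g))
      data.frame(frame = i, time = series$times[i], I0 = NA_real_,
                 I0_err = NA_real_, Rg = NA_real_, Rg_err = NA_real_,
                 ok = FALSE)
    else
      data.frame(frame = i, time = series$times[i], I0 = g$I0,
                 I0_err = g$I0_err, Rg = g$Rg, Rg_err = g$Rg_err, ok = TRUE)
  })
  do.call(rbind, rows)
}

# all pairwise CORMAP p-values within a window pass the Bonferroni-adjusted
# threshold alpha / n_pairs. With scale = TRUE each second frame is scaled
# to the first by the closed-form chi2-optimal factor before comparison
# (sample windows span an elution peak, so concentrations differ).
.window_cormap_ok <- function(frames, idx, alpha, scale = FALSE) {
  if (length(idx) < 2) return(TRUE)
  npairs <- choose(length(idx), 2)
  thr <- alpha / npairs
  for (i in seq_along(idx)[-length(idx)]) {
    for (j in (i + 1):length(idx)) {
      a <- frames[[idx[i]]]$intensity
      b <- frames[[idx[j]]]$intensity
      if (scale) {
        w <- 1 / frames[[idx[i]]]$sigma^2
        b <- b * sum(w * a * b) / sum(w * b^2)
      }
      p <- cormap_test(a, b)$p_value
      if (p < thr) return(FALSE)
    }
  }
  TRUE
}

#' Select buffer or sample frames
#'
#' Buffer mode: the longest contiguous window on the chosen side of the
#' elution peak (\code{side = "pre"} or \code{"post"}; never auto-switched)
#' whose frames are pairwise statistically indistinguishable under CORMAP
#' (all pairwise P-values above a Bonferroni-adjusted threshold).
#'
#' Sample mode: the contiguous window centred on the I(0) maximum over
#' which each frame's Rg differs from the window mean by less than the
#' combined standard errors and pairwise CORMAP passes, i.e. the flat part
#' of the Rg trace. Because concentration varies across an elution peak,
#' sample-mode CORMAP compares solvent-subtracted frames after optimal
#' multiplicative scaling (a raw comparison would flag the concentration
#' difference itself); buffer-mode comparisons are raw and unscaled so that
#' background drift is caught.
#'
#' @param series a \code{\link{sas_frame_series}}.
#' @param traces result of \code{\link{frame_traces}}.
#' @param mode \code{"buffer"} or \code{"sample"}.
#' @param side buffer side relative to the elution peak (\code{"pre"} or
#'   \code{"post"}); explicit configuration, following the practice that a
#'   drifting solvent background is handled by choosing the stable side.
#' @param alpha CORMAP family significance level (default 0.01),
#'   Bonferroni-adjusted over the pairs in the window.
#' @param n_min minimum acceptable window length (default 5).
#' @param rg_k multiple of the combined standard error allowed between a
#'   frame Rg and the window mean in sample mode (default 2).
#' @param solvent optional solvent-estimate \code{\link{sas_profile}} used
#'   to subtract frames before the sample-mode comparison; defaults to the
#'   average of the baseline-level frames.
#' @return list with \code{indices}, \code{averaged}
#'   (\code{\link{sas_profile}}), and a \code{criteria_log}.
#' @export
select_frames <- function(series, traces, mode = c("buffer", "sample"),
                          side = c("pre", "post"), alpha = 0.01,
                          n_min = 5L, rg_k = 2, solvent = NULL) {
  mode <- match.arg(mode)
  side <- match.arg(side)
  stopifnot(inherits(series, "sas_frame_series"))
  n <- length(series$frames)
  # total-intensity trace: robust against frames where the Guinier fit fails
  m <- vapply(series$frames, function(f) mean(f$intensity), numeric(1))
  i_peak <- if (any(traces$ok)) which.max(ifelse(is.na(traces$I0), -Inf,
                                                 traces$I0))
            else which.max(m)
  if (mode == "buffer") {
    # candidate frames: total intensity at the baseline level of the chosen
    # side of the elution peak (the two sides may legitimately sit at
    # different solvent levels)
    side_idx <- if (side == "pre") seq_len(max(i_peak - 1L, 0L))
                else seq_len(n)[-seq_len(i_peak)]
    if (length(side_idx) < n_min)
      stop("selection error: fewer than ", n_min, " ", side, "-peak frames")
    floor_m <- stats::quantile(m[side_idx], 0.25)
    cand <- side_idx[m[side_idx] <= floor_m * 1.02]
    if (length(cand) < n_min)
      stop("selection error: fewer than ", n_min, " quiet ", side,
           "-peak frames (inspect the I0 trace)")
    runs <- split(cand, cumsum(c(1, diff(cand) != 1)))
    best <- NULL
    for (r in runs) {
      # drop frames nearest the peak first (elution onset/tail leaks there)
      r <- sort(r)
      len <- length(r)
      while (len >= n_min) {
        idx <- if (side == "pre") utils::head(r, len) else utils::tail(r, len)
        if (.window_cormap_ok(series$frames, idx, alpha)) break
        len <- len - 1L
      }
      if (len >= n_min) {
        idx <- if (side == "pre") utils::head(r, len) else utils::tail(r, len)
        if (is.null(best) || length(idx) > length(best)) best <- idx
      }
    }
    if (is.null(best))
      stop("selection error: no CORMAP-compatible ", side,
           "-peak window of length >= ", n_min)
    idx <- best
  } else {
    if (is.na(traces$Rg[i_peak]))
      stop("selection error: no Guinier fit at the I0 maximum")
    if (is.null(solvent)) {
      floor_m <- stats::quantile(m, 0.25)
      quiet_idx <- which(m <= floor_m * 1.02)
      if (length(quiet_idx) < 2)
        stop("selection error: cannot form a solvent estimate from baseline frames")
      solvent <- average_frames(series, quiet_idx)
    }
    cmp_frames <- lapply(series$frames, function(f)
      suppressWarnings(subtract_solvent(f, solvent)))
    idx <- i_peak
    repeat {
      grown <- FALSE
      for (cand in c(min(idx) - 1L, max(idx) + 1L)) {
        if (cand < 1L || cand > n) next
        if (!isTRUE(traces$ok[cand])) next
        trial <- sort(c(idx, cand))
        mu <- mean(traces$Rg[trial])
        tol <- rg_k * sqrt(traces$Rg_err[trial]^2 +
                             mean(traces$Rg_err[trial])^2 / length(trial))
        if (all(abs(traces$Rg[trial] - mu) <= tol) &&
            .window_cormap_ok(cmp_frames, trial, alpha, scale = TRUE)) {
          idx <- trial
          grown <- TRUE
        }
      }
      if (!grown) break
    }
    if (length(idx) < n_min)
      stop("selection error: flat-Rg window around the peak shorter than ",
           n_min, " frames")
  }
  list(indices = idx,
       averaged = average_frames(series, idx),
       criteria_log = list(mode = mode, side = side, alpha = alpha,
                           peak_frame = i_peak,
                           rg_window_mean = mean(traces$Rg[idx], na.rm = TRUE)))
}

#' UV-based concentration trace aligned to SAS frames
#'
#' \code{C [mg/ml] = A280 / (path_cm * epsilon)} with epsilon the extinction
#' coefficient for 0.1 percent w/v at 1 cm path; a 0.31 cm UV cell thus
#' gives the familiar multiplier of about 3.22 on A280. The UV trace is
#' shifted by the transit delay and interpolated at the frame times.
#'
#' @param a280 UV trace \code{list(times =, values =)}.
#' @param path_cm UV cell path length, cm.
#' @param epsilon extinction coefficient (A280, 0.1 percent w/v, 1 cm).
#' @param frame_times SAS frame times, seconds.
#' @param delay_s UV-to-SAS transit delay, seconds (UV leads by delay_s).
#' @return data.frame \code{time}, \code{C_mg_ml}.
#' @export
concentration_trace <- function(a280, path_cm, epsilon, frame_times,
                                delay_s = 0) {
  stopifnot(path_cm > 0, epsilon > 0)
  C_uv <- a280$values / (path_cm * epsilon)
  C <- stats::approx(a280$times + delay_s, C_uv, xout = frame_times,
                     rule = 1)$y
  data.frame(time = frame_times, C_mg_ml = C)
}

#' Estimate the UV-to-SAS transit delay
#'
#' Scans a delay grid and returns the delay maximizing the correlation
#' between the shifted concentration trace and the per-frame I(0) trace.
#'
#' @param a280 UV trace \code{list(times =, values =)}.
#' @param traces result of \code{\link{frame_traces}}.
#' @param delay_grid candidate delays, seconds.
#' @export
estimate_uv_delay <- function(a280, traces, delay_grid) {
  best <- delay_grid[1]; best_r <- -Inf
  i0 <- ifelse(is.na(traces$I0), 0, traces$I0)
  for (d in delay_grid) {
    Cs <- stats::approx(a280$times + d, a280$values, xout = traces$time,
                        rule = 2)$y
    r <- suppressWarnings(stats::cor(Cs, i0))
    if (is.finite(r) && r > best_r) { best_r <- r; best <- d }
  }
  list(delay_s = best, correlation = best_r)
}
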