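# Phase-encoded (traveling-wave) analysis of the wedge-and-ring runs:
# per-vertex Fourier phase and power at the wedge (6 cycles/run) and ring
# (8 cycles/run) fundamental frequencies, combined across opposite-direction
# runs to cancel hemodynamic lag, then decoded to polar angle and
# eccentricity.

#' Convert a raw series to percent signal change
#'
#' Removes a linear trend and expresses the residual as a percentage of the
#' series mean; the output has zero mean.
#'
#' @param series numeric vector (raw BOLD units, nonzero mean).
#' @return detrended, de-meaned series in percent units.
#' @export
to_percent_change <- function(series) {
  if (length(series) <= 2) stop("series too short")
  m <- mean(series)
  if (abs(m) < 1e-8 * max(stats::sd(series), 1e-12)) {
    stop("series mean is (near) zero; percent change undefined")
  }
  t <- seq_along(series)
  resid <- stats::lm.fit(cbind(1, t), series)$residuals
  100 * resid / m
}

#' Fourier phase and power at an integer cycle frequency
#'
#' The discrete Fourier coefficient of the series at exactly
#' \code{n_cycles} per run. Phase is the cosine phase (the argument of the
#' coefficient) wrapped to [0, 2*pi); power is the squared amplitude of the
#' component.
#'
#' @param series numeric vector with any terminal blank volumes already
#'   removed.
#' @param n_cycles integer number of stimulus cycles in the series.
#' @return named numeric vector \code{c(phase, power)}.
#' @export
fundamental_phase <- function(series, n_cycles) {
  Tn <- length(series)
  if (abs(n_cycles - round(n_cycles)) > 1e-9 || n_cycles < 1 ||
      n_cycles >= Tn / 2) {
    stop("n_cycles must be a positive integer below half the series length")
  }
  tt <- seq_len(Tn) - 1L
  cf <- sum(series * exp(-2i * pi * n_cycles * tt / Tn))
  c(phase = Arg(cf) %% (2 * pi), power = (2 * Mod(cf) / Tn)^2)
}

#' Per-vertex phase map for one wedge-and-ring run
#'
#' Applies the Fourier analysis at the wedge and ring fundamentals to every
#' vertex of one run (blank volumes must already be removed).
#'
#' @param data vertices x time matrix (percent signal change, stimulation
#'   volumes only).
#' @param design a \code{stimulus_design} (supplies the cycle counts).
#' @param direction \code{"cw_expand"} or \code{"ccw_contract"}.
#' @return a \code{phase_map} data frame: vertex, phase_polar, power_polar,
#'   phase_ecc, power_ecc, plus coherence-squared columns (fraction of
#'   series variance at each fundamental).
#' @export
phase_map <- function(data, design = stimulus_design(),
                      direction = c("cw_expand", "ccw_contract")) {
  direction <- match.arg(direction)
  fp <- t(apply(data, 1, fundamental_phase, design$wedge_cycles_per_run))
  fe <- t(apply(data, 1, fundamental_phase, design$ring_cycles_per_run))
  tot <- apply(data, 1, function(s) stats::var(s) * (length(s) - 1) /
                 length(s) * 2)
  out <- data.frame(vertex = seq_len(nrow(data)),
                    phase_polar = fp[, "phase"], power_polar = fp[, "power"],
                    phase_ecc = fe[, "phase"], power_ecc = fe[, "power"])
  out$coh2_polar <- ifelse(tot > 0, out$power_polar / tot, 0)
  out$coh2_ecc <- ifelse(tot > 0, out$power_ecc / tot, 0)
  attr(out, "direction") <- direction
  class(out) <- c("phase_map", class(out))
  out
}

# circular mean of two phases via the resultant vector
circ_mean2 <- function(a, b) {
  Arg(exp(1i * a) + exp(1i * b)) %% (2 * pi)
}

#' Combine phase maps from opposite stimulus directions
#'
#' The hemodynamic lag adds the same phase offset to both directions while
#' the stimulus phase reverses sign, so negating the reversed-direction
#' phases and circularly averaging with the forward ones cancels the lag.
#'
#' @param map_fwd phase map from the clockwise/expanding run.
#' @param map_rev phase map from the counterclockwise/contracting run.
#' @return combined \code{phase_map}; powers and coherences are averaged.
#' @export
combine_directions <- function(map_fwd, map_rev) {
  if (nrow(map_fwd) != nrow(map_rev)) stop("maps must share vertices")
  out <- map_fwd
  out$phase_polar <- circ_mean2(map_fwd$phase_polar, -map_rev$phase_polar)
  out$phase_ecc <- circ_mean2(map_fwd$phase_ecc, -map_rev$phase_ecc)
  for (cl in c("power_polar", "power_ecc", "coh2_polar", "coh2_ecc")) {
    out[[cl]] <- (map_fwd[[cl]] + map_rev[[cl]]) / 2
  }
  attr(out, "direction") <- "combined"
  out
}

#' Decode polar angle and eccentricity from a combined phase map
#'
#' Phase is converted to stimulus-cycle progress (the fraction of a cycle
#' at which the vertex responds, referenced to the forward direction).
#' Wedge progress maps linearly to polar angle along the clockwise
#' rotation from the wedge start angle; ring progress maps to eccentricity
#' through the logarithmic ring progression, so progress 0 decodes to the
#' innermost ring eccentricity and progress 1/2 to the geometric mean of
#' the eccentricity range.
#'
#' @param map a combined \code{phase_map}.
#' @param design a \code{stimulus_design}.
#' @param max_ecc maximum stimulated eccentricity (degrees).
#' @return the map with added columns \code{polar_angle_deg} and
#'   \code{eccentricity_deg}.
#' @export
decode_coordinates <- function(map, design = stimulus_design(), max_ecc) {
  p_pol <- ((-map$phase_polar) %% (2 * pi)) / (2 * pi)
  p_ecc <- ((-map$phase_ecc) %% (2 * pi)) / (2 * pi)
  map$polar_angle_deg <- wedge_angle_at(p_pol, design, cw = TRUE)
  e_min <- design$log_min_ecc_deg
  map$eccentricity_deg <- e_min * (max_ecc / e_min)^p_ecc
  map
}

#' Full phase-encoded analysis of a pair of wedge-and-ring runs
#'
#' Removes the terminal blank volumes, smooths each run on the cortical
#' sheet (5 mm FWHM by default), computes per-vertex phase maps at the two
#' fundamentals, combines the opposite directions and decodes visual-field
#' coordinates.
#'
#' @param data_fwd,data_rev vertices x time matrices (percent signal
#'   change, full runs including blanks) for the two directions.
#' @param apertures_fwd the forward-direction \code{aperture_sequence}
#'   (supplies blank flags and design).
#' @param sheet a \code{cortical_sheet} for smoothing.
#' @param fwhm_mm smoothing kernel FWHM (mm); 0 disables smoothing.
#' @param max_ecc maximum stimulated eccentricity; defaults to the grid's.
#' @return decoded combined \code{phase_map}.
#' @export
phase_encode <- function(data_fwd, data_rev, apertures_fwd, sheet,
                         fwhm_mm = 5, max_ecc = NULL) {
  keep <- !apertures_fwd$is_blank
  design <- apertures_fwd$design
  if (is.null(max_ecc)) max_ecc <- apertures_fwd$grid$max_ecc_deg
  sm_f <- smooth_on_sheet(data_fwd[, keep, drop = FALSE], sheet, fwhm_mm)
  sm_r <- smooth_on_sheet(data_rev[, keep, drop = FALSE], sheet, fwhm_mm)
  mf <- phase_map(sm_f, design, "cw_expand")
  mr <- phase_map(sm_r, design, "ccw_contract")
  decode_coordinates(combine_directions(mf, mr), design, max_ecc)
}
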