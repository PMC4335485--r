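# Stimulus generation: carrier pattern, aperture sequences, session schedule.
#
# All geometry is expressed in degrees of visual angle with x rightward,
# y upward and the origin at fixation. Polar angle is measured
# counterclockwise from the positive x-axis. Apertures are binary masks
# sampled once per acquired volume (TR).

#' Visual-field pixel grid
#'
#' Builds the rectangular pixel grid on which carrier frames and aperture
#' masks are rendered. Pixel centers are spaced \code{1/pixels_per_degree}
#' apart and include the fixation point (0, 0).
#'
#' @param max_ecc_deg maximum stimulated eccentricity in degrees (display
#'   radius; 9 or 16 in the designs supported here).
#' @param pixels_per_degree rendering resolution.
#' @return An object of class \code{vf_grid}: pixel coordinate vectors
#'   \code{x}, \code{y} (length \code{n_pixels}), the axis vectors
#'   \code{xs}, \code{ys}, and grid metadata.
#' @export
vf_grid <- function(max_ecc_deg, pixels_per_degree) {
  if (max_ecc_deg <= 0 || pixels_per_degree <= 0) {
    stop("max_ecc_deg and pixels_per_degree must be positive")
  }
  n_half <- round(max_ecc_deg * pixels_per_degree)
  xs <- seq(-n_half, n_half) / pixels_per_degree
  grid <- list(
    xs = xs, ys = xs,
    x = rep(xs, times = length(xs)),
    y = rep(xs, each = length(xs)),
    nx = length(xs), ny = length(xs),
    n_pixels = length(xs)^2,
    pixels_per_degree = pixels_per_degree,
    max_ecc_deg = max_ecc_deg
  )
  class(grid) <- "vf_grid"
  grid
}

#' @export
print.vf_grid <- function(x, ...) {
  cat(sprintf("<vf_grid> %d x %d pixels, +/-%g deg at %g px/deg\n",
              x$nx, x$ny, x$max_ecc_deg, x$pixels_per_degree))
  invisible(x)
}

#' Carrier configuration
#'
#' Parameters of the dynamic high-contrast carrier pattern: a rippling
#' pseudo-checkerboard whose phase parameter theta advances from 0 to 4*pi
#' in equal steps, completing one 2*pi cycle roughly every 1.15 s.
#'
#' @param max_ecc_deg display radius in degrees.
#' @param pixels_per_degree rendering resolution.
#' @param phase_step_ms duration of one theta step (ms).
#' @param n_phase_steps number of steps covering 0 to 4*pi (must be even).
#' @param rotation_deg overall pattern orientation for the trial condition
#'   (0 for cardinal bars, 45 for oblique bars, wedge angle for wedge-ring).
#' @param edge_band_px width in pixels of the blurred fringe at the outer
#'   edge of the stimulated disc.
#' @return A \code{carrier_config} list.
#' @export
carrier_config <- function(max_ecc_deg = 16, pixels_per_degree = 4,
                           phase_step_ms = 32, n_phase_steps = 72,
                           rotation_deg = 0, edge_band_px = 12) {
  if (max_ecc_deg <= 0) stop("max_ecc_deg must be positive")
  if (pixels_per_degree <= 0) stop("pixels_per_degree must be positive")
  if (n_phase_steps %% 2 != 0) stop("n_phase_steps must be even")
  structure(list(
    max_ecc_deg = max_ecc_deg,
    pixels_per_degree = pixels_per_degree,
    phase_step_ms = phase_step_ms,
    n_phase_steps = n_phase_steps,
    rotation_deg = rotation_deg,
    edge_band_px = edge_band_px,
    grid = vf_grid(max_ecc_deg, pixels_per_degree)
  ), class = "carrier_config")
}

#' Carrier phase schedule
#'
#' Tabulates the carrier phase theta (0 to 4*pi in \code{n_phase_steps}
#' equal steps) and the derived spatial-frequency parameter
#' delta = sin(theta)/4 + 1/2 for each animation step.
#'
#' @param cfg a \code{carrier_config}.
#' @return data frame with columns \code{step}, \code{t_ms}, \code{theta},
#'   \code{delta}; attribute \code{cycle_s} gives the duration of one 2*pi
#'   phase cycle in seconds.
#' @export
phase_schedule <- function(cfg) {
  i <- seq_len(cfg$n_phase_steps) - 1L
  theta <- 4 * pi * i / cfg$n_phase_steps
  out <- data.frame(
    step = i,
    t_ms = i * cfg$phase_step_ms,
    theta = theta,
    delta = sin(theta) / 4 + 0.5
  )
  attr(out, "cycle_s") <- (cfg$n_phase_steps / 2) * cfg$phase_step_ms / 1000
  out
}

#' Render one carrier frame
#'
#' Evaluates the carrier luminance pattern
#' \deqn{I(x,y) = \sqrt{x^2+y^2}\,\cos\{2\pi(\sin\delta\,\pi x/180 +
#'   \cos\delta\,\pi y/180)^4 + \theta\}}
#' at the given animation step, rectifies it to a binary black/white
#' pattern (positive values to maximum luminance, zero and negative values
#' to minimum), bounds it within the stimulated disc (pixels beyond
#' \code{max_ecc_deg} set to mean luminance) and linearly ramps contrast
#' down to mean within the \code{edge_band_px} fringe.
#'
#' Luminance is coded 0 = minimum, 0.5 = mean, 1 = maximum.
#'
#' @param t_index animation step, 0-based, in \code{[0, n_phase_steps)}.
#' @param cfg a \code{carrier_config}.
#' @return numeric matrix (\code{nx} by \code{ny}); element \code{[i, j]}
#'   is the pixel at \code{x = xs[i], y = ys[j]}.
#' @export
carrier_frame <- function(t_index, cfg) {
  if (t_index < 0 || t_index >= cfg$n_phase_steps) {
    stop("t_index out of range [0, n_phase_steps)")
  }
  g <- cfg$grid
  sched <- phase_schedule(cfg)
  theta <- sched$theta[t_index + 1L]
  delta <- sched$delta[t_index + 1L]
  # pattern orientation: rotate coordinates by -rotation_deg
  a <- cfg$rotation_deg * pi / 180
  xr <- cos(a) * g$x + sin(a) * g$y
  yr <- -sin(a) * g$x + cos(a) * g$y
  r <- sqrt(g$x^2 + g$y^2)
  arg <- (sin(delta) * pi * xr / 180 + cos(delta) * pi * yr / 180)^4
  I <- r * cos(2 * pi * arg + theta)
  v <- ifelse(I > 0, 1, 0)
  # circular bounding with blurred fringe
  band_deg <- cfg$edge_band_px / cfg$pixels_per_degree
  frac <- pmin(1, pmax(0, (cfg$max_ecc_deg - r) / band_deg))
  v <- 0.5 + (v - 0.5) * frac
  v[r > cfg$max_ecc_deg] <- 0.5
  matrix(v, nrow = g$nx, ncol = g$ny)
}

#' Stimulus design parameters
#'
#' Geometry and timing shared by the aperture sequences. Linear widths are
#' quoted at the 16-degree reference display and scaled by
#' \code{max_ecc/16} at rendering time, so the 9-degree display uses a
#' proportionally narrower bar. The logarithmic eccentricity map runs from
#' \code{log_min_ecc_deg} at fixation to the display edge on both displays.
#'
#' @param bar_width_deg size-invariant bar width at the 16-degree display.
#' @param log_min_ecc_deg inner eccentricity of the logarithmic scaling map.
#' @param wedge_width_deg angular width of the rotating wedge.
#' @param wedge_cycles_per_run,ring_cycles_per_run revolutions per run.
#' @param wedge_volumes_per_cycle,ring_volumes_per_cycle volumes per
#'   revolution (20 and 15: both divide the 120 stimulation volumes).
#' @param volumes_per_sweep,volumes_per_blank bar-run segment lengths.
#' @param ring_overlap_frac radial (log-domain) overlap between adjacent
#'   ring steps.
#' @param wedge_start_deg polar angle of the wedge bisector at run onset.
#' @return A \code{stimulus_design} list.
#' @export
stimulus_design <- function(bar_width_deg = 2.70, log_min_ecc_deg = 0.06,
                            wedge_width_deg = 18,
                            wedge_cycles_per_run = 6, ring_cycles_per_run = 8,
                            wedge_volumes_per_cycle = 20,
                            ring_volumes_per_cycle = 15,
                            volumes_per_sweep = 24, volumes_per_blank = 24,
                            ring_overlap_frac = 0.5, wedge_start_deg = 90) {
  d <- list(bar_width_deg = bar_width_deg, log_min_ecc_deg = log_min_ecc_deg,
            wedge_width_deg = wedge_width_deg,
            wedge_cycles_per_run = wedge_cycles_per_run,
            ring_cycles_per_run = ring_cycles_per_run,
            wedge_volumes_per_cycle = wedge_volumes_per_cycle,
            ring_volumes_per_cycle = ring_volumes_per_cycle,
            volumes_per_sweep = volumes_per_sweep,
            volumes_per_blank = volumes_per_blank,
            ring_overlap_frac = ring_overlap_frac,
            wedge_start_deg = wedge_start_deg)
  stopifnot(all(vapply(d[1:10], function(z) z > 0, logical(1))))
  if (wedge_cycles_per_run * wedge_volumes_per_cycle !=
      ring_cycles_per_run * ring_volumes_per_cycle) {
    stop("wedge and ring cycles must fill the same number of stimulation volumes")
  }
  structure(d, class = "stimulus_design")
}

# internal constructor for aperture sequences
new_aperture_sequence <- function(masks, tr_s, condition, direction,
                                  is_blank, grid, design = NULL) {
  stopifnot(nrow(masks) == length(is_blank), ncol(masks) == grid$n_pixels)
  structure(list(masks = masks, tr_s = tr_s, condition = condition,
                 direction = direction, is_blank = is_blank, grid = grid,
                 design = design),
            class = "aperture_sequence")
}

#' @export
print.aperture_sequence <- function(x, ...) {
  cat(sprintf("<aperture_sequence> %s (%s): %d volumes (%d blank), TR %.2f s, %d px\n",
              x$condition, paste(x$direction, collapse = "/"),
              nrow(x$masks), sum(x$is_blank), x$tr_s, x$grid$n_pixels))
  invisible(x)
}

#' Number of volumes in an aperture sequence
#' @param ap an \code{aperture_sequence}.
#' @export
n_volumes <- function(ap) nrow(ap$masks)

# width of the eccentricity-scaled bar when its center sits at
# eccentricity |c|: log-uniform map from e_min at fixation to the display
# edge, accounting for cortical magnification.
log_bar_width <- function(center_ecc, e_min, e_max) {
  e_min * (e_max / e_min)^(pmin(1, abs(center_ecc) / e_max))
}

#' Drifting-bar aperture sequence
#'
#' One run of the bar stimulus: a sweep of \code{volumes_per_sweep} volumes
#' along \code{direction}, a sweep along the orthogonal direction, and a
#' blank (mean-luminance) period, followed by a second trial with both
#' sweep directions reversed. The bar is perpendicular to its direction of
#' motion and its center traverses the full display diameter in equal
#' steps, starting half a step inside the edge.
#'
#' @param direction sweep axis in degrees: 0, 45, 90 or 135. A cardinal run
#'   uses 0 (sweeps along 0 and 90), an oblique run 45 (sweeps 45 and 135).
#' @param sweep_sign +1 or -1; -1 time-reverses every sweep segment.
#' @param scaled if \code{TRUE} the bar width follows the logarithmic
#'   eccentricity map (narrow near fixation, wide at the periphery);
#'   otherwise it is the constant size-invariant width.
#' @param design a \code{stimulus_design}.
#' @param cfg a \code{carrier_config} (supplies display size and grid).
#' @param tr_s volume repetition time in seconds.
#' @return an \code{aperture_sequence} of
#'   \code{2 * (2 * volumes_per_sweep + volumes_per_blank)} volumes.
#' @export
bar_sequence <- function(direction, sweep_sign = 1, scaled = FALSE,
                         design = stimulus_design(), cfg = carrier_config(),
                         tr_s = 2.55) {
  if (!direction %in% c(0, 45, 90, 135)) {
    stop("direction must be one of 0, 45, 90, 135 degrees")
  }
  stopifnot(sweep_sign %in% c(-1, 1))
  g <- cfg$grid
  R <- cfg$max_ecc_deg
  ns <- design$volumes_per_sweep
  nb <- design$volumes_per_blank
  width_const <- design$bar_width_deg * R / 16
  r <- sqrt(g$x^2 + g$y^2)
  in_disc <- r <= R

  sweep_masks <- function(dir_deg, sgn) {
    a <- dir_deg * pi / 180
    proj <- g$x * cos(a) + g$y * sin(a)
    centers <- -R + (seq_len(ns) - 0.5) * (2 * R / ns)
    if (sgn < 0) centers <- rev(centers)
    m <- matrix(FALSE, nrow = ns, ncol = g$n_pixels)
    for (k in seq_len(ns)) {
      w <- if (scaled) {
        log_bar_width(centers[k], design$log_min_ecc_deg, R)
      } else width_const
      m[k, ] <- in_disc & abs(proj - centers[k]) <= w / 2
    }
    m
  }

  blank <- matrix(FALSE, nrow = nb, ncol = g$n_pixels)
  trial <- function(sgn) {
    rbind(sweep_masks(direction, sgn),
          sweep_masks((direction + 90) %% 180, sgn),
          blank)
  }
  masks <- rbind(trial(sweep_sign), trial(-sweep_sign))
  is_blank <- rep(rep(c(FALSE, TRUE), 2), times = rep(c(2 * ns, nb), 2))
  new_aperture_sequence(
    masks, tr_s,
    condition = if (scaled) "bar_log" else "bar_invariant",
    direction = sprintf("%d/%d deg, sign %+d", direction,
                        (direction + 90) %% 180, sweep_sign),
    is_blank = is_blank, grid = g, design = design
  )
}

# polar angle (degrees, CCW from +x) of every grid pixel
pixel_polar_deg <- function(g) atan2(g$y, g$x) * 180 / pi

# signed angular difference wrapped to (-180, 180]
wrap_deg <- function(d) {
  d <- d %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

# wedge bisector polar angle at cycle progress p in [0, 1);
# cw = clockwise rotation (angle decreasing)
wedge_angle_at <- function(p, design, cw = TRUE) {
  s <- if (cw) -1 else 1
  (design$wedge_start_deg + s * 360 * p) %% 360
}

# log-spaced ring radii for step k (0-based) of a ring cycle: the grid has
# n_steps + 1/overlap - 1 ... with 50% overlap each annulus spans two
# adjacent intervals of a (n_steps + 1)-interval log grid.
ring_radii_at <- function(k, design, e_min, e_max) {
  n <- design$ring_volumes_per_cycle
  u <- seq(0, 1, length.out = n + 2)  # n + 1 intervals; annuli span 2 each
  c(lo = e_min * (e_max / e_min)^u[k + 1],
    hi = e_min * (e_max / e_min)^u[k + 3])
}

#' Simultaneous wedge-and-ring aperture sequence
#'
#' One run of the polar-coordinate stimulus: the union of an 18-degree
#' rotating wedge (one revolution per \code{wedge_volumes_per_cycle}
#' volumes, 6 revolutions per run) and an expanding or contracting annulus
#' stepping through 15 log-spaced positions per cycle (8 cycles per run),
#' with adjacent ring steps sharing half of their radial log-domain extent.
#' The 120 stimulation volumes are followed by a terminal mean-luminance
#' blank period.
#'
#' @param direction \code{"cw_expand"} (clockwise wedge, expanding ring) or
#'   \code{"ccw_contract"} (the time-reversed pairing).
#' @inheritParams bar_sequence
#' @return an \code{aperture_sequence} of 144 volumes (24 blank) under the
#'   default design.
#' @export
wedge_ring_sequence <- function(direction = c("cw_expand", "ccw_contract"),
                                design = stimulus_design(),
                                cfg = carrier_config(), tr_s = 2.55) {
  direction <- match.arg(direction)
  cw <- direction == "cw_expand"
  g <- cfg$grid
  R <- cfg$max_ecc_deg
  e_min <- design$log_min_ecc_deg
  n_stim <- design$wedge_cycles_per_run * design$wedge_volumes_per_cycle
  nb <- design$volumes_per_blank
  r <- sqrt(g$x^2 + g$y^2)
  ang <- pixel_polar_deg(g)
  in_disc <- r <= R

  masks <- matrix(FALSE, nrow = n_stim + nb, ncol = g$n_pixels)
  for (v in seq_len(n_stim) - 1L) {
    pw <- (v %% design$wedge_volumes_per_cycle) / design$wedge_volumes_per_cycle
    alpha <- wedge_angle_at(pw, design, cw = cw)
    wedge <- in_disc & abs(wrap_deg(ang - alpha)) <= design$wedge_width_deg / 2
    k <- v %% design$ring_volumes_per_cycle
    if (!cw) k <- design$ring_volumes_per_cycle - 1L - k
    rad <- ring_radii_at(k, design, e_min, R)
    ring <- r >= rad["lo"] & r <= rad["hi"] & in_disc
    masks[v + 1L, ] <- wedge | ring
  }
  is_blank <- c(rep(FALSE, n_stim), rep(TRUE, nb))
  new_aperture_sequence(masks, tr_s, condition = "wedge_ring",
                        direction = direction, is_blank = is_blank,
                        grid = g, design = design)
}

#' Photic-burst aperture sequence
#'
#' The run used for per-subject HRF estimation: a full-field aperture (the
#' whole stimulated disc) shown for one volume, followed by 11 blank
#' volumes, repeated 10 times.
#'
#' @inheritParams bar_sequence
#' @param n_trials number of burst repetitions.
#' @param volumes_per_trial volumes per repetition (1 burst + blanks).
#' @return an \code{aperture_sequence} of
#'   \code{n_trials * volumes_per_trial} volumes.
#' @export
photic_sequence <- function(cfg = carrier_config(), tr_s = 2.55,
                            n_trials = 10, volumes_per_trial = 12) {
  g <- cfg$grid
  disc <- sqrt(g$x^2 + g$y^2) <= cfg$max_ecc_deg
  n <- n_trials * volumes_per_trial
  masks <- matrix(FALSE, nrow = n, ncol = g$n_pixels)
  onsets <- (seq_len(n_trials) - 1L) * volumes_per_trial + 1L
  masks[onsets, ] <- rep(disc, each = n_trials)
  is_blank <- rep(TRUE, n)
  is_blank[onsets] <- FALSE
  ap <- new_aperture_sequence(masks, tr_s, condition = "photic",
                              direction = "full_field", is_blank = is_blank,
                              grid = g)
  attr(ap, "trial_onsets") <- onsets
  ap
}

#' Full mapping-session schedule
#'
#' The ten mapping runs of one scanning session: two cardinal and two
#' oblique size-invariant bar runs, two cardinal and two oblique
#' logarithmically-scaled bar runs (each pair with opposite sweep signs),
#' and two wedge-and-ring runs in opposite directions.
#'
#' @inheritParams bar_sequence
#' @return named list of ten \code{aperture_sequence} objects; attribute
#'   \code{total_volumes} gives the session volume count.
#' @export
session_schedule <- function(design = stimulus_design(),
                             cfg = carrier_config(), tr_s = 2.55) {
  runs <- list(
    bar_card_fwd     = bar_sequence(0, 1, FALSE, design, cfg, tr_s),
    bar_card_rev     = bar_sequence(0, -1, FALSE, design, cfg, tr_s),
    bar_obli_fwd     = bar_sequence(45, 1, FALSE, design, cfg, tr_s),
    bar_obli_rev     = bar_sequence(45, -1, FALSE, design, cfg, tr_s),
    bar_log_card_fwd = bar_sequence(0, 1, TRUE, design, cfg, tr_s),
    bar_log_card_rev = bar_sequence(0, -1, TRUE, design, cfg, tr_s),
    bar_log_obli_fwd = bar_sequence(45, 1, TRUE, design, cfg, tr_s),
    bar_log_obli_rev = bar_sequence(45, -1, TRUE, design, cfg, tr_s),
    wedge_ring_fwd   = wedge_ring_sequence("cw_expand", design, cfg, tr_s),
    wedge_ring_rev   = wedge_ring_sequence("ccw_contract", design, cfg, tr_s)
  )
  attr(runs, "total_volumes") <- sum(vapply(runs, n_volumes, integer(1)))
  runs
}

#' Fixation-task event list
#'
#' Pseudo-random fixation-dot color changes: the run is divided into 200 ms
#' bins and each bin has probability \code{p} of a color change, except a
#' bin immediately following a change. Generated for completeness; the
#' events play no role in pRF modeling.
#'
#' @param duration_s run duration in seconds.
#' @param p per-bin change probability.
#' @param bin_ms bin duration in milliseconds.
#' @param seed RNG seed.
#' @return data frame of event onset times in seconds.
#' @export
fixation_events <- function(duration_s, p = 0.05, bin_ms = 200, seed = 1) {
  n <- floor(duration_s * 1000 / bin_ms)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  draw <- stats::runif(n) < p
  change <- logical(n)
  for (i in seq_len(n)) {
    change[i] <- draw[i] && (i == 1 || !change[i - 1])
  }
  data.frame(onset_s = (which(change) - 1) * bin_ms / 1000)
}
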