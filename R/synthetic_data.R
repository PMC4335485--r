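# Synthetic cortical sheet with ground-truth retinotopy and BOLD simulation.
#
# The sheet emulates the regularities the pipeline is designed to recover:
# a retinotopic gradient (log-spaced eccentricities, uniform polar angles),
# pRF size increasing linearly with eccentricity at a per-region slope, and
# a neighbor graph on which surface smoothing operates.

# run code with a temporary RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Region specification for the synthetic sheet
#'
#' @param name region label (e.g. "V1").
#' @param sigma_intercept,sigma_slope the linear pRF size law
#'   \code{sigma = intercept + slope * eccentricity} for this region.
#' @export
roi_spec <- function(name, sigma_intercept, sigma_slope) {
  list(name = name, sigma_intercept = sigma_intercept,
       sigma_slope = sigma_slope)
}

#' Synthetic cortical sheet with ground-truth pRFs
#'
#' Lays vertices on a regular 2D grid (one row-block per region, so the
#' neighbor graph is connected), assigns log-spaced eccentricities along
#' one grid axis and uniform polar angles along the other, and draws
#' ground-truth Gaussian pRFs whose size follows each region's linear
#' size-eccentricity law. A small seeded jitter decorrelates vertex
#' positions from the exact grid; sigma is computed from the jittered
#' eccentricity so the constructed linear law holds exactly.
#'
#' @param n_vertices requested total vertex count (rounded up so each
#'   region fills a rectangular grid block).
#' @param rois list of \code{\link{roi_spec}} entries.
#' @param max_ecc maximum display eccentricity (degrees); truth
#'   eccentricities stay within it.
#' @param seed RNG seed for the jitter.
#' @param spacing_mm grid spacing of the sheet in millimetres.
#' @param ecc_range range of ground-truth eccentricities (degrees).
#' @param ecc_jitter_sd log-normal SD of the eccentricity jitter.
#' @param angle_jitter_sd polar-angle jitter SD (degrees).
#' @return a \code{cortical_sheet}: vertex coordinates (mm), edge list with
#'   lengths, an igraph neighbor graph, per-vertex truth table
#'   (x0, y0, sigma, beta, ecc, roi) and the generating parameters.
#' @export
make_sheet <- function(n_vertices, rois = list(roi_spec("V1", 0.5, 0.25)),
                       max_ecc = 9, seed = 1, spacing_mm = 2,
                       ecc_range = c(0.5, max_ecc),
                       ecc_jitter_sd = 0.02, angle_jitter_sd = 2) {
  n_roi <- length(rois)
  n_per <- ceiling(n_vertices / n_roi)
  if (n_per < 16) stop("need at least 16 vertices per region")
  if (ecc_range[2] > max_ecc) stop("ecc_range exceeds max_ecc")
  nx <- ceiling(sqrt(n_per))
  ny <- ceiling(n_per / nx)

  ecc_grid <- exp(seq(log(ecc_range[1]), log(ecc_range[2]), length.out = nx))
  rows_total <- ny * n_roi

  col_idx <- rep(rep(seq_len(nx), times = ny), n_roi)
  row_in_roi <- rep(rep(seq_len(ny), each = nx), n_roi)
  roi_idx <- rep(seq_len(n_roi), each = nx * ny)
  row_global <- row_in_roi + (roi_idx - 1L) * ny
  V <- length(col_idx)

  truth <- with_seed(seed, {
    ecc <- ecc_grid[col_idx] * exp(stats::rnorm(V, 0, ecc_jitter_sd))
    ecc <- pmin(ecc, max_ecc)
    ang <- (row_in_roi - 0.5) / ny * 360 +
      stats::rnorm(V, 0, angle_jitter_sd)
    intercept <- vapply(rois, `[[`, numeric(1), "sigma_intercept")[roi_idx]
    slope <- vapply(rois, `[[`, numeric(1), "sigma_slope")[roi_idx]
    sigma <- intercept + slope * ecc
    if (any(sigma <= 0)) stop("size-eccentricity law yields non-positive sigma")
    data.frame(
      vertex = seq_len(V),
      x0 = ecc * cos(ang * pi / 180),
      y0 = ecc * sin(ang * pi / 180),
      sigma = sigma, beta = 1, ecc = ecc, angle_deg = ang %% 360,
      roi = vapply(rois, `[[`, character(1), "name")[roi_idx]
    )
  })

  coords <- cbind(x_mm = (col_idx - 1) * spacing_mm,
                  y_mm = (row_global - 1) * spacing_mm)
  # 4-connected lattice over the stacked grid
  id <- matrix(seq_len(V)[order(row_global, col_idx)],
               nrow = rows_total, ncol = nx, byrow = TRUE)
  horiz <- cbind(as.vector(id[, -nx]), as.vector(id[, -1]))
  vert <- cbind(as.vector(id[-rows_total, ]), as.vector(id[-1, ]))
  edges <- data.frame(from = c(horiz[, 1], vert[, 1]),
                      to = c(horiz[, 2], vert[, 2]),
                      length = spacing_mm)
  graph <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = seq_len(V))
  )

  structure(list(
    coords = coords, edges = edges, graph = graph, truth = truth,
    roi = truth$roi, n_vertices = V, max_ecc = max_ecc,
    spacing_mm = spacing_mm, seed = seed,
    map_params = data.frame(
      roi = vapply(rois, `[[`, character(1), "name"),
      sigma_intercept = vapply(rois, `[[`, numeric(1), "sigma_intercept"),
      sigma_slope = vapply(rois, `[[`, numeric(1), "sigma_slope")
    )
  ), class = "cortical_sheet")
}

#' @export
print.cortical_sheet <- function(x, ...) {
  cat(sprintf("<cortical_sheet> %d vertices, %d region(s), max ecc %g deg\n",
              x$n_vertices, nrow(x$map_params), x$max_ecc))
  invisible(x)
}

#' Add difference-of-Gaussians ground truth
#'
#' Converts the sheet's ground truth to a center-surround (DoG) profile:
#' the neural response becomes the center Gaussian sum minus
#' \code{surround_amp} times the sum of a wider surround Gaussian
#' (\code{surround_ratio} times the center sigma). Used to probe how
#' surround suppression biases plain-Gaussian size estimates under
#' different aperture configurations.
#'
#' The defaults describe a moderate surround: twice the center width at a
#' fifth of its peak amplitude. When \code{surround_amp * surround_ratio^2}
#' reaches 1 the integrated surround cancels the integrated center, the
#' full-field response is non-positive and size estimates degenerate; a
#' warning flags that regime.
#'
#' @param sheet a \code{cortical_sheet}.
#' @param surround_ratio surround/center sigma ratio (> 1).
#' @param surround_amp surround amplitude relative to center, in [0, 1).
#' @export
make_dog_truth <- function(sheet, surround_ratio = 2, surround_amp = 0.2) {
  if (surround_ratio <= 1) stop("surround_ratio must exceed 1")
  if (surround_amp < 0 || surround_amp >= 1) {
    stop("surround_amp must be in [0, 1)")
  }
  if (surround_amp * surround_ratio^2 >= 1) {
    warning("surround integral cancels the center (amp * ratio^2 >= 1); net full-field response is non-positive")
  }
  sheet$truth$surround_sigma <- sheet$truth$sigma * surround_ratio
  sheet$truth$surround_amp <- surround_amp
  sheet
}

#' Noise specification for BOLD simulation
#'
#' @param cnr contrast-to-noise ratio: per-vertex peak of the noiseless
#'   prediction divided by the noise SD. \code{Inf} disables noise.
#' @param ar1_rho lag-1 temporal autocorrelation of the noise, in [0, 1).
#' @param seed RNG seed.
#' @export
noise_spec <- function(cnr = 3, ar1_rho = 0, seed = 1) {
  if (cnr <= 0) stop("cnr must be positive")
  if (ar1_rho < 0 || ar1_rho >= 1) stop("ar1_rho must be in [0, 1)")
  list(cnr = cnr, ar1_rho = ar1_rho, seed = seed)
}

# noiseless predictions for all sheet vertices under one aperture run:
# returns a T x V matrix (unconvolved neural level)
sheet_neural <- function(sheet, apertures) {
  g <- apertures$grid
  tr <- sheet$truth
  d2 <- outer(g$x, tr$x0, "-")^2 + outer(g$y, tr$y0, "-")^2
  W <- exp(-sweep(d2, 2, 2 * tr$sigma^2, "/"))
  neural <- apertures$masks %*% W
  if (!is.null(tr$surround_amp)) {
    Ws <- exp(-sweep(d2, 2, 2 * tr$surround_sigma^2, "/"))
    neural <- neural - sweep(apertures$masks %*% Ws, 2, tr$surround_amp, "*")
  }
  neural
}

#' Simulate BOLD time series on a synthetic sheet
#'
#' Runs the forward model generatively for every vertex's ground-truth pRF
#' under the given aperture sequence(s), convolves with the HRF, scales by
#' beta, and adds AR(1) Gaussian noise calibrated so that the per-vertex
#' peak of the noiseless prediction divided by the noise SD equals the
#' requested CNR. Vertices whose pRF is never stimulated (zero peak)
#' receive noise at the median stimulated-vertex level. Units are percent
#' signal change.
#'
#' @param sheet a \code{cortical_sheet}.
#' @param apertures an \code{aperture_sequence} or list of them; runs are
#'   convolved independently and concatenated in time.
#' @param hrf an \code{hrf_kernel} or \code{hrf_params}.
#' @param noise a \code{\link{noise_spec}}.
#' @return numeric matrix, vertices x time; attribute \code{run_lengths}
#'   records the per-run volume counts.
#' @export
simulate_bold <- function(sheet, apertures, hrf = hrf_params(),
                          noise = noise_spec()) {
  runs <- if (inherits(apertures, "aperture_sequence")) {
    list(apertures)
  } else apertures
  k <- as_hrf_kernel(hrf)
  sig_runs <- lapply(runs, function(ap) {
    neural <- sheet_neural(sheet, ap)
    m <- ap$tr_s / k$params$dt
    if (abs(m - round(m)) > 1e-6) {
      stop("HRF dt must equal the TR or an integer up-sampling of it")
    }
    m <- as.integer(round(m))
    if (m == 1L) {
      conv_causal_mat(neural, k$h)
    } else {
      up <- neural[rep(seq_len(nrow(neural)), each = m), , drop = FALSE]
      conv_causal_mat(up, k$h)[(seq_len(nrow(neural)) - 1L) * m + 1L, ,
                               drop = FALSE]
    }
  })
  signal <- do.call(rbind, sig_runs)
  signal <- sweep(signal, 2, sheet$truth$beta, "*")

  if (is.finite(noise$cnr)) {
    peak <- apply(abs(signal), 2, max)
    ref <- stats::median(peak[peak > 0])
    sd_v <- ifelse(peak > 0, peak, ref) / noise$cnr
    eps <- with_seed(noise$seed, {
      z <- matrix(stats::rnorm(length(signal)), nrow = nrow(signal))
      if (noise$ar1_rho > 0) {
        z <- apply(z * sqrt(1 - noise$ar1_rho^2), 2, function(col) {
          as.numeric(stats::filter(col, noise$ar1_rho, method = "recursive"))
        })
      }
      z
    })
    signal <- signal + sweep(eps, 2, sd_v, "*")
  }
  out <- t(signal)
  attr(out, "run_lengths") <- vapply(sig_runs, nrow, integer(1))
  out
}
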