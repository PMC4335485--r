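# Forward model: 2D Gaussian pRF -> neural prediction -> BOLD prediction.

#' Gaussian pRF
#'
#' The four-parameter encoding model of a vertex's population receptive
#' field: visual-field center \code{(x0, y0)} in degrees, spatial spread
#' \code{sigma} (standard deviation of the 2D Gaussian, degrees) and
#' response amplitude \code{beta}.
#'
#' @param x0,y0 receptive-field center (degrees of visual angle).
#' @param sigma spatial spread, must be positive.
#' @param beta signal amplitude (arbitrary units).
#' @export
gaussian_prf <- function(x0, y0, sigma, beta = 1) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (!is.finite(beta)) stop("beta must be finite")
  structure(list(x0 = x0, y0 = y0, sigma = sigma, beta = beta),
            class = "gaussian_prf")
}

#' @export
print.gaussian_prf <- function(x, ...) {
  cat(sprintf("<gaussian_prf> center (%.2f, %.2f) deg, sigma %.2f deg, beta %.3g\n",
              x$x0, x$y0, x$sigma, x$beta))
  invisible(x)
}

#' Gaussian receptive-field weights on a pixel grid
#'
#' \code{w(x, y) = exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma^2))}, with unit
#' peak at the pRF center.
#'
#' @param prf a \code{gaussian_prf} (or list with x0, y0, sigma).
#' @param grid a \code{vf_grid}.
#' @return numeric vector of length \code{grid$n_pixels}, aligned with
#'   \code{grid$x}/\code{grid$y}.
#' @export
gaussian_weights <- function(prf, grid) {
  if (prf$sigma <= 0) stop("sigma must be positive")
  exp(-((grid$x - prf$x0)^2 + (grid$y - prf$y0)^2) / (2 * prf$sigma^2))
}

#' Predicted neural time series
#'
#' At each volume, the sum of Gaussian receptive-field weights falling
#' inside the binary stimulus aperture. Blank volumes give exactly zero.
#'
#' @param prf a \code{gaussian_prf}.
#' @param apertures an \code{aperture_sequence}.
#' @return numeric vector, one value per volume.
#' @export
neural_prediction <- function(prf, apertures) {
  w <- gaussian_weights(prf, apertures$grid)
  as.numeric(apertures$masks %*% w)
}

#' Double-gamma HRF parameters
#'
#' The three free shape parameters of the hemodynamic response function:
#' the delay of the positive response peak, the delay of the undershoot
#' peak, and the amplitude ratio between response and undershoot. Each
#' component is a gamma-shaped impulse response with fixed shape exponent,
#' peaking at its delay.
#'
#' @param response_delay positive-peak time (s).
#' @param undershoot_delay undershoot-peak time (s).
#' @param ratio response:undershoot amplitude ratio.
#' @param dt kernel sampling interval (s).
#' @param shape fixed gamma shape exponent (power of t).
#' @export
hrf_params <- function(response_delay = 6, undershoot_delay = 16,
                       ratio = 6, dt = 2.55, shape = 5) {
  if (response_delay <= 0 || undershoot_delay <= 0) {
    stop("delays must be positive")
  }
  if (ratio <= 0) stop("ratio must be positive")
  structure(list(response_delay = response_delay,
                 undershoot_delay = undershoot_delay,
                 ratio = ratio, dt = dt, shape = shape),
            class = "hrf_params")
}

#' @export
print.hrf_params <- function(x, ...) {
  cat(sprintf("<hrf_params> response %.2f s, undershoot %.2f s, ratio %.2f (dt %.3g s)\n",
              x$response_delay, x$undershoot_delay, x$ratio, x$dt))
  invisible(x)
}

# unit-peak gamma-shaped impulse response peaking at t = d
gamma_bump <- function(t, d, shape) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / d)^shape * exp(-shape * (t[pos] - d) / d)
  out
}

#' Sampled double-gamma HRF kernel
#'
#' \code{h(t) = g(t; response_delay) - g(t; undershoot_delay) / ratio},
#' where each g is a unit-peak gamma bump; the difference is renormalized
#' to unit peak. \code{h(0) = 0} and the late tail is negative
#' (the undershoot) whenever the undershoot peaks later than the response.
#'
#' @param params an \code{hrf_params}.
#' @param duration kernel length (s); must cover the response delay.
#' @return an \code{hrf_kernel}: list with sample times \code{t}, values
#'   \code{h}, and the generating \code{params}.
#' @export
double_gamma <- function(params, duration = 32) {
  if (duration < params$response_delay) {
    stop("duration must be at least the response delay")
  }
  t <- seq(0, duration, by = params$dt)
  h <- gamma_bump(t, params$response_delay, params$shape) -
    gamma_bump(t, params$undershoot_delay, params$shape) / params$ratio
  h <- h / max(h)
  structure(list(t = t, h = h, params = params), class = "hrf_kernel")
}

# causal discrete convolution, truncated to length(x)
conv_causal <- function(x, h) {
  nx <- length(x)
  if (nx == 0) return(numeric(0))
  stats::convolve(x, rev(h), type = "open")[seq_len(nx)]
}

# columnwise causal convolution of a T x C matrix with kernel h (FFT-based)
conv_causal_mat <- function(m, h) {
  n <- nrow(m)
  L <- stats::nextn(n + length(h) - 1L)
  fh <- stats::fft(c(h, rep(0, L - length(h))))
  fm <- stats::mvfft(rbind(m, matrix(0, L - n, ncol(m))))
  out <- Re(stats::mvfft(fm * fh, inverse = TRUE)) / L
  out[seq_len(n), , drop = FALSE]
}

#' Predicted BOLD time series
#'
#' Causal convolution of the neural prediction with the HRF kernel at the
#' volume sampling rate (or an integer up-sampling of it), truncated to the
#' run length and scaled by the pRF amplitude \code{beta}.
#'
#' @param prf a \code{gaussian_prf}.
#' @param apertures an \code{aperture_sequence}.
#' @param hrf an \code{hrf_kernel} (from \code{\link{double_gamma}}) or an
#'   \code{hrf_params} object.
#' @return numeric vector, one value per volume.
#' @export
bold_prediction <- function(prf, apertures, hrf) {
  k <- as_hrf_kernel(hrf)
  n <- neural_prediction(prf, apertures)
  convolve_to_tr(n, k, apertures$tr_s) * prf$beta
}

as_hrf_kernel <- function(hrf) {
  if (inherits(hrf, "hrf_kernel")) hrf else double_gamma(hrf)
}

# convolve a TR-resolution neural series with a kernel sampled at dt,
# where dt divides the TR; returns the series sampled at volume onsets.
convolve_to_tr <- function(neural, kernel, tr_s) {
  dt <- kernel$params$dt
  m <- tr_s / dt
  if (abs(m - round(m)) > 1e-6) {
    stop("HRF dt must equal the TR or an integer up-sampling of it")
  }
  m <- as.integer(round(m))
  if (m == 1L) return(conv_causal(neural, kernel$h))
  up <- rep(neural, each = m)
  y <- conv_causal(up, kernel$h)
  y[(seq_along(neural) - 1L) * m + 1L]
}
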