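# Per-subject HRF estimation from the photic-burst run.

#' Trial-averaged photic epoch
#'
#' Splits the photic-burst run into its trial epochs, rejects outlier
#' values (more than \code{sd_thresh} standard deviations from the
#' across-trial mean at each epoch time point) and averages the surviving
#' trials. When a vertices x time matrix is supplied, vertices are first
#' pooled by averaging the most visually responsive set: those in the top
#' decile of spectral power at the burst repetition frequency.
#'
#' @param series numeric vector (one pooled series) or vertices x time
#'   matrix for the photic run.
#' @param trial_onsets volume indices (1-based) of the burst onsets; must
#'   be evenly spaced.
#' @param epoch_len epoch length in volumes.
#' @param sd_thresh outlier rejection threshold in SD units.
#' @param pool_quantile fraction of vertices retained when pooling a
#'   matrix (by stimulus-frequency power).
#' @return numeric vector of length \code{epoch_len}: the averaged epoch,
#'   with attribute \code{n_excluded} (outliers removed).
#' @export
trial_average <- function(series, trial_onsets, epoch_len = 12,
                          sd_thresh = 1.5, pool_quantile = 0.9) {
  if (length(trial_onsets) < 2) stop("need at least 2 trials")
  gaps <- diff(trial_onsets)
  if (length(unique(gaps)) > 1) stop("trial onsets must be evenly spaced")
  if (is.matrix(series)) {
    n_cyc <- length(trial_onsets)
    pw <- apply(series, 1, function(s) fundamental_phase(s, n_cyc)["power"])
    keep <- pw >= stats::quantile(pw, pool_quantile)
    series <- colMeans(series[keep, , drop = FALSE])
  }
  epochs <- t(vapply(trial_onsets,
                     function(o) series[o:(o + epoch_len - 1L)],
                     numeric(epoch_len)))
  avg <- numeric(epoch_len)
  n_excluded <- 0L
  for (j in seq_len(epoch_len)) {
    x <- epochs[, j]
    m <- mean(x)
    s <- stats::sd(x)
    keep <- if (s > 0) abs(x - m) <= sd_thresh * s else rep(TRUE, length(x))
    if (!any(keep)) {
      stop(sprintf("all trials rejected as outliers at epoch time point %d", j))
    }
    n_excluded <- n_excluded + sum(!keep)
    avg[j] <- mean(x[keep])
  }
  attr(avg, "n_excluded") <- n_excluded
  avg
}

#' Fit the double-gamma HRF to an averaged epoch
#'
#' Least-squares fit of the three free shape parameters (response delay,
#' undershoot delay, response:undershoot ratio) plus a nuisance amplitude
#' to the trial-averaged photic epoch. The amplitude is profiled out by
#' linear least squares inside a Nelder-Mead search over the shape
#' parameters, started from a small lattice of response delays for
#' robustness.
#'
#' @param avg_epoch averaged epoch (percent signal change), one value per
#'   volume from burst onset.
#' @param dt volume spacing in seconds (the TR).
#' @param shape fixed gamma shape exponent (see \code{\link{hrf_params}}).
#' @param starts response-delay starting values for the multi-start search.
#' @return an \code{hrf_params} object with extra fields: \code{amplitude},
#'   \code{rsq}, and \code{reliable} (FALSE when the optimizer failed to
#'   converge or the fitted amplitude is negligible). Never throws on
#'   non-convergence.
#' @export
fit_hrf <- function(avg_epoch, dt, shape = 5, starts = c(4, 6, 8)) {
  if (length(avg_epoch) < 11) stop("epoch must be at least 11 volumes")
  t <- (seq_along(avg_epoch) - 1L) * dt
  ss_tot <- sum((avg_epoch - mean(avg_epoch))^2)

  shape_sse <- function(p) {
    d1 <- p[1]; d2 <- p[2]; ratio <- p[3]
    if (d1 <= 0 || d2 <= 0 || ratio <= 0) return(list(sse = Inf))
    h <- gamma_bump(t, d1, shape) - gamma_bump(t, d2, shape) / ratio
    pk <- max(h)
    if (pk <= 0) return(list(sse = Inf))
    h <- h / pk
    denom <- sum(h^2)
    a <- if (denom > 0) sum(avg_epoch * h) / denom else 0
    list(sse = sum((avg_epoch - a * h)^2), amplitude = a)
  }

  best <- NULL
  for (d1_0 in starts) {
    fit <- stats::optim(c(d1_0, 16, 6), function(p) shape_sse(p)$sse,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 5000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  res <- shape_sse(best$par)
  out <- hrf_params(response_delay = best$par[1],
                    undershoot_delay = best$par[2],
                    ratio = best$par[3], dt = dt, shape = shape)
  out$amplitude <- res$amplitude
  out$rsq <- if (ss_tot > 0) 1 - res$sse / ss_tot else NA_real_
  epoch_scale <- stats::sd(avg_epoch)
  out$reliable <- best$convergence == 0 && is.finite(res$amplitude) &&
    epoch_scale > 0 && abs(res$amplitude) > 1e-6 * epoch_scale
  out
}

#' Estimate the HRF from a photic-burst run
#'
#' Convenience wrapper: trial-average the run (with outlier rejection and
#' vertex pooling) and fit the double-gamma model.
#'
#' @param data vertices x time matrix (or vector) for the photic run.
#' @param apertures the \code{\link{photic_sequence}} used (supplies trial
#'   onsets and TR).
#' @param ... passed to \code{\link{fit_hrf}}.
#' @export
estimate_hrf <- function(data, apertures, ...) {
  onsets <- attr(apertures, "trial_onsets")
  epoch_len <- if (length(onsets) > 1) diff(onsets)[1] else 12L
  avg <- trial_average(data, onsets, epoch_len = epoch_len)
  fit_hrf(avg, dt = apertures$tr_s, ...)
}
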