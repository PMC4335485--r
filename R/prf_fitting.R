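# Two-stage pRF estimation: exhaustive coarse grid search on smoothed data,
# Nelder-Mead refinement of (x0, y0, sigma, beta) on unsmoothed data.

# stack a list of aperture runs sharing one grid into a single time axis
stack_runs <- function(apertures) {
  runs <- if (inherits(apertures, "aperture_sequence")) {
    list(apertures)
  } else apertures
  g <- runs[[1]]$grid
  for (ap in runs) {
    if (!identical(ap$grid$xs, g$xs)) stop("all runs must share one pixel grid")
  }
  lens <- vapply(runs, n_volumes, integer(1))
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  list(masks = do.call(rbind, lapply(runs, `[[`, "masks")),
       grid = g, tr_s = runs[[1]]$tr_s,
       run_rows = Map(seq, starts, ends),
       n_volumes = sum(lens))
}

# per-run causal convolution of a stacked T x C prediction matrix
conv_by_run <- function(m, stacked, kernel) {
  for (rows in stacked$run_rows) {
    m[rows, ] <- conv_causal_mat(m[rows, , drop = FALSE], kernel$h)
  }
  m
}

#' Coarse-fit search grid
#'
#' The three-dimensional candidate space of the coarse stage: pRF centers
#' on a square lattice (default 2.4-degree steps) within the stimulated
#' bounds, crossed with exponentially spaced sigma levels (default 34
#' steps from 0.32 to 32 degrees). One unit-amplitude HRF-convolved
#' prediction is generated per candidate; the coarse stage is
#' scale-invariant so amplitude is omitted. Candidates are ordered by
#' sigma, then by center eccentricity, which makes the argmax tie-break
#' deterministic (smallest sigma, then most foveal center).
#'
#' @param apertures an \code{aperture_sequence} or list of runs (convolved
#'   independently, concatenated in time).
#' @param hrf an \code{hrf_kernel} or \code{hrf_params}.
#' @param xy_step center lattice step (degrees).
#' @param sigma_range,n_sigma endpoints and count of the exponential sigma
#'   ladder.
#' @return a \code{search_grid}: candidate table and T x C prediction
#'   matrix, plus the stacked aperture container used to build it.
#' @export
build_search_grid <- function(apertures, hrf, xy_step = 2.4,
                              sigma_range = c(0.32, 32), n_sigma = 34) {
  stacked <- stack_runs(apertures)
  kernel <- as_hrf_kernel(hrf)
  R <- stacked$grid$max_ecc_deg
  xc <- seq(-R, R, by = xy_step)
  if (length(xc) < 2) stop("empty candidate bounds")
  sc <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                length.out = n_sigma))
  cand <- expand.grid(x0 = xc, y0 = xc, sigma = sc,
                      KEEP.OUT.ATTRS = FALSE)
  cand <- cand[order(cand$sigma, cand$x0^2 + cand$y0^2), ]
  rownames(cand) <- NULL

  g <- stacked$grid
  d2 <- outer(g$x, cand$x0, "-")^2 + outer(g$y, cand$y0, "-")^2
  W <- exp(-sweep(d2, 2, 2 * cand$sigma^2, "/"))
  pred <- conv_by_run(stacked$masks %*% W, stacked, kernel)

  structure(list(candidates = cand, predictions = pred,
                 stacked = stacked, kernel = kernel,
                 xy_step = xy_step, sigma_range = sigma_range,
                 n_sigma = n_sigma),
            class = "search_grid")
}

#' @export
print.search_grid <- function(x, ...) {
  cat(sprintf("<search_grid> %d candidates (%d sigma levels), %d volumes\n",
              nrow(x$candidates), x$n_sigma, x$stacked$n_volumes))
  invisible(x)
}

#' Gaussian smoothing on the cortical sheet
#'
#' Per-time-point Gaussian smoothing in geodesic (graph) distance along the
#' vertex neighbor graph, the surface analogue of the spherical smoothing
#' used before coarse fitting (8.3 mm FWHM) and before phase-encoded
#' analysis (5 mm FWHM). The Gaussian kernel is normalized to be doubly
#' stochastic (Sinkhorn balancing), so a spatially constant map passes
#' through unchanged and the spatial mean of every time point is preserved.
#'
#' @param data vertices x time matrix.
#' @param sheet a \code{cortical_sheet} supplying the neighbor graph.
#' @param fwhm_mm kernel full width at half maximum in mm; 0 is the
#'   identity.
#' @return smoothed matrix of the same shape.
#' @export
smooth_on_sheet <- function(data, sheet, fwhm_mm) {
  if (fwhm_mm <= 0) return(data)
  if (nrow(data) != sheet$n_vertices) {
    stop("data rows must match sheet vertices")
  }
  comp <- igraph::components(sheet$graph)
  if (comp$no > 1) {
    warning(sprintf("sheet graph has %d components; smoothing acts within components",
                    comp$no))
  }
  s <- fwhm_mm / (2 * sqrt(2 * log(2)))
  D <- igraph::distances(sheet$graph, weights = sheet$edges$length)
  K <- exp(-D^2 / (2 * s^2))
  # Sinkhorn balancing to a doubly stochastic kernel
  u <- rep(1, nrow(K))
  v <- rep(1, nrow(K))
  for (i in seq_len(500)) {
    u <- 1 / as.numeric(K %*% v)
    v <- 1 / as.numeric(crossprod(K, u))
    S <- K * outer(u, v)
    if (max(abs(rowSums(S) - 1)) < 1e-12 &&
        max(abs(colSums(S) - 1)) < 1e-12) break
  }
  out <- S %*% data
  dimnames(out) <- dimnames(data)
  out
}

#' Coarse fit: exhaustive correlation search
#'
#' For each vertex, the Pearson correlation between its (smoothed) time
#' series and every candidate prediction; the argmax candidate seeds the
#' fine fit. Vertices whose best correlation is not positive, or whose
#' squared correlation does not exceed \code{incl_r2}, are excluded from
#' fine fitting. Zero-variance series are excluded rather than raising an
#' error.
#'
#' @param data vertices x time matrix (smoothed).
#' @param grid a \code{search_grid}.
#' @param incl_r2 inclusion threshold on the squared correlation
#'   (strictly greater-than).
#' @return data frame: vertex, start candidate (x0, y0, sigma), r_max,
#'   r2_coarse, included.
#' @export
coarse_fit <- function(data, grid, incl_r2 = 0.05) {
  if (ncol(data) != nrow(grid$predictions)) {
    stop("series length must match grid predictions")
  }
  Tn <- ncol(data)
  dm <- data - rowMeans(data)
  dsd <- sqrt(rowSums(dm^2))
  pm <- grid$predictions
  pm <- sweep(pm, 2, colMeans(pm), "-")
  psd <- sqrt(colSums(pm^2))
  ok_p <- psd > 0
  pm[, ok_p] <- sweep(pm[, ok_p, drop = FALSE], 2, psd[ok_p], "/")
  pm[, !ok_p] <- 0
  ok_v <- dsd > 0
  r <- matrix(0, nrow(data), ncol(pm))
  if (any(ok_v)) {
    r[ok_v, ] <- (dm[ok_v, , drop = FALSE] / dsd[ok_v]) %*% pm
  }
  best <- max.col(r, ties.method = "first")
  r_max <- r[cbind(seq_len(nrow(r)), best)]
  cand <- grid$candidates[best, ]
  out <- data.frame(vertex = seq_len(nrow(data)),
                    x0 = cand$x0, y0 = cand$y0, sigma = cand$sigma,
                    r_max = r_max, r2_coarse = r_max^2)
  out$included <- ok_v & out$r_max > 0 & out$r2_coarse > incl_r2
  out
}

# single-vertex prediction machinery shared by fine_fit and cross-validation
predict_bold_stacked <- function(x0, y0, sigma, beta, stacked, kernel) {
  g <- stacked$grid
  w <- exp(-((g$x - x0)^2 + (g$y - y0)^2) / (2 * sigma^2))
  n <- as.numeric(stacked$masks %*% w)
  out <- numeric(length(n))
  for (rows in stacked$run_rows) {
    out[rows] <- conv_causal(n[rows], kernel$h)
  }
  out * beta
}

#' Fine fit: Nelder-Mead refinement
#'
#' Simplex minimization of the squared residuals between the unsmoothed
#' vertex series and the model prediction over (x0, y0, sigma, beta),
#' started from the coarse-fit candidate with beta initialized by
#' least-squares projection. Non-positive sigma is repelled by an infinite
#' objective. Goodness of fit is the coefficient of determination
#' 1 - SS_res / SS_tot on the unsmoothed data.
#'
#' @param series unsmoothed time series (length = total volumes).
#' @param start list or row with starting x0, y0, sigma.
#' @param apertures an \code{aperture_sequence}, list of runs, or the
#'   stacked container from a \code{search_grid}.
#' @param hrf an \code{hrf_kernel} or \code{hrf_params}.
#' @param reltol simplex relative tolerance.
#' @param maxit iteration cap (default 400 per free parameter).
#' @return one-row data frame: x0, y0, sigma, beta, r2_fine, converged.
#'   On non-convergence the starting values are retained and
#'   \code{converged} is \code{FALSE}.
#' @export
fine_fit <- function(series, start, apertures, hrf,
                     reltol = 1e-4, maxit = 1600) {
  stacked <- if (is.list(apertures) && !is.null(apertures$masks)) {
    apertures
  } else stack_runs(apertures)
  kernel <- as_hrf_kernel(hrf)
  if (length(series) != stacked$n_volumes) {
    stop("series length must match the aperture sequence")
  }
  ss_tot <- sum((series - mean(series))^2)

  b0 <- predict_bold_stacked(start$x0, start$y0, start$sigma, 1,
                             stacked, kernel)
  denom <- sum(b0^2)
  beta0 <- if (denom > 0) sum(series * b0) / denom else 0

  obj <- function(p) {
    if (p[3] <= 0) return(Inf)
    pred <- predict_bold_stacked(p[1], p[2], p[3], p[4], stacked, kernel)
    sum((series - pred)^2)
  }
  p0 <- c(start$x0, start$y0, start$sigma, beta0)
  sse0 <- obj(p0)
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit))
  converged <- fit$convergence == 0
  p <- if (converged) fit$par else p0
  sse <- if (converged) fit$value else sse0
  data.frame(x0 = p[1], y0 = p[2], sigma = p[3], beta = p[4],
             r2_fine = if (ss_tot > 0) 1 - sse / ss_tot else NA_real_,
             converged = converged)
}

#' Fit the pRF model across a sheet
#'
#' The full two-stage estimation: smooth the data on the cortical sheet,
#' run the exhaustive coarse search on the smoothed series, then refine
#' every included vertex on its unsmoothed series.
#'
#' @param data vertices x time matrix (percent signal change, unsmoothed).
#' @param sheet a \code{cortical_sheet} (geometry for smoothing).
#' @param grid a \code{search_grid} built on the same aperture runs.
#' @param fwhm_mm smoothing kernel FWHM before the coarse stage (mm).
#' @param incl_r2 coarse-stage inclusion threshold.
#' @param reltol,maxit fine-stage simplex settings.
#' @return data frame with one row per vertex: vertex_id, x0, y0, sigma,
#'   beta, r2_coarse, r2_fine, converged, included. Excluded vertices keep
#'   their coarse candidate and NA fine parameters.
#' @export
fit_prf <- function(data, sheet, grid, fwhm_mm = 8.3, incl_r2 = 0.05,
                    reltol = 1e-4, maxit = 1600) {
  sm <- smooth_on_sheet(data, sheet, fwhm_mm)
  coarse <- coarse_fit(sm, grid, incl_r2 = incl_r2)
  out <- data.frame(vertex_id = coarse$vertex,
                    x0 = coarse$x0, y0 = coarse$y0, sigma = coarse$sigma,
                    beta = NA_real_, r2_coarse = coarse$r2_coarse,
                    r2_fine = NA_real_, converged = NA,
                    included = coarse$included)
  idx <- which(coarse$included)
  for (i in idx) {
    f <- fine_fit(data[i, ], coarse[i, ], grid$stacked, grid$kernel,
                  reltol = reltol, maxit = maxit)
    out[i, c("x0", "y0", "sigma", "beta", "r2_fine")] <-
      f[c("x0", "y0", "sigma", "beta", "r2_fine")]
    out$converged[i] <- f$converged
  }
  out
}
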