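test_that("search grid respects bounds, spacing and the sigma ladder", {
  grid <- build_search_grid(bar_run_coarse(), kernel_default())
  cand <- grid$candidates
  expect_true(all(abs(cand$x0) <= 9 & abs(cand$y0) <= 9))
  xs <- sort(unique(cand$x0))
  expect_equal(diff(xs), rep(2.4, length(xs) - 1))
  expect_equal(min(xs), -9)
  sig <- sort(unique(cand$sigma))
  expect_length(sig, 34)
  expect_equal(range(sig), c(0.32, 32))
  # consecutive sigma ratio constant (exponential ladder)
  expect_equal(diff(log(sig)), rep(diff(log(sig))[1], 33))
  expect_equal(nrow(grid$predictions), 144)
  expect_equal(ncol(grid$predictions), nrow(cand))
})

test_that("sheet smoothing is doubly stochastic in effect", {
  sheet <- sheet_small()
  V <- sheet$n_vertices
  set.seed(3)
  dat <- matrix(rnorm(V * 7), V, 7)
  sm <- smooth_on_sheet(dat, sheet, fwhm_mm = 8.3)
  # constants pass through unchanged
  const <- matrix(5, V, 3)
  expect_equal(smooth_on_sheet(const, sheet, 8.3), const, tolerance = 1e-9)
  # the spatial mean of every time point is preserved
  expect_equal(colMeans(sm), colMeans(dat), tolerance = 1e-9)
  # smoothing is averaging: per-timepoint variance cannot increase
  expect_true(all(apply(sm, 2, var) <= apply(dat, 2, var) + 1e-12))
  # fwhm 0 is the identity
  expect_identical(smooth_on_sheet(dat, sheet, 0), dat)
  expect_error(smooth_on_sheet(dat[-1, ], sheet, 5), "must match")
})

test_that("coarse fit equals an independent exhaustive re-implementation", {
  grid <- cached("grid_coarse_small", function() {
    build_search_grid(bar_run_coarse(), kernel_default(),
                      xy_step = 3, sigma_range = c(0.5, 4), n_sigma = 5)
  })
  set.seed(17)
  n_vox <- 4
  truth <- data.frame(x0 = runif(n_vox, -5, 5), y0 = runif(n_vox, -5, 5),
                      sigma = runif(n_vox, 0.8, 3))
  ap <- bar_run_coarse()
  dat <- t(vapply(seq_len(n_vox), function(i) {
    bold_prediction(gaussian_prf(truth$x0[i], truth$y0[i], truth$sigma[i]),
                    ap, kernel_default()) + rnorm(144, sd = 0.3)
  }, numeric(144)))
  got <- coarse_fit(dat, grid)
  for (i in seq_len(n_vox)) {
    r <- suppressWarnings(apply(grid$predictions, 2, cor, dat[i, ]))
    r[is.na(r)] <- 0
    expect_equal(got$r_max[i], max(r), tolerance = 1e-10)
    best <- which.max(r)
    expect_equal(got$x0[i], grid$candidates$x0[best])
    expect_equal(got$y0[i], grid$candidates$y0[best])
    expect_equal(got$sigma[i], grid$candidates$sigma[best])
  }
})

test_that("coarse fit excludes flat and anticorrelated series", {
  # a miniature hand-built candidate set with orthogonal predictions
  tt <- seq_len(48)
  p1 <- sin(2 * pi * tt / 24)
  p3 <- cos(2 * pi * tt / 24)
  fake <- structure(list(
    candidates = data.frame(x0 = c(0, 1, 2), y0 = 0, sigma = c(1, 2, 3)),
    predictions = cbind(p1, rep(1, 48), p3)
  ), class = "search_grid")
  dat <- rbind(p1 + 0.01 * p3, -p1, rep(2, 48))
  got <- coarse_fit(dat, fake)
  expect_true(got$included[1])
  expect_equal(got$sigma[1], 1)
  expect_false(got$included[2])  # best correlation not positive
  expect_false(got$included[3])  # zero variance
  expect_error(coarse_fit(dat[, 1:10], fake), "must match")
})

test_that("fine fit recovers an off-grid pRF from a coarse start", {
  runs <- bar_runs_std()
  k <- kernel_default()
  truth <- gaussian_prf(1.3, -2.1, 1.7, beta = 2.4)
  series <- c(bold_prediction(truth, runs[[1]], k),
              bold_prediction(truth, runs[[2]], k))
  start <- list(x0 = 2.4, y0 = -2.4, sigma = 1.4)
  fit <- fine_fit(series, start, runs, k)
  expect_true(fit$converged)
  expect_lt(abs(fit$x0 - 1.3), 0.1)
  expect_lt(abs(fit$y0 + 2.1), 0.1)
  expect_lt(abs(fit$sigma - 1.7) / 1.7, 0.05)
  expect_lt(abs(fit$beta - 2.4) / 2.4, 0.05)
  expect_gt(fit$r2_fine, 0.999)
})

test_that("fine fit keeps the starting values on non-convergence", {
  runs <- bar_runs_std()
  k <- kernel_default()
  truth <- gaussian_prf(1.3, -2.1, 1.7, beta = 2.4)
  series <- c(bold_prediction(truth, runs[[1]], k),
              bold_prediction(truth, runs[[2]], k))
  start <- list(x0 = 2.4, y0 = -2.4, sigma = 1.4)
  fit <- fine_fit(series, start, runs, k, maxit = 1)
  expect_false(fit$converged)
  expect_equal(fit$x0, 2.4)
  expect_equal(fit$y0, -2.4)
  expect_equal(fit$sigma, 1.4)
  expect_error(fine_fit(series[1:10], start, runs, k), "must match")
})

test_that("fit_prf runs the full two-stage pipeline on a small sheet", {
  sheet <- sheet_small()
  runs <- bar_runs_std()
  k <- kernel_default()
  grid <- build_search_grid(runs, k, xy_step = 3,
                            sigma_range = c(0.5, 6), n_sigma = 10)
  dat <- simulate_bold(sheet, runs, k, noise_spec(cnr = Inf))
  dat[1, ] <- 0  # a dead vertex must be excluded, not fatal
  fits <- fit_prf(dat, sheet, grid, fwhm_mm = 0)
  expect_equal(nrow(fits), sheet$n_vertices)
  expect_false(fits$included[1])
  expect_true(is.na(fits$r2_fine[1]))
  ok <- fits$included & fits$converged
  expect_gt(mean(ok[-1]), 0.9)
  err_c <- sqrt((fits$x0[ok] - sheet$truth$x0[ok])^2 +
                  (fits$y0[ok] - sheet$truth$y0[ok])^2)
  err_s <- abs(fits$sigma[ok] - sheet$truth$sigma[ok]) / sheet$truth$sigma[ok]
  expect_lt(median(err_c), 0.1)
  expect_lt(median(err_s), 0.05)
})
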