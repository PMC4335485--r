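test_that("goodness-of-fit thresholding is strict and NA-safe", {
  fits <- data.frame(vertex_id = 1:5, x0 = 0, y0 = 0, sigma = 1,
                     r2_fine = c(0.05, 0.1, 0.100001, NA, 0.5))
  thr <- threshold_fits(fits, r2_min = 0.1)
  expect_equal(thr$vertex_id, c(3L, 5L))
  expect_equal(attr(thr, "n_surviving"), 2L)
  # survivor counts are monotone non-increasing in the threshold
  counts <- vapply(c(0, 0.05, 0.1, 0.3, 0.6),
                   function(th) nrow(threshold_fits(fits, th)), integer(1))
  expect_true(all(diff(counts) <= 0))
  # alternative column
  fits$r2_coarse <- c(0.2, 0.01, 0.01, 0.01, 0.01)
  expect_equal(threshold_fits(fits, 0.1, column = "r2_coarse")$vertex_id, 1L)
})

test_that("blank truncation drops the earliest blanks and stays aligned", {
  ap <- bar_run_coarse()
  dat <- matrix(seq_len(3 * 144), nrow = 3)
  out <- truncate_blanks(ap, dat, keep = 24)
  expect_equal(n_volumes(out$apertures), 120)
  expect_equal(sum(out$apertures$is_blank), 24)
  # the dropped volumes are the 24 earliest blanks (volumes 49-72)
  kept <- setdiff(seq_len(144), 49:72)
  expect_equal(out$data, dat[, kept])
  expect_equal(out$apertures$masks, ap$masks[kept, ])
  # keeping all blanks is a no-op
  all_kept <- truncate_blanks(ap, dat, keep = 48)
  expect_identical(all_kept$data, dat)
  expect_error(truncate_blanks(ap, dat, keep = 100), "fewer blank")
  expect_error(truncate_blanks(ap, dat[, 1:50], keep = 24), "must match")
})

test_that("eccentricity binning averages within then across subjects", {
  fits <- data.frame(
    x0 = c(0.5, 1.5, 0.6, 1.4, 0.5, 1.5), y0 = 0,
    sigma = c(1.0, 1.2, 1.1, 1.3, 0.8, 1.0),
    subject = c(1, 1, 1, 1, 2, 2), roi = "V1")
  out <- bin_sigma_by_eccentricity(fits, bin_deg = 1, max_ecc = 9)
  b0 <- out[out$bin_lo == 0, ]
  # subject 1 mean in [0,1): (1.0 + 1.1)/2 = 1.05; subject 2: 0.8
  expect_equal(b0$mean_sigma, mean(c(1.05, 0.8)))
  expect_equal(b0$sem, sd(c(1.05, 0.8)) / sqrt(2))
  expect_equal(b0$n_subjects, 2)
  # half-open bins: eccentricity exactly 1 falls in [1, 2)
  one <- bin_sigma_by_eccentricity(
    data.frame(x0 = 1, y0 = 0, sigma = 2), bin_deg = 1, max_ecc = 9)
  expect_equal(one$bin_lo, 1)
  # vertices beyond the stimulated field are excluded
  out2 <- bin_sigma_by_eccentricity(
    data.frame(x0 = c(1, 12), y0 = 0, sigma = c(1, 9)),
    bin_deg = 1, max_ecc = 9)
  expect_equal(nrow(out2), 1)
})

test_that("sigma-eccentricity slopes are exact OLS and antisymmetric", {
  set.seed(37)
  ecc <- runif(40, 0.5, 8)
  fits <- data.frame(x0 = ecc, y0 = 0, sigma = 0.1 + 0.2 * ecc,
                     subject = rep(1:2, each = 20), roi = "V1",
                     condition = "a")
  sl <- sigma_ecc_slope(fits)$slopes
  expect_equal(sl$slope, c(0.2, 0.2), tolerance = 1e-10)
  # identical conditions: zero difference, t = 0
  both <- rbind(fits, transform(fits, condition = "b"))
  cmp <- sigma_ecc_slope(both)$comparison
  expect_equal(cmp$mean_diff, 0)
  expect_equal(cmp$t, 0)
  # swapping the condition order negates the comparison
  shift <- rbind(fits, transform(fits, condition = "b",
                                 sigma = sigma + 0.05 * x0))
  c_ab <- sigma_ecc_slope(shift, conditions = c("a", "b"))$comparison
  c_ba <- sigma_ecc_slope(shift, conditions = c("b", "a"))$comparison
  expect_equal(c_ab$mean_diff, -0.05, tolerance = 1e-10)
  expect_equal(c_ba$mean_diff, 0.05, tolerance = 1e-10)
  expect_equal(c_ab$t, -c_ba$t)
  # degenerate inputs are rejected
  expect_error(sigma_ecc_slope(fits[1:2, ]), "at least 3")
  degen <- data.frame(x0 = 1, y0 = 0, sigma = 1:4)
  expect_error(sigma_ecc_slope(degen), "degenerate eccentricity")
  unmatched <- rbind(fits, transform(fits[fits$subject == 1, ],
                                     condition = "b"))
  expect_error(sigma_ecc_slope(unmatched), "matched subjects")
})

test_that("model and phase eccentricity estimates are compared correctly", {
  set.seed(39)
  ecc <- runif(30, 0.5, 8.5)
  prf_fits <- data.frame(vertex_id = 1:30, x0 = ecc, y0 = 0, sigma = 1,
                         r2_fine = 0.6)
  pm <- data.frame(vertex = 1:30, eccentricity_deg = ecc, coh2_ecc = 0.5)
  out <- compare_ecc_estimates(prf_fits, pm, max_ecc = 9)
  expect_equal(out$mean_discrepancy, 0, tolerance = 1e-12)
  expect_equal(unname(out$poly_coef), c(0, 1, 0), tolerance = 1e-8)
  # an inflated foveal phase estimate yields a positive discrepancy
  pm2 <- pm
  pm2$eccentricity_deg <- pm$eccentricity_deg + 0.5
  out2 <- compare_ecc_estimates(prf_fits, pm2, max_ecc = 9)
  expect_equal(out2$mean_discrepancy, 0.5 / 9, tolerance = 1e-9)
  # thresholding applies to both sides; too few shared vertices errors
  prf_fits$r2_fine[1:25] <- 0.01
  expect_error(compare_ecc_estimates(prf_fits, pm, max_ecc = 9),
               "fewer than 10")
})

test_that("goodness-of-fit ANOVA flags a real condition effect", {
  subj <- rep(1:8, times = 3)
  cond <- rep(c("bars_invariant", "bars_log", "wedge_ring"), each = 8)
  set.seed(43)
  subj_eff <- rnorm(8, sd = 0.02)[subj]
  r2 <- 0.2 + c(0.06, 0.0, -0.03)[as.integer(factor(cond))] +
    subj_eff + rnorm(24, sd = 0.01)
  out <- gof_anova(data.frame(subject = subj, condition = cond, r2 = r2))
  expect_equal(out$df, 2)
  expect_equal(out$df_resid, 14)
  expect_lt(out$p, 1e-4)
})
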