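test_that("vf_grid places pixel centers symmetrically around fixation", {
  g <- vf_grid(9, 2)
  expect_s3_class(g, "vf_grid")
  expect_equal(g$nx, 2 * 9 * 2 + 1)
  expect_equal(g$n_pixels, g$nx^2)
  expect_true(any(g$x == 0 & g$y == 0))
  expect_equal(diff(g$xs), rep(0.5, g$nx - 1))
  expect_equal(range(g$xs), c(-9, 9))
  expect_error(vf_grid(-1, 2), "positive")
  expect_error(vf_grid(9, 0), "positive")
})

test_that("carrier phase schedule covers two cycles at the stated rate", {
  cfg <- carrier_config()
  sched <- phase_schedule(cfg)
  expect_equal(nrow(sched), 72)
  expect_equal(sched$theta[1], 0)
  expect_equal(max(sched$theta), 4 * pi * 71 / 72)
  expect_equal(attr(sched, "cycle_s"), 1.152)
  expect_equal(sched$delta[1], 0.5)
  expect_true(all(sched$delta >= 0.25 & sched$delta <= 0.75))
  expect_error(carrier_config(n_phase_steps = 71), "even")
})

test_that("carrier frames are binary inside the disc and mean outside", {
  cfg <- carrier_config(9, 1, edge_band_px = 2)
  fr <- carrier_frame(0, cfg)
  expect_equal(dim(fr), c(19, 19))
  expect_true(all(fr >= 0 & fr <= 1))
  r <- sqrt(outer(cfg$grid$xs^2, rep(1, 19)) +
              outer(rep(1, 19), cfg$grid$xs^2))
  expect_true(all(fr[r > 9] == 0.5))
  core <- fr[r < 9 - 2]  # inside the disc, clear of the fringe
  expect_true(all(core %in% c(0, 1)))
  expect_error(carrier_frame(72, cfg), "out of range")
  expect_error(carrier_frame(-1, cfg), "out of range")
})

test_that("stimulus design validates cycle arithmetic", {
  d <- stimulus_design()
  expect_equal(d$wedge_cycles_per_run * d$wedge_volumes_per_cycle, 120)
  expect_equal(d$ring_cycles_per_run * d$ring_volumes_per_cycle, 120)
  expect_error(stimulus_design(wedge_cycles_per_run = 5),
               "same number of stimulation volumes")
})

test_that("bar runs have the documented block structure", {
  ap <- bar_run_coarse()
  expect_s3_class(ap, "aperture_sequence")
  expect_equal(n_volumes(ap), 144)
  expect_equal(sum(ap$is_blank), 48)
  # blank volumes are all-zero masks
  expect_true(all(!ap$masks[ap$is_blank, ]))
  # stimulation volumes are nonempty and lie within the disc
  r <- sqrt(ap$grid$x^2 + ap$grid$y^2)
  expect_true(all(rowSums(ap$masks[!ap$is_blank, ]) > 0))
  expect_true(all(!ap$masks[, r > 9]))
  expect_error(bar_sequence(30), "direction must be one of")
})

test_that("bar geometry: orientation, width scaling, sweep reversal", {
  cfg <- cfg_coarse()
  ap <- bar_run_coarse()
  g <- ap$grid
  # during the first sweep (direction 0) the bar is a vertical strip:
  # active pixels span a narrow x range at the half-width of the scaled bar
  w <- 2.70 * 9 / 16
  centers <- -9 + (seq_len(24) - 0.5) * (18 / 24)
  for (k in c(1, 12, 24)) {
    on <- ap$masks[k, ]
    expect_true(all(abs(g$x[on] - centers[k]) <= w / 2 + 1e-9))
  }
  # opposite sweep_sign time-reverses each sweep segment
  ap_rev <- bar_sequence(0, -1, FALSE, stimulus_design(), cfg)
  expect_equal(ap_rev$masks[1:24, ], ap$masks[24:1, ])
  expect_equal(ap_rev$masks[25:48, ], ap$masks[48:25, ])
})

test_that("log-scaled bars narrow toward fixation and widen outward", {
  cfg <- cfg_std()
  d <- stimulus_design()
  ap <- bar_sequence(0, 1, TRUE, d, cfg)
  expect_equal(ap$condition, "bar_log")
  # the underlying width law is monotone in |eccentricity| with the
  # documented endpoints
  e <- seq(0, 9, by = 0.1)
  w <- prfmap:::log_bar_width(e, 0.06, 9)
  expect_true(all(diff(w) > 0))
  expect_equal(w[1], 0.06)
  expect_equal(w[length(w)], 9)
  # rendered area: peripheral bars dwarf foveal ones
  area <- rowSums(ap$masks[1:24, ])
  centers <- -9 + (seq_len(24) - 0.5) * (18 / 24)
  expect_gt(area[which.max(abs(centers))], 10 * max(1, area[which.min(abs(centers))]))
  # near fixation the scaled bar is narrower than the size-invariant bar
  ap_inv <- bar_sequence(0, 1, FALSE, d, cfg)
  foveal <- which.min(abs(centers))
  expect_lt(sum(ap$masks[foveal, ]), sum(ap_inv$masks[foveal, ]))
})

test_that("wedge-and-ring run has 120 stimulation + 24 terminal blanks", {
  ap <- wedge_ring_sequence("cw_expand", cfg = cfg_coarse())
  expect_equal(n_volumes(ap), 144)
  expect_equal(sum(ap$is_blank), 24)
  expect_true(all(ap$is_blank[121:144]))
  expect_true(all(!ap$masks[121:144, ]))
  r <- sqrt(ap$grid$x^2 + ap$grid$y^2)
  expect_true(all(!ap$masks[, r > 9]))
  # wedge revolution period: the wedge-only part of the mask repeats
  # every 20 volumes; the union repeats with the 60-volume joint period
  expect_equal(ap$masks[1, ], ap$masks[61, ])
})

test_that("wedge and ring schedules follow the stated geometry", {
  d <- stimulus_design()
  # wedge: starts at the upper vertical meridian, rotates clockwise,
  # one revolution per cycle
  expect_equal(prfmap:::wedge_angle_at(0, d, cw = TRUE), 90)
  expect_equal(prfmap:::wedge_angle_at(0.25, d, cw = TRUE), 0)
  expect_equal(prfmap:::wedge_angle_at(0.25, d, cw = FALSE), 180)
  expect_equal(prfmap:::wedge_angle_at(1, d, cw = TRUE), 90)
  # ring: log-spaced steps from the inner eccentricity to the display
  # edge, adjacent annuli sharing half of their radial log extent
  n <- d$ring_volumes_per_cycle
  first <- prfmap:::ring_radii_at(0, d, 0.06, 9)
  last <- prfmap:::ring_radii_at(n - 1, d, 0.06, 9)
  expect_equal(unname(first["lo"]), 0.06)
  expect_equal(unname(last["hi"]), 9)
  for (k in 0:(n - 3)) {
    a <- prfmap:::ring_radii_at(k, d, 0.06, 9)
    b <- prfmap:::ring_radii_at(k + 1, d, 0.06, 9)
    # 50% overlap in the log domain
    expect_equal(unname(log(a["hi"]) - log(b["lo"])),
                 unname(log(a["hi"]) - log(a["lo"])) / 2)
  }
})

test_that("photic run is 10 single-volume bursts with 11 blank volumes", {
  cfg <- cfg_coarse()
  ap <- photic_sequence(cfg)
  expect_equal(n_volumes(ap), 120)
  onsets <- attr(ap, "trial_onsets")
  expect_equal(onsets, seq(1, 109, by = 12))
  expect_equal(sum(!ap$is_blank), 10)
  disc <- sqrt(cfg$grid$x^2 + cfg$grid$y^2) <= 9
  expect_equal(ap$masks[onsets[3], ], disc)
  expect_true(all(!ap$masks[-onsets, ]))
})

test_that("session schedule assembles ten runs totaling 1440 volumes", {
  runs <- cached("session_coarse", function() {
    session_schedule(cfg = cfg_coarse())
  })
  expect_length(runs, 10)
  expect_equal(attr(runs, "total_volumes"), 1440)
  expect_setequal(
    names(runs),
    c("bar_card_fwd", "bar_card_rev", "bar_obli_fwd", "bar_obli_rev",
      "bar_log_card_fwd", "bar_log_card_rev", "bar_log_obli_fwd",
      "bar_log_obli_rev", "wedge_ring_fwd", "wedge_ring_rev"))
  expect_equal(unname(vapply(runs, n_volumes, integer(1))), rep(144, 10))
})

test_that("display down-scaling rescales geometry, not timing", {
  d <- stimulus_design()
  ap16 <- bar_sequence(0, 1, FALSE, d, carrier_config(16, 1))
  ap9 <- bar_run_coarse()
  expect_equal(n_volumes(ap16), n_volumes(ap9))
  # the bar occupies the same fraction of pixel columns on both displays
  frac16 <- sum(ap16$masks[12, ]) / ap16$grid$n_pixels
  frac9 <- sum(ap9$masks[12, ]) / ap9$grid$n_pixels
  expect_lt(abs(frac16 - frac9), 0.02)
})

test_that("fixation events are deterministic and non-adjacent", {
  ev1 <- fixation_events(360, seed = 4)
  ev2 <- fixation_events(360, seed = 4)
  expect_identical(ev1, ev2)
  expect_true(nrow(ev1) > 0)
  if (nrow(ev1) > 1) {
    expect_true(all(diff(ev1$onset_s) >= 0.4 - 1e-9))
  }
})
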