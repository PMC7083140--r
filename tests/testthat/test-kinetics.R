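test_that("force traces validate sampling and protocol", {
  expect_error(force_trace(c(0, 1, 1.5), c(0, 0, 0)), "uniform")
  expect_error(force_trace(c(0, 1, 0.5), c(0, 0, 0)), "increasing")
  expect_error(
    force_trace(seq(0, 10, 0.01), rep(0, 1001),
                protocol = data.frame(frequency_hz = 1, duration_s = 60)),
    "exceed")
})

test_that("slice geometry reproduces the standard cross-section", {
  geom <- slice_geometry()
  expect_identical(geom$area_mm2, 1.25)
  expect_error(slice_geometry(damaged_margin_mm = 0.4), "positive")
  expect_equal(wall_tension(2.5, geom), 2.0)
  expect_equal(wall_tension(0, geom), 0)
})

test_that("twitch windows are one per stimulus, disjoint and ordered", {
  gen <- gen_force_trace(protocol = data.frame(frequency_hz = 1,
                                               duration_s = 40))
  tw <- detect_twitches(gen$trace)
  expect_equal(nrow(tw), 40L)
  expect_true(all(diff(tw$stim_s) > 0))
  expect_true(all(tw$end_s[-nrow(tw)] <= tw$start_s[-1] + 1e-12))

  flat <- force_trace(seq(0, 10, 1e-3), rep(0, 10001))
  expect_warning(none <- detect_twitches(flat), "no twitches")
  expect_equal(nrow(none), 0L)
})

test_that("twitch parameters match closed-form and geometric references", {
  gen <- gen_force_trace(protocol = data.frame(frequency_hz = 0.5,
                                               duration_s = 40),
                         twitch_shape = data.frame(frequency_hz = 0.5,
                                                   tau_r_s = 0.05,
                                                   tau_d_s = 0.15),
                         amplitude_mN = 1.2)
  tw <- detect_twitches(gen$trace)
  p <- twitch_params(gen$trace, tw[3, ], baseline_mN = 0.1)
  expect_equal(p$ttp_s, log(3) * 0.0075 / 0.1, tolerance = 0.015)
  expect_equal(p$f_max_mN, 1.2, tolerance = 1e-3)
  expect_equal(p$cd90_s, p$ttp_s + p$ttr_s)

  # symmetric triangular pulse: TTP = rise, TTR = 90% of the fall
  t <- seq(0, 1, 1e-3)
  f <- pmax(0, 1 - abs(t - 0.3) / 0.1)
  tri <- force_trace(t, f)
  ptri <- twitch_params(tri, list(start_s = 0.15, end_s = 0.8,
                                  stim_s = 0.2),
                        baseline_mN = 0, onset = "stimulus",
                        smooth_ms = 0)
  expect_equal(ptri$ttp_s, 0.1, tolerance = 1e-6)
  expect_equal(ptri$ttr_s, 0.09, tolerance = 1e-6)

  # scaling force scales f_max and leaves every time unchanged
  sc <- force_trace(gen$trace$time_s, gen$trace$force_mN * 3,
                    protocol = gen$trace$protocol,
                    stimulus_times_s = gen$trace$stimulus_times_s)
  psc <- twitch_params(sc, tw[3, ], baseline_mN = 0.3)
  expect_equal(psc$f_max_mN, 3 * p$f_max_mN, tolerance = 1e-9)
  expect_equal(psc$ttp_s, p$ttp_s)
  expect_equal(psc$ttr_s, p$ttr_s)
})

test_that("interval averages use the last 30 s of each interval", {
  gen <- gen_force_trace()
  fr <- interval_average(gen$trace)
  expect_equal(fr$table$n_twitches, c(6L, 15L, 30L, 60L))
  # identical twitches: the mean equals a single twitch's parameters
  tw <- detect_twitches(gen$trace)
  i05 <- which(tw$stim_s >= 210 & tw$stim_s < 240)[3]  # 0.5 Hz window
  p1 <- twitch_params(gen$trace, tw[i05, ], baseline_mN = 0.1)
  expect_equal(fr$table$f_max_mN[2], p1$f_max_mN, tolerance = 1e-4)

  short <- gen_force_trace(protocol = data.frame(frequency_hz = 1,
                                                 duration_s = 20))
  expect_warning(interval_average(short$trace), "in full")
})

test_that("FFR ratios are programmed, dimensionless and flag gaps", {
  gen <- gen_force_trace(amplitude_mN = c(`0.2` = 0.9, `0.5` = 1,
                                          `1` = 1, `2` = 1))
  r <- ffr_ratios(interval_average(gen$trace))
  expect_equal(r$ffr_1_0p5, 1, tolerance = 5e-3)

  neg <- gen_force_trace(amplitude_mN = c(`0.2` = 0.9, `0.5` = 1,
                                          `1` = 0.9, `2` = 0.8))
  rn <- ffr_ratios(interval_average(neg$trace))
  expect_equal(rn$ffr_1_0p5, 0.9, tolerance = 5e-3)
  expect_equal(rn$ffr_2_0p5, 0.8, tolerance = 5e-3)

  # multiplying the whole trace by k > 0 leaves the ratios unchanged
  tr <- neg$trace
  sc <- force_trace(tr$time_s, tr$force_mN * 4.2, protocol = tr$protocol,
                    stimulus_times_s = tr$stimulus_times_s)
  rs <- ffr_ratios(interval_average(sc))
  expect_equal(rs$ffr_1_0p5, rn$ffr_1_0p5, tolerance = 1e-9)
  expect_equal(rs$ffr_2_0p5, rn$ffr_2_0p5, tolerance = 1e-9)

  # a missing frequency yields a flagged NA ratio
  part <- gen_force_trace(protocol = data.frame(
    frequency_hz = c(0.5, 1), duration_s = c(40, 40)))
  expect_warning(rp <- ffr_ratios(interval_average(part$trace)),
                 "missing")
  expect_true(is.na(rp$ffr_2_0p5))
  expect_false(is.na(rp$ffr_1_0p5))
})

test_that("small noise perturbs interval means by less than 2%", {
  clean <- interval_average(gen_force_trace(rng_seed = 1)$trace)
  noisy <- interval_average(gen_force_trace(noise_sd = 0.01,
                                            rng_seed = 1)$trace)
  expect_lt(max(abs(noisy$table$f_max_mN / clean$table$f_max_mN - 1)),
            0.02)
})

test_that("slice aggregation is the component-wise median", {
  expect_error(aggregate_slices(list()), "no slices")
  mk <- function(scale) {
    gen <- gen_force_trace(amplitude_mN = c(`0.2` = 0.9, `0.5` = 1,
                                            `1` = 1.08, `2` = 1.05) * scale)
    interval_average(gen$trace)
  }
  frs <- lapply(c(0.9, 1.0, 1.3), mk)
  med <- aggregate_slices(frs)
  expect_equal(med$table$f_max_mN, frs[[2]]$table$f_max_mN)
  one <- aggregate_slices(frs[2])
  expect_equal(one$table, frs[[2]]$table)
  # duplicating a flanking pair around the median leaves it unchanged
  med2 <- aggregate_slices(c(frs, frs[c(1, 3)]))
  expect_equal(med2$table$f_max_mN, med$table$f_max_mN)
})
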