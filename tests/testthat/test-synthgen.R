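test_that("phantom spec validates its geometry invariants", {
  expect_error(tubule_phantom_spec(lattice_spacing_um = 0.05,
                                   tubule_radius_um = 0.04),
               "twice tubule_radius_um")
  expect_error(tubule_phantom_spec(cell_extent_um = c(1, 1, 1)),
               "64 voxels")
  expect_error(tubule_phantom_spec(geometry = "custom"), "custom_mask")
  expect_error(tubule_phantom_spec(noise_sd = -1), "non-negative")
})

test_that("generators are deterministic for a fixed seed", {
  spec <- tubule_phantom_spec(cell_extent_um = c(5.8, 5.8, 5.8),
                              noise_sd = 3, rng_seed = 11L)
  a <- gen_tsystem_stack(spec, compute_truth = "none")
  b <- gen_tsystem_stack(spec, compute_truth = "none")
  expect_identical(a$stack$intensities, b$stack$intensities)

  m1 <- gen_myocyte_mosaic(16, disarray_fraction = 0.25, noise_sd = 2,
                           rng_seed = 5L)
  m2 <- gen_myocyte_mosaic(16, disarray_fraction = 0.25, noise_sd = 2,
                           rng_seed = 5L)
  expect_identical(m1$image, m2$image)
  expect_identical(m1$truth$true_orientations_deg,
                   m2$truth$true_orientations_deg)

  t1 <- gen_force_trace(noise_sd = 0.01, rng_seed = 9L)
  t2 <- gen_force_trace(noise_sd = 0.01, rng_seed = 9L)
  expect_identical(t1$trace$force_mN, t2$trace$force_mN)

  c1 <- gen_cohort(n_samples = 3, rng_seed = 7L)
  c2 <- gen_cohort(n_samples = 3, rng_seed = 7L)
  expect_identical(c1$samples, c2$samples)
})

test_that("surface-only phantoms carry no tubules and a flagged truth", {
  spec <- tubule_phantom_spec(cell_extent_um = c(5.8, 5.8, 5.8),
                              geometry = "surface-only")
  ph <- gen_tsystem_stack(spec)
  expect_false(any(ph$truth$tubule_mask))
  expect_true(is.na(ph$truth$true_delta_tt_um))
  expect_true(any(ph$truth$surface_mask))
})

test_that("exhaustive distance oracle handles the degenerate cases", {
  d <- c(20L, 20L, 20L)
  cell <- array(TRUE, d)
  expect_equal(as.numeric(brute_force_dtt(cell, cell, 0.1)), 0)

  tub <- array(FALSE, d); tub[5, 5, 5] <- TRUE
  one <- array(FALSE, d); one[5, 5, 8] <- TRUE
  expect_equal(as.numeric(brute_force_dtt(tub, one, 0.1)), 0.3)

  empty <- array(FALSE, d)
  res <- brute_force_dtt(empty, cell, 0.1)
  expect_true(is.nan(res))
  expect_true(attr(res, "flagged"))
  expect_error(brute_force_dtt(tub, empty, 0.1), "cell_mask is empty")
})

test_that("sheet and lattice phantom truths match the closed forms", {
  # parallel planes spaced d: mean distance d/4
  sh <- gen_tsystem_stack(tubule_phantom_spec(
    cell_extent_um = c(5.8, 5.8, 6.1), geometry = "sheets",
    lattice_spacing_um = 1.0), compute_truth = "brute")
  expect_lt(abs(sh$truth$true_delta_tt_um - 0.25) / 0.25, 0.03)

  # square lattice of lines spaced d: mean (d/6)(sqrt(2) + asinh(1))
  la <- gen_tsystem_stack(tubule_phantom_spec(
    cell_extent_um = c(6.1, 6.1, 5.8), geometry = "full-lattice",
    lattice_spacing_um = 1.0), compute_truth = "brute")
  closed <- (1.0 / 6) * (sqrt(2) + log(1 + sqrt(2)))
  expect_lt(abs(la$truth$true_delta_tt_um - closed) / closed, 0.03)
})

test_that("mosaic generator renders the programmed orientation field", {
  expect_error(gen_myocyte_mosaic(0), "at least 1")
  one <- gen_myocyte_mosaic(1, mean_angle_deg = 0, angle_sd_deg = 0,
                            rng_seed = 1)
  expect_equal(sort(unique(as.vector(one$truth$label_map))), c(0L, 1L))
  expect_equal(one$truth$true_orientations_deg, 0)
  # interior dim, boundary bright
  expect_lt(mean(one$image[one$truth$label_map == 1]),
            mean(one$image[one$truth$label_map == 0]))

  same <- gen_myocyte_mosaic(25, mean_angle_deg = 12, angle_sd_deg = 0,
                             rng_seed = 2)
  expect_equal(length(unique(same$truth$true_orientations_deg)), 1L)

  dis <- gen_myocyte_mosaic(100, disarray_fraction = 0.1,
                            angle_sd_deg = 8, rng_seed = 3)
  dmain <- abs(dis$truth$true_orientations_deg - 0) %% 180
  dmain <- pmin(dmain, 180 - dmain)
  expect_equal(sum(dmain > 30), 10L)
  expect_equal(length(dis$truth$disarray_ids), 10L)
})

test_that("striation generator obeys Nyquist and its stated structure", {
  expect_error(gen_sarcomere_pattern(length_um = 1.0, pixel_size_um = 0.3),
               "Nyquist")
  img <- gen_sarcomere_pattern(2.05, angle_deg = 0, pixel_size_um = 0.15,
                               noise_sd = 0)
  # periodicity along x only: every column is constant
  expect_equal(max(apply(img, 2, sd)), 0)
  expect_gt(sd(img[1, ]), 0)
  # FFT of the noiseless pattern peaks at the programmed frequency
  for (L in c(2.05, 1.80)) {
    row <- gen_sarcomere_pattern(L, 0, c(64, 256), 0.15)[1, ]
    sp <- Mod(fft(row - mean(row)))^2
    khat <- which.max(sp[2:128])  # cycles over the window
    expect_equal(khat, round(256 * 0.15 / L))
  }
})

test_that("force-trace generator matches its closed-form kinetics", {
  expect_equal(twitch_ttp(0.05, 0.15), log(3) * 0.0075 / 0.1)
  expect_error(twitch_ttp(0.2, 0.1), "tau_d must exceed tau_r")
  expect_error(gen_force_trace(
    twitch_shape = data.frame(frequency_hz = c(0.2, 0.5, 1, 2),
                              tau_r_s = 0.2, tau_d_s = 0.1)),
    "tau_d must exceed tau_r")

  # peak of the unit twitch equals the closed-form factor, at TTP
  tt <- seq(0, 2, by = 1e-5)
  f <- twitch_force(tt, 0.05, 0.15, f_max = 1)
  expect_equal(max(f), 1, tolerance = 1e-8)
  expect_equal(tt[which.max(f)], twitch_ttp(0.05, 0.15), tolerance = 1e-4)

  gen <- gen_force_trace(amplitude_mN = c(`0.2` = 0.9, `0.5` = 1,
                                          `1` = 1.08, `2` = 0.8))
  expect_equal(gen$truth$ffr_1_0p5, 1.08)
  expect_equal(gen$truth$ffr_2_0p5, 0.8)
  # one stimulus per pacing period over each 120 s interval
  expect_equal(length(gen$trace$stimulus_times_s),
               sum(c(0.2, 0.5, 1, 2) * 120))
})

test_that("cohort generator reproduces the printed interaction model", {
  expect_error(gen_cohort(2), "at least 3")
  expect_error(gen_cohort(5, noise_sds = list(ttr = -1, ffr = 0,
                                              tension = 0, ttp = 0)),
               "non-negative")
  co <- gen_cohort(40, noise_sds = list(ttr = 0, ffr = 0, tension = 0,
                                        ttp = 0), rng_seed = 4)
  s <- co$samples
  expect_equal(s$ttr_s, 0.36 * (s$delta_tt_um -
                                0.069 * s$ncx1 * s$delta_tt_um))
  # the printed model evaluated at dTT = 1, NCX1 = 1
  expect_equal(0.36 * (1 - 0.069 * 1), 0.33516)

  flat <- gen_cohort(400, ffr_slope = 0,
                     noise_sds = list(ttr = 0, ffr = 0.05, tension = 0.3,
                                      ttp = 0), rng_seed = 5)
  expect_lt(abs(cor(flat$samples$delta_tt_um, flat$samples$ffr_1_0p5)),
            0.12)
})
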