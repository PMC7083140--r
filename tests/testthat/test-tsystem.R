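test_that("separable distance transform agrees with the exhaustive oracle", {
  set.seed(101)
  for (rep in 1:3) {
    d <- c(18L, 16L, 20L)
    mask <- array(runif(prod(d)) < 0.02, d)
    if (!any(mask)) mask[1, 1, 1] <- TRUE
    vs <- c(0.1, 0.12, 0.09)
    cell <- array(TRUE, d)
    dm <- distance_transform(mask, vs)
    expect_equal(mean(dm), as.numeric(brute_force_dtt(mask, cell, vs)),
                 tolerance = 1e-12)
  }
})

test_that("attenuation correction inverts an exponential depth gain", {
  # uniform volume with a known exponential depth gain
  set.seed(2)
  d <- c(64L, 32L, 32L)
  z_um <- (seq_len(d[1]) - 1L) * 0.1
  x <- array(rnorm(prod(d), 50, 0.5), d) * exp(-0.02 * z_um)
  st <- voxel_stack(x, 0.1)
  corr <- correct_attenuation(st)
  expect_equal(attr(corr, "attenuation_coefficient_per_um"), 0.02,
               tolerance = 0.1)   # 0.02 +- 0.002
  pm <- apply(corr$intensities, 1, mean)
  expect_lt(diff(range(pm)) / mean(pm), 0.02)

  # no attenuation: near-identity
  st0 <- voxel_stack(array(rnorm(prod(d), 50, 0.5), d), 0.1)
  corr0 <- correct_attenuation(st0)
  rel <- abs(apply(corr0$intensities, 1, mean) /
             apply(st0$intensities, 1, mean) - 1)
  expect_lt(max(rel), 0.01)

  zero <- voxel_stack(array(0, c(16, 16, 16)), 0.1)
  expect_error(correct_attenuation(zero), "all-zero")
})

test_that("deconvolution is conservative, monotone, and identity at zero", {
  st <- voxel_stack(array(runif(16^3, 1, 5), c(16, 16, 16)) |>
                      array(c(16, 16, 16)), 0.1)
  expect_error(denoise_deconvolve(st, psf_sigma_um = -1), "non-negative")
  id <- denoise_deconvolve(st, psf_sigma_um = 0, iterations = 0L)
  expect_identical(id$intensities, st$intensities)

  # blurred two-point phantom: contrast strictly increases with iterations
  x <- array(0.01, c(64, 64, 64))
  x[32, 32, 28] <- 50; x[32, 32, 37] <- 50
  blurred <- voxel_stack(
    myoslice:::blur3_fft(x, c(2, 2, 2)), 0.1)
  contrast <- sapply(c(1, 3, 10), function(it) {
    dec <- denoise_deconvolve(blurred, psf_sigma_um = 0.2,
                              iterations = it)
    prof <- dec$intensities[32, 32, 26:39]
    (max(prof) - min(prof[5:10])) / max(prof)
  })
  expect_true(all(diff(contrast) > 0))
  # total intensity conserved
  dec10 <- denoise_deconvolve(blurred, psf_sigma_um = 0.2,
                              iterations = 10L)
  expect_equal(sum(dec10$intensities), sum(blurred$intensities),
               tolerance = 0.01)
})

test_that("histogram threshold separates a bimodal stack", {
  set.seed(3)
  d <- c(32L, 32L, 32L)
  fg <- array(runif(prod(d)) < 0.2, d)
  x <- array(rnorm(prod(d), 10, 1.5), d)
  x[fg] <- rnorm(sum(fg), 100, 5)
  x[x < 0] <- 0
  st <- voxel_stack(x, 0.1)
  mask <- segment_membrane(st)
  expect_equal(mean(mask), 0.2, tolerance = 0.1)   # fraction 0.20 +- 0.02
  expect_gt(sum(mask & fg) / sum(fg), 0.99)

  inv <- segment_membrane(voxel_stack(max(x) - x, 0.1), invert = TRUE)
  expect_identical(inv, mask)

  expect_error(segment_membrane(voxel_stack(array(1, d), 0.1)),
               "constant")
})

test_that("cell mask recovers the phantom interior with and without marker", {
  spec <- tubule_phantom_spec(cell_extent_um = c(5.8, 5.8, 5.8),
                              geometry = "surface-only", noise_sd = 1,
                              rng_seed = 6)
  ph <- gen_tsystem_stack(spec, compute_truth = "none")
  cell <- build_cell_mask(ph$stack)
  tr <- ph$truth$cell_mask
  expect_gt(sum(cell & tr) / sum(cell | tr), 0.95)

  # marker channel filling the true cell
  marker <- array(5, dim(tr)); marker[tr] <- 80
  mst <- voxel_stack(marker, 0.1, channel = "RyR")
  cell_m <- build_cell_mask(ph$stack, marker_stack = mst)
  expect_gt(sum(cell_m & tr) / sum(cell_m | tr), 0.95)

  # marker covering the whole frame
  whole <- voxel_stack(array(50, dim(tr)), 0.1)
  expect_true(all(build_cell_mask(ph$stack, marker_stack = whole)))
})

test_that("surface separation partitions the intracellular membrane", {
  ph <- gen_tsystem_stack(tubule_phantom_spec(
    cell_extent_um = c(5.8, 5.8, 5.8), geometry = "full-lattice",
    tubule_radius_um = 0.15), compute_truth = "none")
  membrane <- ph$truth$tubule_mask | ph$truth$surface_mask
  cell <- ph$truth$cell_mask
  masks <- extract_tsystem(membrane, cell, 0.1, surface_margin_um = 0.3)
  truth_tub <- ph$truth$tubule_mask & !ph$truth$surface_mask
  expect_gt(sum(masks$tubule_mask & truth_tub) / sum(truth_tub), 0.9)
  expect_false(any(masks$tubule_mask & masks$surface_mask))
  expect_equal(masks$tubule_mask | masks$surface_mask, membrane & cell)

  # degenerate margin: everything intracellular is t-system
  m0 <- extract_tsystem(membrane, cell, 0.1, surface_margin_um = 0)
  expect_equal(m0$tubule_mask, membrane & cell)

  # surface-only phantom: empty tubule mask with a warning
  so <- gen_tsystem_stack(tubule_phantom_spec(
    cell_extent_um = c(5.8, 5.8, 5.8), geometry = "surface-only"),
    compute_truth = "none")
  expect_warning(
    ms <- extract_tsystem(so$truth$surface_mask, so$truth$cell_mask, 0.1),
    "no t-system")
  expect_false(any(ms$tubule_mask))
})

test_that("mean tubule distance behaves as the metric demands", {
  d <- c(24L, 24L, 24L)
  cell <- array(TRUE, d)
  # tubules everywhere: distance zero
  all_m <- segmentation_masks(cell, cell, cell, array(FALSE, d))
  expect_equal(compute_dtt(all_m, 0.1)$delta_tt_um, 0)

  # empty tubules: flagged NaN, not an error
  none <- segmentation_masks(array(FALSE, d), cell, array(FALSE, d),
                             array(FALSE, d))
  res <- compute_dtt(none, 0.1)
  expect_true(is.nan(res$delta_tt_um))
  expect_true(res$flagged)

  # sheet spacing d gives d/4, and doubling the spacing doubles it
  full_masks <- function(ph) segmentation_masks(
    ph$truth$tubule_mask | ph$truth$surface_mask, ph$truth$cell_mask,
    ph$truth$tubule_mask, array(FALSE, dim(ph$truth$cell_mask)))
  ph1 <- gen_tsystem_stack(tubule_phantom_spec(
    cell_extent_um = c(5.8, 5.8, 6.1), geometry = "sheets",
    lattice_spacing_um = 1.0), compute_truth = "none")
  m1 <- compute_dtt(full_masks(ph1), 0.1)
  expect_equal(m1$delta_tt_um, 0.25, tolerance = 0.04)  # 0.25 +- 0.01
  ph2 <- gen_tsystem_stack(tubule_phantom_spec(
    cell_extent_um = c(5.8, 5.8, 6.1), geometry = "sheets",
    lattice_spacing_um = 2.0), compute_truth = "none")
  m2 <- compute_dtt(full_masks(ph2), 0.1)
  expect_equal(m2$delta_tt_um / m1$delta_tt_um, 2, tolerance = 0.05)

  # scale equivariance: voxel size scaled by k scales the metric by k
  expect_equal(compute_dtt(full_masks(ph1), 0.25)$delta_tt_um,
               2.5 * m1$delta_tt_um, tolerance = 1e-12)

  # monotonicity: deleting tubule voxels never decreases the metric
  set.seed(42)
  tub <- array(runif(prod(d)) < 0.03, d)
  mk <- segmentation_masks(tub, cell, tub, array(FALSE, d))
  v0 <- compute_dtt(mk, 0.1)$delta_tt_um
  keep <- which(tub)
  tub2 <- array(FALSE, d); tub2[sample(keep, length(keep) %/% 2)] <- TRUE
  mk2 <- segmentation_masks(tub2, cell, tub2, array(FALSE, d))
  expect_gte(compute_dtt(mk2, 0.1)$delta_tt_um, v0)
})

test_that("per-sample aggregation is a symmetric mean with low-n warning", {
  expect_error(aggregate_sample_dtt(list()), "no stacks")
  expect_warning(one <- aggregate_sample_dtt(c(0.8)), "fewer than 3")
  expect_equal(one$delta_tt_um, 0.8)
  agg <- aggregate_sample_dtt(c(0.9, 1.1, 1.0))
  expect_equal(agg$delta_tt_um, 1.0)
  expect_equal(agg$n_stacks, 3L)
  perm <- aggregate_sample_dtt(c(1.0, 0.9, 1.1))
  expect_equal(perm$delta_tt_um, agg$delta_tt_um)
})

test_that("the full imaging chain recovers true dTT on noisy phantoms", {
  for (sp in c(1.0, 1.6)) {
    spec <- tubule_phantom_spec(
      cell_extent_um = c(5.8, 5.8, 5.8), geometry = "full-lattice",
      lattice_spacing_um = sp, tubule_radius_um = 0.15, noise_sd = 2,
      attenuation_coefficient_per_um = 0.01, blur_sigma_um = 0.1,
      rng_seed = round(10 * sp))
    ph <- gen_tsystem_stack(spec, compute_truth = "brute")
    m <- analyze_tsystem_stack(ph$stack, psf_sigma_um = 0.1,
                               iterations = 10L,
                               surface_margin_um = 0.3)
    expect_lt(abs(m$delta_tt_um / ph$truth$true_delta_tt_um - 1), 0.1)
  }
})
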