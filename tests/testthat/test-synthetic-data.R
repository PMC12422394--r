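# Phantom generator: geometry, ground-truth consistency, speckle model.

test_that("a spec without vessels renders an empty lumen set", {
  spec <- one_tube_spec()
  spec$vessels <- list()
  ph <- generate_phantom(spec)
  expect_identical(ph$truth$luminal_fraction, 0)
  expect_false(any(ph$truth$lumen))
  expect_true(any(ph$truth$band))
})

test_that("rendered lumen matches the brute-force point-in-cylinder oracle", {
  spec <- one_tube_spec(radius = 50)
  ph <- generate_phantom(spec)
  y <- round(spec$n_bscans / 2) * 10
  oracle <- rasterize_tube_oracle(spec$n_axial, spec$n_ascans, spec$n_bscans,
                                  c(10, 10, 10),
                                  p0 = c(0, y, 450),
                                  p1 = c((spec$n_ascans - 1) * 10, y, 450),
                                  radius = 50)
  oracle <- oracle & ph$truth$band
  expect_identical(ph$truth$lumen, oracle)
  expect_equal(ph$truth$luminal_fraction, sum(oracle) / sum(ph$truth$band))
})

test_that("ground-truth surfaces and rendered band agree voxelwise", {
  for (sd_amp in c(0, 15)) {
    spec <- one_tube_spec(surface_amplitude = sd_amp, seed = 3L)
    ph <- generate_phantom(spec)
    band2 <- choroid3d:::band_array(truth_boundaries(ph))
    expect_identical(ph$truth$band, band2)
    expect_false(any(ph$truth$lumen & !ph$truth$band))
  }
})

test_that("phantom generation is deterministic in the seed", {
  a <- generate_phantom(phantom_spec(seed = 5L))
  b <- generate_phantom(phantom_spec(seed = 5L))
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_identical(a$truth$inner_um, b$truth$inner_um)
  c <- generate_phantom(phantom_spec(seed = 6L))
  expect_false(identical(a$truth$inner_um, c$truth$inner_um))
})

test_that("a vessel escaping the choroid band is rejected with its index", {
  spec <- one_tube_spec()
  spec$vessels[[1]]$points[, 3] <- c(100, 100)  # above the band
  expect_error(generate_phantom(spec), "vessel 1 escapes")
  expect_error(phantom_spec(vessels = list(vessel_tube(c(0, 100, 700),
                                                       c(100, 100, 700), 5))),
               "2 axial spacings")
  expect_error(phantom_spec(lumen_intensity = 0.7, stroma_intensity = 0.5),
               "hyporeflective")
  expect_error(phantom_spec(n_axial = 4), ">= 8")
})

test_that("pairwise edge gaps match the analytic tube layout", {
  spec <- parallel_tubes_spec(ys = c(160, 420), radii = c(50, 40))
  ph <- generate_phantom(spec)
  gaps <- ph$truth$pairwise_edge_gaps
  expect_equal(nrow(gaps), 1L)
  expect_equal(gaps$gap_um, 260 - 90, tolerance = 1e-8)
})

test_that("speckle is multiplicative, unit-mean, clipped and seeded", {
  spec <- one_tube_spec()
  ph <- generate_phantom(spec)
  expect_error(apply_speckle(ph$volume, speckle_shape = 0), "> 0")

  # vanishing-noise limit
  quiet <- apply_speckle(ph$volume, speckle_shape = 1e8, seed = 1L)
  expect_lt(max(abs(quiet$intensities - ph$volume$intensities)), 0.01)

  # law of large numbers on a constant 0.5 volume (CV = 1/sqrt(shape)); the
  # [0,1] clip truncates the gamma tail, so the exact target is
  # E[min(G, 2)]/2 for G ~ Gamma(4, 4), slightly below 0.5
  const <- oct_volume(array(0.5, dim = c(100, 100, 100)), c(10, 10, 10))
  sp <- apply_speckle(const, speckle_shape = 4, seed = 2L)
  target <- 0.5 * pgamma(2, 5, 4) + (1 - pgamma(2, 4, 4))
  se <- 0.5 / sqrt(4) / sqrt(1e6)
  expect_lt(abs(mean(sp$intensities) - target), 3 * se)
  expect_lt(abs(mean(sp$intensities) - 0.5), 0.01)
  expect_gte(min(sp$intensities), 0)
  expect_lte(max(sp$intensities), 1)

  # bit-identical repeat under a fixed seed
  s1 <- apply_speckle(ph$volume, 4, seed = 9L)
  s2 <- apply_speckle(ph$volume, 4, seed = 9L)
  expect_identical(s1$intensities, s2$intensities)
  s3 <- apply_speckle(ph$volume, 4, seed = 10L)
  expect_false(identical(s1$intensities, s3$intensities))
})
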