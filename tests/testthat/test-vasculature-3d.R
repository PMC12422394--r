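# Sector grid geometry, optic-disc exclusion, labelling, projections.

mk_vol <- function(n = 64L, pitch = 100) {
  oct_volume(array(0.5, dim = c(8, n, n)), c(pitch, pitch, 10),
             laterality = "OD", fovea_index = c(n / 2, n / 2))
}

test_that("sector assignment follows the five-sector geometry", {
  grid <- build_sector_grid(mk_vol())
  f <- grid$fovea_center
  expect_equal(sector_of_xy(grid, f[["x"]], f[["y"]]), "central")
  expect_equal(sector_of_xy(grid, f[["x"]], f[["y"]] - 3000), "superior")
  expect_equal(sector_of_xy(grid, f[["x"]], f[["y"]] + 3000), "inferior")
  # exact diagonal: priority superior > inferior > nasal > temporal
  expect_equal(sector_of_xy(grid, f[["x"]] + 3000, f[["y"]] - 3000), "superior")
  expect_equal(sector_of_xy(grid, f[["x"]] + 3000, f[["y"]] + 3000), "inferior")
  # laterality: same physical point swaps nasal/temporal between OD and OS
  grid_os <- build_sector_grid(mk_vol(), laterality = "OS")
  expect_equal(sector_of_xy(grid, f[["x"]] + 3000, f[["y"]]), "nasal")
  expect_equal(sector_of_xy(grid_os, f[["x"]] + 3000, f[["y"]]), "temporal")
  expect_error(build_sector_grid(mk_vol(), fovea_center = c(-10, 0)), "outside")
})

test_that("sectors partition the en-face plane exactly", {
  for (n in c(16L, 33L, 64L)) {
    grid <- build_sector_grid(mk_vol(n))
    sm <- sector_map(grid)
    expect_true(all(sm %in% c("central", "nasal", "temporal", "superior", "inferior")))
    counts <- table(factor(sm, levels = c("central", "nasal", "temporal",
                                          "superior", "inferior")))
    expect_equal(sum(counts), n * n)   # pairwise disjoint by construction
    expect_gt(counts[["central"]], 0)
    if (n * 100 > 2 * 2000) expect_true(all(counts > 0))
  }
})

test_that("per-sector aggregation and the five-sector mean are exact", {
  grid <- build_sector_grid(mk_vol())
  sm <- sector_map(grid)
  m <- matrix(100, nrow(sm), ncol(sm))
  agg <- aggregate_by_sector(m, grid)
  expect_equal(unname(agg), rep(100, 6))
  m2 <- matrix(20, nrow(sm), ncol(sm))
  m2[sm == "central"] <- 10
  agg2 <- aggregate_by_sector(m2, grid)
  expect_equal(unname(agg2[["central"]]), 10)
  expect_equal(unname(agg2[["nasal"]]), 20)
  expect_equal(unname(agg2[["mean"]]), (10 + 4 * 20) / 5)
})

test_that("mean-of-sectors is invariant under a laterality flip", {
  grid_od <- build_sector_grid(mk_vol())
  grid_os <- build_sector_grid(mk_vol(), laterality = "OS")
  set.seed(8)
  m <- matrix(runif(64 * 64), 64, 64)
  a <- aggregate_by_sector(m, grid_od)
  b <- aggregate_by_sector(m, grid_os)
  expect_equal(a[["nasal"]], b[["temporal"]])
  expect_equal(a[["temporal"]], b[["nasal"]])
  expect_equal(a[["mean"]], b[["mean"]])
})

test_that("optic-disc exclusion clears only the footprint and is idempotent", {
  spec <- parallel_tubes_spec(ys = c(160, 420), radii = c(50, 40))
  ph <- generate_phantom(spec)
  mask <- truth_mask(ph)
  expect_equal(label_vasculature(mask)$n_components, 2L)

  expect_identical(mask_optic_disc(mask, NULL), mask)
  empty_disc <- list(center = c(100, 100), radius = 0)
  expect_identical(mask_optic_disc(mask, empty_disc)$luminal, mask$luminal)

  all_disc <- list(center = c(320, 320), radius = 1e6)
  expect_false(any(mask_optic_disc(mask, all_disc)$luminal))

  # a footprint over exactly one of two tubes drops the component count by one
  d <- dim(mask$luminal)
  stripe <- matrix(FALSE, d[3], d[2])
  stripe[abs((seq_len(d[3]) - 1) * 10 - 160) <= 120, ] <- TRUE
  m1 <- mask_optic_disc(mask, stripe)
  expect_equal(label_vasculature(m1)$n_components, 1L)
  m2 <- mask_optic_disc(m1, stripe)
  expect_identical(m1$luminal, m2$luminal)
})

test_that("labelling counts components and volumes against the rasterization", {
  spec <- parallel_tubes_spec(ys = c(160, 420), radii = c(50, 40))
  ph <- generate_phantom(spec)
  vasc <- label_vasculature(truth_mask(ph))
  expect_equal(vasc$n_components, 2L)
  expect_equal(sum(vasc$volumes_um3),
               sum(ph$truth$lumen) * prod(spec$spacing))
  # tubes sharing an endpoint form a single component
  ext_x <- (spec$n_ascans - 1) * 10
  yspec <- phantom_spec(n_bscans = 64L, n_ascans = 64L, n_axial = 96L,
                        spacing = c(10, 10, 10), inner_depth_mean = 300,
                        choroid_thickness_mean = 300, retina_thickness = 150,
                        surface_amplitude = 0, seed = 1L,
                        vessels = list(
                          vessel_tube(c(0, 320, 450), c(ext_x, 320, 450), 40),
                          vessel_tube(c(ext_x, 320, 450), c(0, 100, 450), 30)))
  yph <- generate_phantom(yspec)
  expect_equal(label_vasculature(truth_mask(yph))$n_components, 1L)
  # empty mask is valid
  m <- truth_mask(ph)
  m$luminal[] <- FALSE
  ev <- label_vasculature(m)
  expect_equal(ev$n_components, 0L)
  expect_length(ev$volumes_um3, 0)
})

test_that("en-face projections match the analytic footprint", {
  spec <- one_tube_spec(radius = 50)
  ph <- generate_phantom(spec)
  ef <- make_enface(truth_mask(ph))
  y <- round(spec$n_bscans / 2) * 10
  rows_hit <- which(apply(ef, 1, any))
  expect_true(all(abs((rows_hit - 1) * 10 - y) <= 50 + 10))
  expect_true(all(ef[rows_hit[3], ]))  # ribbon spans the full scan width
  zero <- make_enface(array(FALSE, dim = dim(ph$truth$lumen)))
  expect_false(any(zero))
  # intensity projection restricted to the band
  efi <- make_enface(ph$volume, band = ph$truth$band)
  expect_equal(dim(efi), c(spec$n_bscans, spec$n_ascans))
  expect_true(all(efi >= 0.1 & efi <= 0.6))
})
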