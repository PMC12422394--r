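# Centerlines, vessel selection, diameter/IVD measurement, QC aggregation.

central_grid <- function(ph) build_sector_grid(ph$volume)

test_that("a straight tube yields one unbranched centerline with the right radius", {
  spec <- one_tube_spec(radius = 50)
  ph <- generate_phantom(spec)
  vasc <- label_vasculature(truth_mask(ph))
  cl <- extract_centerlines(vasc)
  p <- cl$points
  expect_equal(unique(p$component), 1L)
  expect_false(any(p$is_branch))
  expect_true(all(is.finite(p$ord)))                 # ordered path
  expect_true(all(abs(p$radius_um - 50) <= 5 + 1e-9))  # half a voxel
  # diameters at seeded random sites: 100 um within one isotropic voxel
  grid <- central_grid(ph)
  for (s in c(1L, 99L)) {
    d <- measure_diameters(cl, 1L, grid, "central", seed = s)
    expect_length(as.numeric(d), 3L)
    expect_true(all(abs(d - 100) <= 10 + 1e-9))
  }
  # fixed seed reproduces the same sites
  d1 <- measure_diameters(cl, 1L, grid, "central", seed = 7L)
  d2 <- measure_diameters(cl, 1L, grid, "central", seed = 7L)
  expect_identical(attr(d1, "sites"), attr(d2, "sites"))
})

test_that("a Y-junction is flagged as one branch-point cluster", {
  ext_x <- 63 * 10
  spec <- phantom_spec(n_bscans = 64L, n_ascans = 64L, n_axial = 96L,
                       spacing = c(10, 10, 10), inner_depth_mean = 300,
                       choroid_thickness_mean = 300, retina_thickness = 150,
                       surface_amplitude = 0, seed = 1L,
                       vessels = list(
                         vessel_tube(c(0, 320, 450), c(ext_x, 320, 450), 40),
                         vessel_tube(c(320, 320, 450), c(630, 560, 450), 30)))
  ph <- generate_phantom(spec)
  vasc <- label_vasculature(truth_mask(ph))
  cl <- extract_centerlines(vasc)
  br <- cl$points[cl$points$is_branch, ]
  expect_gte(nrow(br), 1L)
  # all branch voxels sit in one tight cluster around the junction
  if (nrow(br) > 1) expect_lt(max(dist(cbind(br$x, br$y, br$z))), 100)
  # straight-run exclusion: eligible sites keep their distance from the branch
  expect_true(all(cl$points$dist_branch_um[!cl$points$is_branch &
                                             cl$points$dist_branch_um >= cl$l_min]
                  >= 100))
})

test_that("an empty vasculature gives an empty, error-free result", {
  spec <- one_tube_spec()
  ph <- generate_phantom(spec)
  m <- truth_mask(ph)
  m$luminal[] <- FALSE
  vasc <- label_vasculature(m)
  cl <- extract_centerlines(vasc)
  expect_equal(nrow(cl$points), 0L)
  bio <- suppressWarnings(
    sector_and_global_metrics(vasc, cl, central_grid(ph), seed = 1L))
  expect_equal(bio$n_vessels_measured, 0L)
  expect_true(all(is.na(bio$sectors$mchvd_um)))
})

test_that("a tapered tube's radii grow monotonically along the path", {
  ext_x <- 63 * 10
  spec <- phantom_spec(n_bscans = 64L, n_ascans = 64L, n_axial = 160L,
                       spacing = c(10, 10, 10), inner_depth_mean = 300,
                       choroid_thickness_mean = 400, retina_thickness = 150,
                       surface_amplitude = 0, seed = 1L,
                       vessels = list(vessel_tube(c(0, 320, 500),
                                                  c(ext_x, 320, 500),
                                                  c(40, 80))))
  ph <- generate_phantom(spec)
  cl <- extract_centerlines(label_vasculature(truth_mask(ph)))
  p <- cl$points[cl$points$dist_end_um >= cl$l_min, ]   # measurable stretch
  p <- p[order(p$ord), ]
  expect_true(all(p$radius_um >= 80 / 2 - 10 & p$radius_um <= 160 / 2 + 10))
  ## monotone along arclength up to discretization (orientation-agnostic)
  rr <- p$radius_um
  if (rr[1] > rr[length(rr)]) rr <- rev(rr)
  expect_true(all(diff(rr) >= -10))
  expect_gt(cor(seq_along(rr), rr, method = "spearman"), 0.9)
})

test_that("IVD measures the nearest independent edge-to-edge gap", {
  # two parallel tubes, center spacing 300 um, radii 50/40
  spec <- parallel_tubes_spec(ys = c(160, 460), radii = c(50, 40))
  ph <- generate_phantom(spec)
  cl <- extract_centerlines(label_vasculature(truth_mask(ph)))
  grid <- central_grid(ph)
  iv <- measure_ivd(cl, 1L, grid, "central", seed = 3L)
  expect_true(all(abs(iv - (300 - 90)) <= 10 + 1e-9))

  # three tubes: gaps 200 and 400 from the first -> the nearest wins
  spec3 <- parallel_tubes_spec(ys = c(120, 420, 620), radii = c(50, 50, 50),
                               n_bscans = 96L)
  ph3 <- generate_phantom(spec3)
  cl3 <- extract_centerlines(label_vasculature(truth_mask(ph3)))
  grid3 <- central_grid(ph3)
  iv3 <- measure_ivd(cl3, 1L, grid3, "central", seed = 3L)
  expect_true(all(abs(iv3 - 200) <= 10 + 1e-9))

  # a single vessel has no independent neighbour: IVD missing
  spec1 <- one_tube_spec()
  ph1 <- generate_phantom(spec1)
  cl1 <- extract_centerlines(label_vasculature(truth_mask(ph1)))
  iv1 <- measure_ivd(cl1, 1L, central_grid(ph1), "central", seed = 1L)
  expect_true(all(is.na(iv1)))
})

test_that("collaterals of the same component are excluded from IVD", {
  # U-shaped vessel whose return stub passes 100 um from the main run, plus an
  # independent tube 250 um away on the other side
  ext <- 127 * 10
  spec <- phantom_spec(n_bscans = 128L, n_ascans = 128L, n_axial = 120L,
                       spacing = c(10, 10, 10), inner_depth_mean = 300,
                       choroid_thickness_mean = 400, retina_thickness = 150,
                       surface_amplitude = 0, seed = 1L,
                       vessels = list(
                         list(points = rbind(c(0, 400, 500), c(ext, 400, 500),
                                             c(ext, 600, 500), c(900, 600, 500)),
                              radius = 50),
                         vessel_tube(c(0, 50, 500), c(ext, 50, 500), 50)))
  ph <- generate_phantom(spec)
  vasc <- label_vasculature(truth_mask(ph))
  expect_equal(vasc$n_components, 2L)
  cl <- extract_centerlines(vasc)
  grid <- central_grid(ph)
  for (s in 1:4) {
    iv <- measure_ivd(cl, 1L, grid, "central", seed = s)
    # the 100-um collateral gap must never be reported; the independent vessel
    # is at least 250 um away from every point of component 1
    expect_true(all(iv >= 250 - 10))
  }
})

test_that("vessel selection ranks by in-sector volume with stable tie-breaks", {
  spec <- parallel_tubes_spec(ys = c(100, 260, 420, 580),
                              radii = c(80, 60, 40, 20), n_bscans = 96L,
                              n_axial = 120L)
  ph <- generate_phantom(spec)
  vasc <- label_vasculature(truth_mask(ph))
  grid <- central_grid(ph)
  sel <- select_largest_vessels(vasc, grid, "central", n = 3L)
  expect_equal(sel$ids, c(1L, 2L, 3L))    # component order follows y order here
  expect_false(sel$shortfall)
  expect_true(all(diff(sel$volumes_um3) < 0))
  # identical tubes tie -> lower label wins
  spec_tie <- parallel_tubes_spec(ys = c(160, 460), radii = c(50, 50))
  ph_tie <- generate_phantom(spec_tie)
  sel_tie <- select_largest_vessels(label_vasculature(truth_mask(ph_tie)),
                                    central_grid(ph_tie), "central", n = 1L)
  expect_equal(sel_tie$ids, 1L)
  # fewer vessels than requested -> shortfall flag
  sel_short <- select_largest_vessels(label_vasculature(truth_mask(ph_tie)),
                                      central_grid(ph_tie), "central", n = 3L)
  expect_true(sel_short$shortfall)
  expect_equal(length(sel_short$ids), 2L)
})

test_that("the QC rule redraws vessels whose triplet spread exceeds 50 um", {
  # sample-SD of the canonical bad triplet
  expect_equal(sd(c(100, 100, 220)), 69.28203, tolerance = 1e-6)
  calls <- 0L
  fun <- function(seed) {
    calls <<- calls + 1L
    if (calls == 1L) c(100, 100, 220) else c(100, 100, 110)
  }
  res <- choroid3d:::qc_redraw(fun, qc_threshold = 50, max_attempts = 5L, seed = 1L)
  expect_true(res$qc_remeasured)
  expect_false(res$max_attempts)
  expect_equal(res$values, c(100, 100, 110))
  # persistently bad vessels keep the last triplet with a max-attempts flag
  bad <- function(seed) c(100, 100, 220)
  res2 <- choroid3d:::qc_redraw(bad, qc_threshold = 50, max_attempts = 5L, seed = 1L)
  expect_true(res2$max_attempts)
  # a good triplet passes untouched on the first draw
  good <- function(seed) c(100, 105, 110)
  res3 <- choroid3d:::qc_redraw(good, qc_threshold = 50, max_attempts = 5L, seed = 1L)
  expect_false(res3$qc_remeasured)
})

test_that("sector aggregation is the mean of nine values, global the sector mean", {
  spec <- sector_phantom_spec(seed = 3L)
  ph <- generate_phantom(spec)
  vasc <- label_vasculature(truth_mask(ph))
  cl <- extract_centerlines(vasc)
  grid <- build_sector_grid(ph$volume)
  bio <- sector_and_global_metrics(vasc, cl, grid, seed = 11L)
  m <- bio$measurements
  for (s in unique(m$sector)) {
    ms <- m[m$sector == s, ]
    expect_equal(bio$sectors$mchvd_um[bio$sectors$sector == s],
                 mean(ms$diameter_um))
  }
  expect_equal(unname(bio$global[["mchvd_um"]]), mean(bio$sectors$mchvd_um))
  expect_equal(unname(bio$global[["ivd_um"]]), mean(bio$sectors$ivd_um))
  # retained triplets satisfy the QC rule or carry the max-attempts flag
  byv <- split(m, interaction(m$sector, m$vessel_rank, drop = TRUE))
  for (v in byv) {
    expect_true(sd(v$diameter_um) <= 50 + 1e-9 || any(v$qc_max_attempts))
  }
  # determinism of the whole protocol
  bio2 <- sector_and_global_metrics(vasc, cl, grid, seed = 11L)
  expect_identical(bio$measurements, bio2$measurements)
})

test_that("dilating every component widens diameters and shrinks IVD", {
  spec <- parallel_tubes_spec(ys = c(160, 460), radii = c(50, 40))
  ph <- generate_phantom(spec)
  mask <- truth_mask(ph)
  grid <- central_grid(ph)
  measure_both <- function(m) {
    cl <- extract_centerlines(label_vasculature(m))
    list(d = mean(measure_diameters(cl, 1L, grid, "central", seed = 2L)),
         i = mean(measure_ivd(cl, 1L, grid, "central", seed = 2L)))
  }
  base <- measure_both(mask)
  dil <- mask
  dil$luminal <- dilate26_oracle(mask$luminal) & mask$choroid_band
  big <- measure_both(dil)
  expect_gt(big$d, base$d)
  expect_lt(big$i, base$i)
})
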