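# Shared miniature phantoms (built in code at test time, no fixtures on disk).

# Small single-tube phantom: 10 um isotropic, one grid-aligned straight tube.
one_tube_spec <- function(radius = 50, seed = 1L, n_bscans = 32L, n_ascans = 48L,
                          n_axial = 96L, surface_amplitude = 0, ...) {
  ext_x <- (n_ascans - 1) * 10
  y <- round(n_bscans / 2) * 10
  phantom_spec(n_bscans = n_bscans, n_ascans = n_ascans, n_axial = n_axial,
               spacing = c(10, 10, 10), inner_depth_mean = 300,
               choroid_thickness_mean = 300, retina_thickness = 150,
               surface_amplitude = surface_amplitude,
               vessels = list(vessel_tube(c(0, y, 450), c(ext_x, y, 450), radius)),
               seed = seed, ...)
}

# Parallel grid-aligned tubes along x at given y centers (um), common z.
parallel_tubes_spec <- function(ys, radii, z = 450, n_bscans = 64L, n_ascans = 64L,
                               n_axial = 96L, seed = 1L, ...) {
  ext_x <- (n_ascans - 1) * 10
  vessels <- mapply(function(y, r) vessel_tube(c(0, y, z), c(ext_x, y, z), r),
                    ys, radii, SIMPLIFY = FALSE)
  phantom_spec(n_bscans = n_bscans, n_ascans = n_ascans, n_axial = n_axial,
               spacing = c(10, 10, 10), inner_depth_mean = 300,
               choroid_thickness_mean = 300, retina_thickness = 150,
               surface_amplitude = 0, vessels = vessels, seed = seed, ...)
}

truth_boundaries <- function(ph) {
  choroid3d:::boundaries_from_truth(ph$truth, ph$volume$spacing,
                                    dim(ph$volume$intensities)[1])
}

truth_mask <- function(ph) choroid3d:::mask_from_truth(ph$truth, ph$volume)

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
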