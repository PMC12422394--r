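#' Specify a synthetic SS-OCT choroid phantom
#'
#' Describes a scene with four slabs along depth (vitreous, retina, choroid,
#' sclera) whose retina/choroid and choroid/sclera interfaces are smooth random
#' surfaces, and a set of hyporeflective tubular vessels (capsule geometry:
#' line segments dilated by a possibly varying radius) embedded in the choroid
#' band. Defaults are desk-scale: 96 B-scans x 128 A-scans x 160 axial samples
#' at 10 um isotropic spacing, a 288.9 um mean choroid band, and six straight
#' tubes spanning the field. Full clinical dimensions (1024 B-scans of
#' 1024 x 1536 px over 12 x 12 mm) are reachable through the same arguments.
#'
#' @param n_bscans,n_ascans,n_axial grid dimensions (all >= 8).
#' @param spacing voxel spacing in micrometers `(bscan, lateral, axial)`.
#' @param inner_depth_mean mean depth (um) of the choroidal-RPE junction.
#' @param choroid_thickness_mean mean choroid band thickness (um).
#' @param retina_thickness thickness (um) of the uniform retina slab above the
#'   choroid.
#' @param surface_smoothness correlation length (um) of the random surfaces.
#' @param surface_amplitude standard deviation (um) of the surface undulation.
#' @param vessels list of vessels; each a `list(points = <n x 3 matrix of
#'   (x, y, z) um>, radius = <scalar or per-point um>)`. See [vessel_tube()].
#' @param lumen_intensity,stroma_intensity,retina_intensity,sclera_intensity
#'   tissue reflectivities in `[0, 1]`; lumens must be darker than stroma.
#' @param vitreous_intensity reflectivity above the retina.
#' @param speckle_shape gamma shape of the multiplicative speckle model
#'   (larger = cleaner); used by [apply_speckle()].
#' @param disc_region optional en-face circle `list(center = c(x, y) um,
#'   radius = um)` marking the optic disc.
#' @param laterality `"OD"` or `"OS"`.
#' @param seed integer seed driving all phantom randomness.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_bscans = 96L, n_ascans = 128L, n_axial = 160L,
                         spacing = c(10, 10, 10),
                         inner_depth_mean = 600, choroid_thickness_mean = 288.9,
                         retina_thickness = 300,
                         surface_smoothness = 300, surface_amplitude = 10,
                         vessels = NULL,
                         lumen_intensity = 0.15, stroma_intensity = 0.55,
                         retina_intensity = 0.85, sclera_intensity = 0.30,
                         vitreous_intensity = 0.05,
                         speckle_shape = 4, disc_region = NULL,
                         laterality = "OD", seed = 1L) {
  if (!is_count(n_bscans, 8) || !is_count(n_ascans, 8) || !is_count(n_axial, 8))
    stopf("all grid dimensions must be integers >= 8")
  if (length(spacing) != 3 || any(spacing <= 0)) stopf("spacings must be > 0")
  if (lumen_intensity >= stroma_intensity)
    stopf("lumen_intensity must be below stroma_intensity (vessels are hyporeflective)")
  if (speckle_shape <= 0) stopf("speckle_shape must be > 0")
  spacing <- setNames(as.numeric(spacing), c("bscan", "lateral", "axial"))
  if (is.null(vessels))
    vessels <- default_vessel_layout(n_bscans, n_ascans, spacing,
                                     inner_depth_mean, choroid_thickness_mean)
  for (i in seq_along(vessels)) {
    v <- vessels[[i]]
    if (is.null(v$points) || ncol(v$points) != 3 || nrow(v$points) < 2)
      stopf("vessel %d: `points` must be an n x 3 matrix with n >= 2", i)
    r <- v$radius
    if (length(r) == 1) r <- rep(r, nrow(v$points))
    if (length(r) != nrow(v$points) || any(r < 2 * spacing[["axial"]]))
      stopf("vessel %d: radii must cover every point and be >= 2 axial spacings", i)
    vessels[[i]]$radius <- r
  }
  structure(list(n_bscans = as.integer(n_bscans), n_ascans = as.integer(n_ascans),
                 n_axial = as.integer(n_axial), spacing = spacing,
                 inner_depth_mean = inner_depth_mean,
                 choroid_thickness_mean = choroid_thickness_mean,
                 retina_thickness = retina_thickness,
                 surface_smoothness = surface_smoothness,
                 surface_amplitude = surface_amplitude,
                 vessels = vessels,
                 lumen_intensity = lumen_intensity, stroma_intensity = stroma_intensity,
                 retina_intensity = retina_intensity, sclera_intensity = sclera_intensity,
                 vitreous_intensity = vitreous_intensity,
                 speckle_shape = speckle_shape, disc_region = disc_region,
                 laterality = laterality, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Straight or polyline tube helper
#'
#' @param from,to length-3 `(x, y, z)` endpoints in micrometers.
#' @param radius lumen radius in micrometers (scalar, or length 2 for a taper
#'   from `from` to `to`).
#' @return A vessel entry for [phantom_spec()].
#' @export
vessel_tube <- function(from, to, radius) {
  pts <- rbind(from, to)
  list(points = unname(pts), radius = if (length(radius) == 1) radius else radius)
}

default_vessel_layout <- function(n_bscans, n_ascans, spacing,
                                  inner_depth, thickness) {
  ext_x <- (n_ascans - 1) * spacing[["lateral"]]
  ext_y <- (n_bscans - 1) * spacing[["bscan"]]
  # snap tube axes to voxel centers: the inscribed-radius estimator is exact
  # to within half a voxel only for grid-aligned straight tubes
  zmid <- round((inner_depth + thickness / 2) / spacing[["axial"]]) * spacing[["axial"]]
  ys <- round(seq(0.12, 0.88, length.out = 6) * ext_y / spacing[["bscan"]]) *
    spacing[["bscan"]]
  radii <- c(70, 45, 60, 40, 55, 50)
  mapply(function(y, r) vessel_tube(c(0, y, zmid), c(ext_x, y, zmid), r),
         ys, radii, SIMPLIFY = FALSE)
}

# Smooth zero-mean random surface with correlation length `smoothness` um.
# Scaled by the theoretical SD of Gaussian-smoothed white noise so every point
# is (approximately) N(0, amplitude^2); normalizing by the sample SD instead
# produces wild excursions when the field spans only a few correlation
# lengths.
random_surface <- function(n_bscans, n_ascans, spacing, smoothness, amplitude) {
  if (amplitude <= 0) return(matrix(0, n_bscans, n_ascans))
  sig_r <- smoothness / spacing[["bscan"]]
  sig_c <- smoothness / spacing[["lateral"]]
  # white noise on an extended grid so the valid interior is smoothed from
  # genuine iid samples only (no edge replication leaking variance)
  h_r <- (length(gauss_kernel1(sig_r)) - 1L) / 2L
  h_c <- (length(gauss_kernel1(sig_c)) - 1L) / 2L
  z <- matrix(rnorm((n_bscans + 2 * h_r) * (n_ascans + 2 * h_c)),
              n_bscans + 2 * h_r, n_ascans + 2 * h_c)
  s <- gaussian_blur2(z, sig_r, sig_c)
  s <- s[h_r + seq_len(n_bscans), h_c + seq_len(n_ascans), drop = FALSE]
  theo_sd <- sqrt(sum(gauss_kernel1(sig_r)^2) * sum(gauss_kernel1(sig_c)^2))
  (s - mean(s)) / theo_sd * amplitude
}

#' Render a phantom volume and its ground truth
#'
#' Produces the noise-free label volume (vitreous/retina/stroma/lumen/sclera
#' rendered at the spec's reflectivities) and a ground-truth record: the two
#' boundary surfaces, sampled vessel centerlines with radii, the exact luminal
#' fraction of the rendered band, and pairwise edge-to-edge vessel gaps.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return `list(volume = <oct_volume>, truth = <phantom_truth>)`; the truth
#'   carries `inner_um`/`outer_um` surfaces (`[bscan, ascan]` matrices),
#'   `centerlines`, `luminal_fraction`, `pairwise_edge_gaps`, and the logical
#'   arrays `lumen` and `band` aligned with the volume.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- spec$n_axial; nx <- spec$n_ascans; ny <- spec$n_bscans
  sp <- spec$spacing
  dz <- sp[["axial"]]; dx <- sp[["lateral"]]; dy <- sp[["bscan"]]

  surf <- with_seed(spec$seed, {
    list(inner = spec$inner_depth_mean +
           random_surface(ny, nx, sp, spec$surface_smoothness, spec$surface_amplitude),
         dthick = random_surface(ny, nx, sp, spec$surface_smoothness, spec$surface_amplitude))
  })
  inner <- surf$inner
  outer <- inner + spec$choroid_thickness_mean + surf$dthick
  if (any(inner >= outer)) stopf("degenerate phantom: inner surface reaches outer surface")

  zv <- (seq_len(nz) - 1) * dz
  # broadcast surfaces to (z, x, y)
  bc <- function(m) array(rep(as.vector(t(m)), each = nz), dim = c(nz, nx, ny))
  innerA <- bc(inner); outerA <- bc(outer)
  Z <- array(zv, dim = c(nz, nx, ny))
  retina_top <- innerA - spec$retina_thickness

  labels <- array(0L, dim = c(nz, nx, ny))          # 0 vitreous
  labels[Z >= retina_top & Z < innerA] <- 1L        # retina
  labels[Z >= innerA & Z < outerA] <- 2L            # choroid stroma
  labels[Z >= outerA] <- 4L                         # sclera

  # rasterize vessels (capsules), with band-escape checks
  lumen <- array(FALSE, dim = c(nz, nx, ny))
  cl <- list()
  for (vi in seq_along(spec$vessels)) {
    v <- spec$vessels[[vi]]
    pts <- v$points; rad <- v$radius
    for (si in seq_len(nrow(pts) - 1)) {
      p0 <- pts[si, ]; p1 <- pts[si + 1, ]
      r0 <- rad[si]; r1 <- rad[si + 1]
      seg <- p1 - p0
      L <- sqrt(sum(seg^2))
      if (L == 0) next
      # centerline samples for ground truth + escape checks
      ts <- seq(0, 1, length.out = max(2L, ceiling(L / (min(sp) / 2))))
      sx <- p0[1] + ts * seg[1]; sy <- p0[2] + ts * seg[2]; sz <- p0[3] + ts * seg[3]
      sr <- r0 + ts * (r1 - r0)
      ai <- clamp(round(sx / dx) + 1L, 1L, nx)
      bi <- clamp(round(sy / dy) + 1L, 1L, ny)
      in_um <- inner[cbind(bi, ai)]; out_um <- outer[cbind(bi, ai)]
      bad <- which(sz - sr < in_um | sz + sr > out_um)
      if (length(bad))
        stopf("vessel %d escapes the choroid band near (x=%.0f, y=%.0f, z=%.0f) um",
              vi, sx[bad[1]], sy[bad[1]], sz[bad[1]])
      cl[[length(cl) + 1L]] <- data.frame(vessel = vi, x = sx, y = sy, z = sz,
                                          radius = sr)
      # voxel bounding box of the capsule
      rmax <- max(r0, r1)
      ir <- clamp(floor((min(p0[3], p1[3]) - rmax) / dz) : ceiling((max(p0[3], p1[3]) + rmax) / dz) + 1L, 1L, nz)
      jr <- clamp(floor((min(p0[1], p1[1]) - rmax) / dx) : ceiling((max(p0[1], p1[1]) + rmax) / dx) + 1L, 1L, nx)
      kr <- clamp(floor((min(p0[2], p1[2]) - rmax) / dy) : ceiling((max(p0[2], p1[2]) + rmax) / dy) + 1L, 1L, ny)
      ir <- unique(ir); jr <- unique(jr); kr <- unique(kr)
      g <- expand.grid(i = ir, j = jr, k = kr)
      P <- cbind((g$j - 1) * dx, (g$k - 1) * dy, (g$i - 1) * dz)
      d0 <- sweep(P, 2, p0)
      tt <- clamp(as.vector(d0 %*% seg) / (L * L), 0, 1)
      dd <- d0 - outer(tt, seg)
      dist2 <- rowSums(dd^2)
      rt <- r0 + tt * (r1 - r0)
      hit <- dist2 <= rt^2
      if (any(hit)) {
        idx <- (g$i[hit]) + nz * ((g$j[hit] - 1L) + nx * (g$k[hit] - 1L))
        lumen[idx] <- TRUE
      }
    }
  }
  lumen <- lumen & labels == 2L
  labels[lumen] <- 3L

  look <- c(spec$vitreous_intensity, spec$retina_intensity, spec$stroma_intensity,
            spec$lumen_intensity, spec$sclera_intensity)
  vol <- array(look[labels + 1L], dim = c(nz, nx, ny))

  band <- labels == 2L | labels == 3L
  centerlines <- if (length(cl)) do.call(rbind, cl) else
    data.frame(vessel = integer(), x = numeric(), y = numeric(), z = numeric(),
               radius = numeric())
  gaps <- pairwise_edge_gaps(centerlines)

  volume <- oct_volume(vol, sp, laterality = spec$laterality,
                       fovea_index = NULL, id = sprintf("phantom-seed%d", spec$seed))
  truth <- structure(list(inner_um = inner, outer_um = outer,
                          centerlines = centerlines,
                          luminal_fraction = sum(lumen) / sum(band),
                          pairwise_edge_gaps = gaps,
                          lumen = lumen, band = band, labels = labels),
                     class = "phantom_truth")
  list(volume = volume, truth = truth)
}

# Minimum edge-to-edge gap between every vessel pair, from sampled centerlines.
pairwise_edge_gaps <- function(centerlines) {
  ids <- unique(centerlines$vessel)
  if (length(ids) < 2)
    return(data.frame(vessel_a = integer(), vessel_b = integer(), gap_um = numeric()))
  out <- list()
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (b <= a) next
    ca <- centerlines[centerlines$vessel == ids[a], ]
    cb <- centerlines[centerlines$vessel == ids[b], ]
    d2 <- outer(ca$x, cb$x, "-")^2 + outer(ca$y, cb$y, "-")^2 + outer(ca$z, cb$z, "-")^2
    gap <- sqrt(d2) - outer(ca$radius, cb$radius, "+")
    out[[length(out) + 1L]] <- data.frame(vessel_a = ids[a], vessel_b = ids[b],
                                          gap_um = min(gap))
  }
  do.call(rbind, out)
}

#' Apply multiplicative speckle noise
#'
#' Multiplies every voxel by an independent unit-mean gamma variate
#' (`shape = speckle_shape`, `rate = speckle_shape`) and clips to `[0, 1]`, so
#' the expected value of each voxel stays (up to clipping) at its clean
#' intensity and the per-voxel coefficient of variation is
#' `1 / sqrt(speckle_shape)`.
#'
#' @param volume an [oct_volume()].
#' @param speckle_shape gamma shape parameter, > 0.
#' @param seed integer seed; a fixed seed gives a bit-identical repeat.
#' @return A speckled `oct_volume`.
#' @export
apply_speckle <- function(volume, speckle_shape = 4, seed = NULL) {
  stopifnot(inherits(volume, "oct_volume"))
  if (!is.numeric(speckle_shape) || length(speckle_shape) != 1 || speckle_shape <= 0)
    stopf("speckle_shape must be a single value > 0")
  n <- length(volume$intensities)
  g <- with_seed(seed, rgamma(n, shape = speckle_shape, rate = speckle_shape))
  volume$intensities <- array(clamp(volume$intensities * g, 0, 1),
                              dim = dim(volume$intensities))
  volume
}

# Vessel mask taken verbatim from phantom ground truth (oracle path for the
# measurement stage; also used by tests).
mask_from_truth <- function(truth, volume) {
  structure(list(luminal = truth$lumen, choroid_band = truth$band,
                 spacing = volume$spacing, laterality = volume$laterality,
                 fovea_index = volume$fovea_index),
            class = "vessel_mask")
}

#' Phantom specification with vessels in all five sectors
#'
#' A wider desk-scale phantom (64 x 64 en-face grid at 100 um pitch, i.e. a
#' 6.3 x 6.3 mm field with the fovea at its center; 80 axial samples at
#' 20 um) whose twelve straight tubes populate every sector of the standard
#' 4 mm-central five-sector grid: horizontal tubes cross the superior,
#' central and inferior regions, vertical tubes the nasal, temporal and
#' central regions, in three depth layers so crossing tubes never touch.
#' Intended for exercising the full measurement protocol (3 vessels x 3
#' sites per sector) with known tube radii and gaps.
#'
#' @param seed integer seed (surface randomness).
#' @param ... further arguments passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
sector_phantom_spec <- function(seed = 1L, ...) {
  # 40 um isotropic voxels: coarser lateral pitches render tubes as column
  # staircases whose inscribed radius is genuinely below the nominal one.
  # Three depth layers far enough apart that crossing tubes never touch;
  # radii are realistic Haller-layer calibres, axes snapped to voxel centers.
  z1 <- 480; z2 <- 840; z3 <- 1200
  ext <- 6280
  h <- function(y, z, r) vessel_tube(c(0, y, z), c(ext, y, z), r)
  v <- function(x, z, r) vessel_tube(c(x, 0, z), c(x, ext, z), r)
  vessels <- list(
    h(520, z1, 180),  h(3000, z1, 170), h(5520, z1, 175),
    h(920, z3, 150),  h(3480, z3, 140), h(5920, z3, 145),
    v(520, z2, 135),  v(920, z2, 120),  v(5520, z2, 138), v(5920, z2, 125),
    v(2600, z2, 115), v(3720, z2, 110))
  phantom_spec(n_bscans = 158L, n_ascans = 158L, n_axial = 44L,
               spacing = c(40, 40, 40),
               inner_depth_mean = 260, choroid_thickness_mean = 1250,
               retina_thickness = 250, surface_amplitude = 8,
               vessels = vessels, seed = seed, ...)
}
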