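sector_names <- function() c("central", "nasal", "temporal", "superior", "inferior")

#' Build the fovea-centered five-sector grid
#'
#' Partitions the en-face plane into a central disc (default 4 mm diameter)
#' and four wedges cut by the two 45-degree diagonals through the fovea.
#' The left/right wedges map to nasal/temporal according to laterality: for a
#' right eye (OD) the nasal side is toward the image right by default, for a
#' left eye (OS) toward the image left; the convention is configurable via
#' `nasal_side` and recorded on the grid. Points exactly on a wedge boundary
#' are assigned with priority superior > inferior > nasal > temporal so the
#' partition is exact. "Above" the fovea (superior) means smaller B-scan
#' index.
#'
#' @param volume an [oct_volume()] (or any list with `intensities`, `spacing`,
#'   `laterality`, `fovea_index`).
#' @param fovea_center optional en-face `(x, y)` micrometres overriding the
#'   volume's fovea index.
#' @param laterality `"OD"` or `"OS"`; defaults to the volume's.
#' @param central_radius radius of the central sector in micrometres
#'   (default 2000, i.e. a 4 mm diameter disc).
#' @param nasal_side `"right"` or `"left"`; defaults by laterality.
#' @return A `sector_grid` object.
#' @export
build_sector_grid <- function(volume, fovea_center = NULL, laterality = NULL,
                              central_radius = 2000, nasal_side = NULL) {
  d <- dim(volume$intensities)
  spacing <- volume$spacing
  laterality <- laterality %||% volume$laterality
  ext <- c(x = (d[2] - 1) * spacing[["lateral"]], y = (d[3] - 1) * spacing[["bscan"]])
  if (is.null(fovea_center))
    fovea_center <- c(x = (volume$fovea_index[["ascan"]] - 1) * spacing[["lateral"]],
                      y = (volume$fovea_index[["bscan"]] - 1) * spacing[["bscan"]])
  fovea_center <- setNames(as.numeric(fovea_center), c("x", "y"))
  if (fovea_center[1] < 0 || fovea_center[1] > ext[1] ||
      fovea_center[2] < 0 || fovea_center[2] > ext[2])
    stopf("fovea (%.0f, %.0f) um outside the en-face field (%.0f x %.0f um)",
          fovea_center[1], fovea_center[2], ext[1], ext[2])
  nasal_side <- nasal_side %||% if (laterality == "OD") "right" else "left"
  nasal_side <- match.arg(nasal_side, c("right", "left"))
  structure(list(fovea_center = fovea_center, central_radius = central_radius,
                 laterality = laterality, nasal_side = nasal_side,
                 n_bscans = d[3], n_ascans = d[2], spacing = spacing),
            class = "sector_grid")
}

#' @export
print.sector_grid <- function(x, ...) {
  cat(sprintf("<sector_grid %s> fovea (%.0f, %.0f) um; central radius %.0f um; nasal=%s\n",
              x$laterality, x$fovea_center[1], x$fovea_center[2],
              x$central_radius, x$nasal_side))
  invisible(x)
}

#' Sector of arbitrary en-face points
#'
#' @param grid a `sector_grid`.
#' @param x,y en-face coordinates in micrometres.
#' @return Character vector of sector labels.
#' @export
sector_of_xy <- function(grid, x, y) {
  dx <- x - grid$fovea_center[["x"]]
  dy <- y - grid$fovea_center[["y"]]
  r2 <- dx^2 + dy^2
  out <- character(length(dx))
  central <- r2 <= grid$central_radius^2
  out[central] <- "central"
  # boundary priority: superior > inferior > nasal > temporal
  sup <- !central & dy <= 0 & abs(dy) >= abs(dx)
  inf <- !central & !sup & dy >= 0 & abs(dy) >= abs(dx)
  out[sup] <- "superior"
  out[inf] <- "inferior"
  rest <- !central & !sup & !inf
  right <- rest & dx > 0
  left <- rest & dx < 0
  nasal_right <- grid$nasal_side == "right"
  out[right] <- if (nasal_right) "nasal" else "temporal"
  out[left] <- if (nasal_right) "temporal" else "nasal"
  out
}

#' En-face sector label map
#'
#' @param grid a `sector_grid`.
#' @return Character matrix `[bscan, ascan]` of sector labels.
#' @export
sector_map <- function(grid) {
  xs <- (seq_len(grid$n_ascans) - 1) * grid$spacing[["lateral"]]
  ys <- (seq_len(grid$n_bscans) - 1) * grid$spacing[["bscan"]]
  g <- expand.grid(y = ys, x = xs)
  matrix(sector_of_xy(grid, g$x, g$y), grid$n_bscans, grid$n_ascans)
}

# En-face logical footprint of a disc circle, [bscan, ascan].
disc_footprint <- function(disc, n_bscans, n_ascans, spacing) {
  if (is.matrix(disc)) {
    if (!all(dim(disc) == c(n_bscans, n_ascans)))
      stopf("disc raster must be [n_bscans x n_ascans]")
    return(disc)
  }
  xs <- (seq_len(n_ascans) - 1) * spacing[["lateral"]]
  ys <- (seq_len(n_bscans) - 1) * spacing[["bscan"]]
  outer(ys, xs, function(y, x)
    (x - disc$center[1])^2 + (y - disc$center[2])^2 <= disc$radius^2)
}

#' Exclude the optic disc from a vessel mask
#'
#' Clears every luminal voxel whose en-face position falls under the disc
#' footprint; all other voxels are untouched. Idempotent.
#'
#' @param mask a `vessel_mask`.
#' @param disc either `list(center = c(x, y) um, radius = um)` or a logical
#'   en-face raster `[bscan, ascan]`; `NULL` is a no-op.
#' @return The masked `vessel_mask` (with `disc_mask` recorded).
#' @export
mask_optic_disc <- function(mask, disc) {
  stopifnot(inherits(mask, "vessel_mask"))
  if (is.null(disc)) return(mask)
  d <- dim(mask$luminal)
  fp <- disc_footprint(disc, d[3], d[2], mask$spacing)
  if (any(fp)) {
    # expand [bscan, ascan] footprint to (z, x, y)
    fp_zxy <- aperm(array(rep(t(fp), each = d[1]), dim = c(d[1], d[2], d[3])), c(1, 2, 3))
    mask$luminal <- mask$luminal & !fp_zxy
  }
  mask$disc_mask <- fp
  mask
}

#' Label the 3D vasculature
#'
#' 26-connected component labelling of the luminal mask; component volumes use
#' the anisotropic voxel volume.
#'
#' @param mask a `vessel_mask` (after optional [mask_optic_disc()]).
#' @return A `vasculature3d` object: integer `labels` array (0 = background),
#'   `volumes_um3` per component, `spacing`, and the carried band/disc masks.
#'   An empty mask yields a valid empty vasculature.
#' @export
label_vasculature <- function(mask) {
  stopifnot(inherits(mask, "vessel_mask"))
  d <- dim(mask$luminal)
  lab <- array(label_components3(as.vector(mask$luminal), d, 26L), dim = d)
  n <- max(lab)
  voxvol <- prod(mask$spacing)
  volumes <- if (n > 0) tabulate(lab[lab > 0], n) * voxvol else numeric(0)
  structure(list(labels = lab, n_components = n, volumes_um3 = volumes,
                 spacing = mask$spacing, choroid_band = mask$choroid_band,
                 disc_mask = mask$disc_mask %||% NULL,
                 laterality = mask$laterality, fovea_index = mask$fovea_index),
            class = "vasculature3d")
}

#' @export
print.vasculature3d <- function(x, ...) {
  cat(sprintf("<vasculature3d> %d components; largest %.2g um^3\n",
              x$n_components,
              if (x$n_components) max(x$volumes_um3) else 0))
  invisible(x)
}

#' En-face projection
#'
#' Axial mean projection within the choroid band for intensity volumes, or
#' axial max projection for masks.
#'
#' @param x an [oct_volume()], a `vessel_mask`, or a 3D logical/numeric array
#'   laid out `(axial, ascan, bscan)`.
#' @param band optional logical band array restricting an intensity
#'   projection.
#' @return Numeric (or logical for masks) matrix `[bscan, ascan]`.
#' @export
make_enface <- function(x, band = NULL) {
  if (inherits(x, "vessel_mask")) return(t(apply(x$luminal, c(2, 3), any)))
  arr <- if (inherits(x, "oct_volume")) x$intensities else x
  if (is.logical(arr)) return(t(apply(arr, c(2, 3), any)))
  if (!is.null(band)) {
    s <- apply(arr * band, c(2, 3), sum)
    n <- apply(band, c(2, 3), sum)
    return(t(ifelse(n > 0, s / n, NA_real_)))
  }
  t(apply(arr, c(2, 3), mean))
}

#' Per-sector means of an en-face map
#'
#' Arithmetic mean of the defined values inside each sector footprint, plus a
#' `"mean"` entry equal to the unweighted mean of the five sector values
#' (the global per-eye summary). An empty sector propagates `NA`.
#'
#' @param map numeric matrix `[bscan, ascan]`.
#' @param grid a `sector_grid` aligned with the map.
#' @return Named numeric vector `central, nasal, temporal, superior, inferior,
#'   mean`.
#' @export
aggregate_by_sector <- function(map, grid) {
  sm <- sector_map(grid)
  if (!all(dim(sm) == dim(map))) stopf("map and grid are not aligned")
  sec <- vapply(sector_names(), function(s) {
    v <- map[sm == s]
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  if (anyNA(sec)) warning("empty sector(s): ", paste(names(sec)[is.na(sec)], collapse = ", "),
                          "; excluded from the five-sector mean")
  c(sec, mean = mean(sec, na.rm = TRUE))
}
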