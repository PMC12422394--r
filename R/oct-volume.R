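#' Construct an SS-OCT volume object
#'
#' Wraps a 3D intensity stack together with its physical metadata. The array
#' layout is `[axial, ascan, bscan]`, i.e. `intensities[, , b]` is the b-th
#' B-scan with depth along rows and A-scans along columns.
#'
#' @param intensities 3D numeric array in `[0, 1]`, dim `(n_axial, n_ascans,
#'   n_bscans)`.
#' @param spacing numeric length-3 vector of voxel spacings in micrometers,
#'   named or ordered as `(bscan, lateral, axial)`: distance between
#'   consecutive B-scans, between A-scans within a B-scan, and between axial
#'   samples.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param fovea_index integer length-2 `(bscan, ascan)` position of the fovea.
#' @param id character scan identifier.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(intensities, spacing, laterality = "OD",
                       fovea_index = NULL, id = "volume") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stopf("`intensities` must be a 3D array")
  rng <- range(intensities)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    stopf("intensities must be finite and within [0, 1]")
  if (length(spacing) != 3L || any(spacing <= 0))
    stopf("`spacing` must be 3 positive micrometre values (bscan, lateral, axial)")
  spacing <- setNames(as.numeric(spacing), c("bscan", "lateral", "axial"))
  laterality <- match.arg(laterality, c("OD", "OS"))
  d <- dim(intensities)
  if (is.null(fovea_index)) fovea_index <- c(ceiling(d[3] / 2), ceiling(d[2] / 2))
  fovea_index <- as.integer(fovea_index)
  if (fovea_index[1] < 1 || fovea_index[1] > d[3] ||
      fovea_index[2] < 1 || fovea_index[2] > d[2])
    stopf("fovea_index (%d, %d) outside the grid", fovea_index[1], fovea_index[2])
  structure(list(intensities = intensities, spacing = spacing,
                 laterality = laterality,
                 fovea_index = setNames(fovea_index, c("bscan", "ascan")),
                 id = as.character(id)),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<oct_volume '%s'> %d B-scans x %d axial x %d A-scans (%s)\n",
              x$id, d[3], d[1], d[2], x$laterality))
  cat(sprintf("  spacing (bscan/lateral/axial): %.2f/%.2f/%.2f um; fovea at B%d A%d\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$fovea_index[1], x$fovea_index[2]))
  invisible(x)
}

# En-face physical extent in micrometers: x along A-scans, y along B-scans.
enface_extent <- function(volume) {
  d <- dim(volume$intensities)
  c(x = (d[2] - 1) * volume$spacing[["lateral"]],
    y = (d[3] - 1) * volume$spacing[["bscan"]])
}

# Fovea position in en-face micrometers.
fovea_um <- function(volume) {
  c(x = (volume$fovea_index[["ascan"]] - 1) * volume$spacing[["lateral"]],
    y = (volume$fovea_index[["bscan"]] - 1) * volume$spacing[["bscan"]])
}
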