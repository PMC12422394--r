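#' Phansalkar binarization parameters
#'
#' Constants of the Phansalkar local threshold
#' `T = m * (1 + p * exp(-q * m) + k * (s / R - 1))`, with `m`, `s` the local
#' mean and (population) standard deviation over a square window centered at
#' each pixel. The 16 x 16 window follows the vessel-segmentation protocol;
#' `k`, `R`, `p`, `q` default to the constants of Phansalkar's original
#' low-contrast-image publication.
#'
#' @param window square window side in pixels (dense sliding window centered
#'   on every pixel, edges replicated).
#' @param k,R,p,q threshold constants; `R` is the dynamic-range normalizer of
#'   the local standard deviation.
#' @param min_component_voxels components smaller than this are removed in the
#'   post-processing stage.
#' @param median_k median prefilter kernel applied to each B-scan before
#'   thresholding (1 disables).
#' @param open_iter iterations of 3x3x1 in-plane morphological opening applied
#'   to the 3D mask.
#' @return A `binarization_params` list.
#' @export
binarization_params <- function(window = 16L, k = 0.25, R = 0.5, p = 2, q = 10,
                                min_component_voxels = 50L, median_k = 3L,
                                open_iter = 1L) {
  if (window < 3) stopf("window must be >= 3")
  if (R <= 0) stopf("R must be > 0")
  if (min_component_voxels < 1) stopf("min_component_voxels must be >= 1")
  structure(as.list(environment()), class = "binarization_params")
}

#' Phansalkar local thresholding of one B-scan
#'
#' Marks a pixel as luminal (vessel) when its intensity is strictly below the
#' local threshold `T = m * (1 + p * exp(-q * m) + k * (s / R - 1))`. The
#' local statistics are computed over a dense sliding window centered at every
#' pixel with edge replication.
#'
#' @param bscan 2D numeric matrix with intensities in `[0, 1]`.
#' @param params a [binarization_params()] list.
#' @return Logical matrix of luminal pixels.
#' @export
phansalkar_threshold <- function(bscan, params = binarization_params()) {
  if (min(bscan) < 0 || max(bscan) > 1) stopf("intensities must be in [0, 1]")
  st <- local_mean_sd(bscan, params$window)
  thr <- st$mean * (1 + params$p * exp(-params$q * st$mean) +
                      params$k * (st$sd / params$R - 1))
  bscan < thr
}

#' Segment choroidal vessel lumens in a volume
#'
#' Applies Phansalkar thresholding per B-scan (after optional median
#' denoising and per-B-scan intensity normalization), intersects the result
#' with the choroid band defined by the boundaries, and cleans the 3D mask
#' with in-plane morphological opening followed by removal of small
#' 26-connected components.
#'
#' @param volume an [oct_volume()].
#' @param boundaries a `choroid_boundaries` object for the same volume.
#' @param params a [binarization_params()] list.
#' @return A `vessel_mask` object with logical arrays `luminal` and
#'   `choroid_band` aligned to the volume, plus the voxel spacing.
#' @export
binarize_vessels <- function(volume, boundaries, params = binarization_params()) {
  stopifnot(inherits(volume, "oct_volume"), inherits(boundaries, "choroid_boundaries"))
  d <- dim(volume$intensities)
  band <- band_array(boundaries, d[1])
  if (!any(band)) stopf("empty choroid band")
  luminal <- array(FALSE, dim = d)
  for (b in seq_len(d[3])) {
    img <- volume$intensities[, , b]
    norm <- normalize01(img)
    if (is.null(norm)) next
    if (params$median_k > 1) norm <- median_filter2(norm, params$median_k)
    luminal[, , b] <- phansalkar_threshold(norm, params)
  }
  luminal <- luminal & band
  luminal <- open3_inplane(luminal, params$open_iter)
  luminal <- luminal & band
  if (any(luminal) && params$min_component_voxels > 1) {
    lab <- label_components3(as.vector(luminal), d, 26L)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= params$min_component_voxels)
    luminal <- array(lab %in% keep & lab > 0, dim = d)
  }
  structure(list(luminal = luminal, choroid_band = band,
                 spacing = volume$spacing, laterality = volume$laterality,
                 fovea_index = volume$fovea_index),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %s voxels; %d luminal / %d band (%.1f%%)\n",
              paste(dim(x$luminal), collapse = "x"),
              sum(x$luminal), sum(x$choroid_band),
              100 * sum(x$luminal) / max(1, sum(x$choroid_band))))
  invisible(x)
}

#' Choroidal vascularity index
#'
#' `CVI = 100 * luminal voxels / choroid-band voxels`, computed over the whole
#' volume and, when a sector grid is supplied, restricted to each sector's
#' en-face footprint. A sector with no band voxels yields `NA` (missing), not
#' zero.
#'
#' @param mask a `vessel_mask`.
#' @param grid optional [build_sector_grid()] result.
#' @return `list(global = %, sector = named vector of the five sectors,
#'   mean_of_sectors = unweighted mean of the five sector values)`; without a
#'   grid only `global` is returned.
#' @export
compute_cvi <- function(mask, grid = NULL) {
  stopifnot(inherits(mask, "vessel_mask"))
  nb_band <- sum(mask$choroid_band)
  if (nb_band == 0) stopf("empty choroid band")
  global <- 100 * sum(mask$luminal) / nb_band
  if (is.null(grid)) return(list(global = global))
  sm <- sector_map(grid)
  d <- dim(mask$luminal)
  # per-column (a, b) voxel counts, then aggregate columns by sector
  lum_col <- apply(mask$luminal, c(2, 3), sum)   # [ascan, bscan]
  band_col <- apply(mask$choroid_band, c(2, 3), sum)
  sec <- vapply(sector_names(), function(s) {
    cols <- t(sm) == s                            # sm is [bscan, ascan]
    bsum <- sum(band_col[cols])
    if (bsum == 0) NA_real_ else 100 * sum(lum_col[cols]) / bsum
  }, numeric(1))
  list(global = global, sector = sec,
       mean_of_sectors = mean(sec, na.rm = TRUE))
}
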