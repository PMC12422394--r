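#' Parameters of the choroid boundary pipeline
#'
#' Constants of the classical per-B-scan delineation pipeline (median
#' denoising, CLAHE, Otsu binarization, morphological cleanup, connected
#' component analysis, robust locally weighted regression within and across
#' B-scans). None of these are dictated by the underlying measurement
#' protocol, so all are exposed here.
#'
#' @param median_k median filter kernel side (odd).
#' @param clahe_tiles CLAHE tile grid `(rows, cols)`.
#' @param clahe_clip CLAHE clip limit (multiple of the uniform bin height).
#' @param close_iter iterations of 3x3 closing applied to the bright mask so
#'   vessel lumens merge into the retina-choroid slab before component
#'   analysis.
#' @param open_iter iterations of 3x3 opening removing speckle specks.
#' @param lowess_f lowess smoother span for the boundary regressions.
#' @param lowess_iter robustness iterations of the lowess fits.
#' @param min_band_px minimum plausible band height in pixels.
#' @param min_valid_frac minimum fraction of A-scans with a candidate band for
#'   a B-scan to count as delineated.
#' @param max_failed_frac abort threshold on the fraction of failed B-scans.
#' @return A `seg_params` list.
#' @export
seg_params <- function(median_k = 5L, clahe_tiles = c(8L, 8L), clahe_clip = 1.2,
                       close_iter = 8L, open_iter = 1L,
                       lowess_f = 0.2, lowess_iter = 3L,
                       min_band_px = 3L, min_valid_frac = 0.5,
                       max_failed_frac = 0.25) {
  structure(as.list(environment()), class = "seg_params")
}

# Single B-scan boundary estimate. Returns list(inner, outer) fractional pixel
# vectors (NA where no candidate) or NULL when the B-scan has no usable band.
delineate_bscan <- function(img, params) {
  norm <- normalize01(img)
  if (is.null(norm)) return(NULL)
  med <- median_filter2(norm, params$median_k)
  eq <- clahe(med, tiles = params$clahe_tiles, clip = params$clahe_clip)
  thr <- otsu_threshold(eq)
  bright <- eq >= thr
  bright <- open2(bright, params$open_iter)
  bright <- close2(bright, params$close_iter)
  if (!any(bright)) return(NULL)

  d <- dim(bright)
  lab <- label_components3(as.vector(bright), c(d[1], d[2], 1L), 26L)
  lab <- matrix(lab, d[1], d[2])
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)

  # split retina from stroma on the denoised intensities: a first Otsu removes
  # the dark lumens/background, a second separates the brighter retina slab.
  t1 <- otsu_threshold(med)
  upper <- med[comp & med > t1]
  if (length(upper) < 10) return(NULL)
  t2 <- otsu_threshold(upper)
  retina <- comp & med >= t2
  retina <- open2(retina, 1L)

  nc <- ncol(img)
  inner <- rep(NA_real_, nc); outer <- rep(NA_real_, nc)
  for (a in seq_len(nc)) {
    rows_c <- which(comp[, a])
    if (!length(rows_c)) next
    rows_r <- which(retina[, a])
    if (!length(rows_r)) next
    # deepest retina run of plausible extent (speckle fragments the mask, so
    # the largest run can stop well short of the junction)
    runs <- split(rows_r, cumsum(c(1, diff(rows_r) != 1)))
    long <- runs[lengths(runs) >= 2]
    run <- if (length(long)) long[[length(long)]] else runs[[length(runs)]]
    inn <- max(run) + 0.5
    out <- max(rows_c) + 0.5
    if (out - inn < params$min_band_px) next
    inner[a] <- inn; outer[a] <- out
  }
  if (mean(!is.na(inner)) < params$min_valid_frac) return(NULL)
  list(inner = inner, outer = outer)
}

fill_na_1d <- function(y) {
  ok <- which(!is.na(y))
  if (!length(ok)) return(y)
  approx(ok, y[ok], xout = seq_along(y), rule = 2)$y
}

smooth_lowess <- function(y, f, iter) {
  ok <- is.finite(y)
  if (sum(ok) < 5) return(y)
  out <- y
  fit <- lowess(which(ok), y[ok], f = f, iter = iter)
  out[ok] <- fit$y
  fill_na_1d(out)
}

#' Delineate the choroid boundaries of a volume
#'
#' Runs the classical multistep pipeline on each B-scan (median filtering,
#' contrast-limited adaptive histogram equalization, Otsu binarization,
#' morphological filtering, largest-bright-component analysis giving initial
#' inner/outer estimates) and then smooths the two surfaces with robust
#' locally weighted regression along each B-scan and again across B-scans.
#' B-scans without a candidate band are flagged as failed and interpolated
#' from their neighbours; if more than `max_failed_frac` of B-scans fail the
#' delineation aborts.
#'
#' @param volume an [oct_volume()].
#' @param params a [seg_params()] list.
#' @return A `choroid_boundaries` object: fractional-pixel `inner` and `outer`
#'   matrices `[bscan, ascan]`, a per-B-scan `corrected` flag (manual
#'   overrides), and a `failed` flag (interpolated B-scans).
#' @export
delineate_choroid <- function(volume, params = seg_params()) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$intensities)
  nb <- d[3]; na_ <- d[2]; nz <- d[1]
  inner <- matrix(NA_real_, nb, na_)
  outer <- matrix(NA_real_, nb, na_)
  failed <- logical(nb)
  for (b in seq_len(nb)) {
    est <- delineate_bscan(volume$intensities[, , b], params)
    if (is.null(est)) { failed[b] <- TRUE; next }
    inner[b, ] <- smooth_lowess(est$inner, params$lowess_f, params$lowess_iter)
    outer[b, ] <- smooth_lowess(est$outer, params$lowess_f, params$lowess_iter)
  }
  if (mean(failed) > params$max_failed_frac)
    stopf("no candidate band: %d of %d B-scans failed delineation", sum(failed), nb)
  # interpolate failed B-scans from neighbours, then smooth across B-scans
  for (a in seq_len(na_)) {
    inner[, a] <- smooth_lowess(fill_na_1d(inner[, a]), params$lowess_f, params$lowess_iter)
    outer[, a] <- smooth_lowess(fill_na_1d(outer[, a]), params$lowess_f, params$lowess_iter)
  }
  inner <- clamp(inner, 1, nz)
  outer <- clamp(outer, 1, nz)
  swap <- inner > outer
  if (any(swap)) outer[swap] <- inner[swap]
  structure(list(inner = inner, outer = outer,
                 corrected = logical(nb), failed = failed,
                 n_axial = nz, spacing = volume$spacing),
            class = "choroid_boundaries")
}

#' @export
print.choroid_boundaries <- function(x, ...) {
  cat(sprintf("<choroid_boundaries> %d B-scans x %d A-scans; %d failed, %d corrected\n",
              nrow(x$inner), ncol(x$inner), sum(x$failed), sum(x$corrected)))
  invisible(x)
}

#' Apply manual boundary overrides
#'
#' Replaces delineated boundary positions verbatim at the given A-scan
#' locations and marks the touched B-scans as corrected. This hook stands in
#' for both the deep-learning segmenter and the human corrector of the
#' original workflow.
#'
#' @param boundaries a `choroid_boundaries` object.
#' @param overrides data frame with columns `bscan, ascan, inner_px, outer_px`
#'   (fractional pixels).
#' @return The corrected `choroid_boundaries`.
#' @export
apply_boundary_overrides <- function(boundaries, overrides) {
  stopifnot(inherits(boundaries, "choroid_boundaries"))
  if (is.null(overrides) || nrow(overrides) == 0) return(boundaries)
  need <- c("bscan", "ascan", "inner_px", "outer_px")
  if (!all(need %in% names(overrides)))
    stopf("overrides must have columns %s", paste(need, collapse = ", "))
  nb <- nrow(boundaries$inner); na_ <- ncol(boundaries$inner)
  for (r in seq_len(nrow(overrides))) {
    b <- overrides$bscan[r]; a <- overrides$ascan[r]
    if (!is_count(b) || b > nb || !is_count(a) || a > na_)
      stopf("override %d references invalid location (bscan=%s, ascan=%s)", r, b, a)
    inn <- overrides$inner_px[r]; out <- overrides$outer_px[r]
    if (!is.finite(inn) || !is.finite(out) || inn > out)
      stopf("override violates inner <= outer at (bscan=%d, ascan=%d)", b, a)
    if (inn < 1 || out > boundaries$n_axial)
      stopf("override outside axial extent at (bscan=%d, ascan=%d)", b, a)
    boundaries$inner[b, a] <- inn
    boundaries$outer[b, a] <- out
    boundaries$corrected[b] <- TRUE
  }
  boundaries
}

#' Choroidal thickness map
#'
#' @param boundaries a `choroid_boundaries` object.
#' @param spacing voxel spacing `(bscan, lateral, axial)` in micrometers;
#'   defaults to the spacing recorded on the boundaries.
#' @return Matrix `[bscan, ascan]` of thickness in micrometers,
#'   `(outer - inner) * axial spacing`.
#' @export
compute_thickness_map <- function(boundaries, spacing = NULL) {
  stopifnot(inherits(boundaries, "choroid_boundaries"))
  spacing <- spacing %||% boundaries$spacing
  dz <- if (length(spacing) == 3) spacing[[3]] else spacing[[1]]
  pmax(boundaries$outer - boundaries$inner, 0) * dz
}

# Logical choroid-band array (z, x, y): voxel centers between the fractional
# inner/outer boundary pixels.
band_array <- function(boundaries, n_axial = boundaries$n_axial) {
  nb <- nrow(boundaries$inner); na_ <- ncol(boundaries$inner)
  band <- array(FALSE, dim = c(n_axial, na_, nb))
  z <- seq_len(n_axial)
  for (b in seq_len(nb)) {
    innb <- boundaries$inner[b, ]; outb <- boundaries$outer[b, ]
    band[, , b] <- outer(z, innb, ">=") & outer(z, outb, "<=")
  }
  band
}

# Boundaries taken verbatim from phantom ground truth (oracle path used in
# tests and for GUI-free overrides).
boundaries_from_truth <- function(truth, spacing, n_axial) {
  inner_px <- truth$inner_um / spacing[["axial"]] + 1
  # the rendered band uses z < outer strictly; nudge so band_array() agrees
  outer_px <- truth$outer_um / spacing[["axial"]] + 1 - 1e-9
  structure(list(inner = inner_px, outer = outer_px,
                 corrected = rep(TRUE, nrow(inner_px)),
                 failed = logical(nrow(inner_px)),
                 n_axial = n_axial, spacing = spacing),
            class = "choroid_boundaries")
}
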