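# Automated analogue of the grader protocol: skeleton-based centerlines with
# inscribed radii, selection of the three largest vessels per sector, seeded
# random measurement sites on straight runs, the 50-um QC rule, and the
# sector/global aggregation of MChVD and IVD.

#' Extract vessel centerlines
#'
#' Resamples the labelled vasculature to isotropic voxels (nearest-neighbour,
#' at the smallest voxel dimension unless overridden), skeletonizes it with a
#' topology-preserving 3D thinning, and annotates every skeleton point with
#' its inscribed radius (the Euclidean distance transform value at the
#' skeleton voxel, in micrometres; exact to about half a voxel for
#' grid-aligned tubes), its neighbour degree, branch-point flags, and its
#' Euclidean
#' distance to the nearest branch point and to the nearest curve endpoint of
#' the same component. Straight runs are the skeleton stretches farther than
#' `l_min` from any branch point; measurement sites additionally keep `l_min`
#' away from curve endpoints, where open tube caps make the inscribed radius
#' unreliable.
#'
#' @param vasc a `vasculature3d` object.
#' @param l_min straight-run exclusion radius around branch points (um).
#' @param target_spacing isotropic resampling pitch (um); defaults to the
#'   smallest voxel dimension.
#' @return A `centerlines` object; `$points` is a data frame with component,
#'   isotropic voxel indices, micrometre coordinates, `radius_um`, `degree`,
#'   `is_branch`, `dist_branch_um` and (for unbranched components) a path
#'   order `ord`. An empty vasculature yields an empty result.
#' @export
extract_centerlines <- function(vasc, l_min = 100, target_spacing = NULL) {
  stopifnot(inherits(vasc, "vasculature3d"))
  d <- dim(vasc$labels)
  # array axes are (axial, ascan, bscan) -> spacings (axial, lateral, bscan)
  sp_axes <- c(vasc$spacing[["axial"]], vasc$spacing[["lateral"]], vasc$spacing[["bscan"]])
  target <- target_spacing %||% min(sp_axes)
  nd <- pmax(2L, as.integer(round((d - 1) * sp_axes / target)) + 1L)
  maps <- lapply(1:3, function(ax)
    clamp(round((seq_len(nd[ax]) - 1) * target / sp_axes[ax]) + 1L, 1L, d[ax]))
  labels_iso <- vasc$labels[maps[[1]], maps[[2]], maps[[3]], drop = FALSE]
  empty <- data.frame(component = integer(), i = integer(), j = integer(),
                      k = integer(), x = numeric(), y = numeric(), z = numeric(),
                      radius_um = numeric(), degree = integer(),
                      is_branch = logical(), dist_branch_um = numeric(),
                      ord = integer())
  obj <- structure(list(points = empty, labels_iso = labels_iso, dims_iso = nd,
                        target_spacing = target, l_min = l_min,
                        cache = new.env(parent = emptyenv())),
                   class = "centerlines")
  if (!any(labels_iso > 0)) return(obj)

  mask_iso <- labels_iso > 0
  skel <- array(skeletonize3(as.vector(mask_iso), nd), dim = nd)
  edt <- array(edt3(as.vector(mask_iso), nd, rep(target, 3)), dim = nd)
  pts <- which(skel, arr.ind = TRUE)
  colnames(pts) <- c("i", "j", "k")

  # neighbour degree within the skeleton (26-connectivity)
  deg <- integer(nrow(pts))
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    ii <- pts[, 1] + di; jj <- pts[, 2] + dj; kk <- pts[, 3] + dk
    ok <- ii >= 1 & jj >= 1 & kk >= 1 & ii <= nd[1] & jj <= nd[2] & kk <= nd[3]
    deg[ok] <- deg[ok] + skel[cbind(ii[ok], jj[ok], kk[ok])]
  }

  comp <- labels_iso[pts]
  p <- data.frame(component = comp,
                  i = pts[, 1], j = pts[, 2], k = pts[, 3],
                  x = (pts[, 2] - 1) * target,
                  y = (pts[, 3] - 1) * target,
                  z = (pts[, 1] - 1) * target,
                  radius_um = edt[pts],
                  degree = deg,
                  is_branch = deg >= 3L,
                  dist_branch_um = Inf, dist_end_um = Inf, ord = NA_integer_)

  for (cid in unique(p$component)) {
    sel <- which(p$component == cid)
    br <- sel[p$is_branch[sel]]
    en <- sel[p$degree[sel] <= 1L]
    if (length(en)) {
      d2e <- outer(p$x[sel], p$x[en], "-")^2 + outer(p$y[sel], p$y[en], "-")^2 +
        outer(p$z[sel], p$z[en], "-")^2
      p$dist_end_um[sel] <- sqrt(apply(cbind(d2e), 1, min))
    }
    if (length(br)) {
      d2 <- outer(p$x[sel], p$x[br], "-")^2 + outer(p$y[sel], p$y[br], "-")^2 +
        outer(p$z[sel], p$z[br], "-")^2
      p$dist_branch_um[sel] <- sqrt(apply(d2, 1, min))
    } else if (length(sel) > 1) {
      # unbranched: order along the path by a greedy nearest-neighbour walk
      ends <- sel[p$degree[sel] <= 1L]
      start <- if (length(ends)) ends[1] else sel[1]
      coords <- cbind(p$x[sel], p$y[sel], p$z[sel])
      rownames(coords) <- sel
      visited <- logical(length(sel)); names(visited) <- sel
      cur <- as.character(start); ordv <- integer(0)
      repeat {
        visited[cur] <- TRUE
        ordv <- c(ordv, as.integer(cur))
        rem <- which(!visited)
        if (!length(rem)) break
        dd <- colSums((t(coords[names(rem), , drop = FALSE]) - coords[cur, ])^2)
        nxt <- names(rem)[which.min(dd)]
        if (min(dd) > (2 * sqrt(3) * target)^2) break  # disconnected leftover
        cur <- nxt
      }
      p$ord[ordv] <- seq_along(ordv)
    }
  }
  obj$points <- p
  obj
}

#' @export
print.centerlines <- function(x, ...) {
  cat(sprintf("<centerlines> %d points, %d components, %d branch points (iso %.1f um)\n",
              nrow(x$points), length(unique(x$points$component)),
              sum(x$points$is_branch), x$target_spacing))
  invisible(x)
}

# Within-sector luminal volume (um^3) of every component: matrix
# [component, sector].
sector_component_volumes <- function(vasc, grid) {
  d <- dim(vasc$labels)
  pos <- which(vasc$labels > 0)
  n <- vasc$n_components
  out <- matrix(0, nrow = n, ncol = 5, dimnames = list(NULL, sector_names()))
  if (!length(pos) || n == 0) return(out)
  sm <- sector_map(grid)
  j <- ((pos - 1L) %/% d[1]) %% d[2] + 1L   # ascan
  k <- (pos - 1L) %/% (d[1] * d[2]) + 1L    # bscan
  sec <- sm[cbind(k, j)]
  lab <- vasc$labels[pos]
  counts <- tapply(rep(1, length(pos)), list(factor(lab, levels = seq_len(n)),
                                             factor(sec, levels = sector_names())),
                   sum, default = 0)
  out[] <- counts * prod(vasc$spacing)
  out
}

#' Rank the largest vessels of a sector
#'
#' Components are ranked by their luminal volume *within* the sector
#' footprint; ties break toward the lower component label. Fewer than `n`
#' available vessels are all returned with a shortfall flag.
#'
#' @param vasc a `vasculature3d`.
#' @param grid a `sector_grid`.
#' @param sector one of `central, nasal, temporal, superior, inferior`.
#' @param n number of vessels requested (protocol default 3).
#' @return `list(ids, volumes_um3, shortfall)`; zero vessels gives empty ids.
#' @export
select_largest_vessels <- function(vasc, grid, sector, n = 3L) {
  sector <- match.arg(sector, sector_names())
  sv <- sector_component_volumes(vasc, grid)[, sector]
  ids <- which(sv > 0)
  ids <- ids[order(-sv[ids], ids)]
  list(ids = head(ids, n), volumes_um3 = sv[head(ids, n)],
       shortfall = length(ids) < n, ranked = ids)
}

eligible_sites <- function(cl, component, grid, sector) {
  p <- cl$points
  sel <- p$component == component & p$dist_branch_um >= cl$l_min &
    p$dist_end_um >= cl$l_min
  if (!any(sel)) return(integer(0))
  idx <- which(sel)
  idx[sector_of_xy(grid, p$x[idx], p$y[idx]) == sector]
}

#' Measure cross-sectional diameters of a vessel
#'
#' Draws `n_sites` seeded random sites from the vessel's in-sector straight
#' runs (skeleton points at least `l_min` from any branch point) and reports
#' the inscribed diameter `2 x radius` at each site, in micrometres.
#'
#' @param cl a `centerlines` object.
#' @param component component label of the vessel.
#' @param grid,sector sector restriction for the sites.
#' @param n_sites number of measurement sites (protocol default 3).
#' @param seed integer seed; fixed seed gives identical site choices.
#' @return Numeric vector of diameters with the chosen point indices as
#'   attribute `sites`, or `NULL` when the vessel has no straight run in the
#'   sector (caller should fall back to the next-largest vessel).
#' @export
measure_diameters <- function(cl, component, grid, sector, n_sites = 3L, seed = 1L) {
  idx <- eligible_sites(cl, component, grid, sector)
  if (!length(idx)) return(NULL)
  sites <- with_seed(seed,
    idx[sample.int(length(idx), n_sites, replace = length(idx) < n_sites)])
  out <- 2 * cl$points$radius_um[sites]
  attr(out, "sites") <- sites
  out
}

#' Measure intervessel distances of a vessel
#'
#' At `n_sites` seeded random straight-run sites of the selected vessel, the
#' IVD is the edge-to-edge gap to the nearest independent vessel: the distance
#' from the site to the nearest voxel of *another* 26-connected component,
#' minus the vessel's own inscribed radius at the site. Collaterals (same
#' component) are excluded by construction.
#'
#' @inheritParams measure_diameters
#' @return Numeric vector of gaps (um), or `NULL` when the vessel has no
#'   straight run in the sector. All-`NA` when no independent vessel exists.
#' @export
measure_ivd <- function(cl, component, grid, sector, n_sites = 3L, seed = 1L) {
  idx <- eligible_sites(cl, component, grid, sector)
  if (!length(idx)) return(NULL)
  key <- paste0("dother_", component)
  d_other <- cl$cache[[key]]
  if (is.null(d_other)) {
    others <- cl$labels_iso > 0 & cl$labels_iso != component
    if (!any(others)) return(rep(NA_real_, n_sites))
    d_other <- array(edt3(as.vector(!others), cl$dims_iso,
                          rep(cl$target_spacing, 3)), dim = cl$dims_iso)
    cl$cache[[key]] <- d_other
  }
  sites <- with_seed(seed,
    idx[sample.int(length(idx), n_sites, replace = length(idx) < n_sites)])
  p <- cl$points[sites, ]
  gap <- d_other[cbind(p$i, p$j, p$k)] - p$radius_um
  out <- pmax(gap, 0)
  attr(out, "sites") <- sites
  out
}

qc_redraw <- function(measure_fun, qc_threshold, max_attempts, seed) {
  qc_remeasured <- FALSE
  for (attempt in seq_len(max_attempts)) {
    vals <- measure_fun(derive_seed(seed, attempt))
    if (is.null(vals)) return(NULL)
    s <- if (sum(is.finite(vals)) >= 2) sd(vals[is.finite(vals)]) else 0
    if (!is.finite(s) || s <= qc_threshold)
      return(list(values = vals, qc_remeasured = qc_remeasured, max_attempts = FALSE))
    qc_remeasured <- TRUE
  }
  list(values = vals, qc_remeasured = TRUE, max_attempts = TRUE)
}

#' Sector and global vessel biomarkers of one eye
#'
#' Runs the full measurement protocol: per sector, the three largest vessels
#' (falling back to further candidates when a vessel exposes no straight run
#' in the sector) are measured at three seeded random sites each for diameter
#' and for intervessel distance, giving nine values per sector and biomarker;
#' a vessel whose triplet has a sample standard deviation above
#' `qc_threshold` (50 um) is re-measured with a fresh seeded draw (up to
#' `max_attempts`, keeping the last triplet with a flag). Sector MChVD/IVD are
#' the means of the nine retained values and the global value is the
#' unweighted mean of the five sector values. CTh and CVI sector values are
#' attached when a thickness map and vessel mask are supplied.
#'
#' @param vasc a `vasculature3d`.
#' @param cl its [extract_centerlines()] result.
#' @param grid a `sector_grid`.
#' @param thickness_map optional `[bscan, ascan]` thickness map (um).
#' @param mask optional `vessel_mask` for CVI.
#' @param n_vessels,n_sites protocol counts (3 and 3).
#' @param qc_threshold QC limit on a vessel's triplet SD (um).
#' @param max_attempts bound on QC redraws.
#' @param seed integer seed feeding every site draw.
#' @param eye_id,subject_id,group labels carried into the output.
#' @return An `eye_biomarkers` object: `$sectors` (per-sector data frame),
#'   `$global` (named vector, unweighted five-sector means),
#'   `$measurements` (one row per site), and `$n_vessels_measured`.
#' @export
sector_and_global_metrics <- function(vasc, cl, grid, thickness_map = NULL,
                                      mask = NULL, n_vessels = 3L, n_sites = 3L,
                                      qc_threshold = 50, max_attempts = 5L,
                                      seed = 1L, eye_id = "eye", subject_id = eye_id,
                                      group = NA_character_) {
  secs <- sector_names()
  meas <- list()
  sector_rows <- list()
  n_measured <- 0L
  for (s in secs) {
    ranked <- select_largest_vessels(vasc, grid, s, n = n_vessels)$ranked
    chosen <- list()
    for (id in ranked) {
      if (length(chosen) >= n_vessels) break
      dres <- qc_redraw(function(sd_seed)
        measure_diameters(cl, id, grid, s, n_sites, seed = sd_seed),
        qc_threshold, max_attempts, derive_seed(seed, s, id, "diam"))
      if (is.null(dres)) next  # no straight run in sector: next-largest vessel
      ires <- qc_redraw(function(sd_seed)
        measure_ivd(cl, id, grid, s, n_sites, seed = sd_seed),
        qc_threshold, max_attempts, derive_seed(seed, s, id, "ivd"))
      chosen[[length(chosen) + 1L]] <- list(id = id, d = dres, i = ires)
    }
    if (!length(chosen)) {
      sector_rows[[s]] <- data.frame(sector = s, mchvd_um = NA_real_,
                                     ivd_um = NA_real_, n_vessels = 0L)
      next
    }
    diams <- unlist(lapply(chosen, function(v) as.numeric(v$d$values)))
    ivds <- unlist(lapply(chosen, function(v)
      if (is.null(v$i)) rep(NA_real_, n_sites) else as.numeric(v$i$values)))
    n_measured <- n_measured + length(chosen)
    for (rk in seq_along(chosen)) {
      v <- chosen[[rk]]
      meas[[length(meas) + 1L]] <- data.frame(
        eye_id = eye_id, sector = s, vessel_rank = rk, component = v$id,
        site = seq_len(n_sites),
        diameter_um = as.numeric(v$d$values),
        ivd_um = if (is.null(v$i)) NA_real_ else as.numeric(v$i$values),
        qc_remeasured = v$d$qc_remeasured ||
          (!is.null(v$i) && isTRUE(v$i$qc_remeasured)),
        qc_max_attempts = isTRUE(v$d$max_attempts) ||
          (!is.null(v$i) && isTRUE(v$i$max_attempts)))
    }
    sector_rows[[s]] <- data.frame(
      sector = s,
      mchvd_um = mean(diams, na.rm = TRUE),
      ivd_um = if (all(is.na(ivds))) NA_real_ else mean(ivds, na.rm = TRUE),
      n_vessels = length(chosen))
  }
  sectors <- do.call(rbind, sector_rows)
  rownames(sectors) <- NULL
  if (!is.null(thickness_map))
    sectors$cth_um <- aggregate_by_sector(thickness_map, grid)[sectors$sector]
  if (!is.null(mask))
    sectors$cvi_pct <- compute_cvi(mask, grid)$sector[sectors$sector]

  global_of <- function(v) {
    miss <- is.na(v)
    if (all(miss)) return(NA_real_)
    if (any(miss))
      warning("sector(s) without measurements excluded from the global mean: ",
              paste(sectors$sector[miss], collapse = ", "))
    mean(v[!miss])
  }
  global <- c(mchvd_um = global_of(sectors$mchvd_um),
              ivd_um = global_of(sectors$ivd_um))
  if (!is.null(sectors$cth_um)) global["cth_um"] <- global_of(sectors$cth_um)
  if (!is.null(sectors$cvi_pct)) global["cvi_pct"] <- global_of(sectors$cvi_pct)

  structure(list(sectors = sectors, global = global,
                 measurements = if (length(meas)) do.call(rbind, meas) else NULL,
                 n_vessels_measured = n_measured,
                 eye_id = eye_id, subject_id = subject_id, group = group),
            class = "eye_biomarkers")
}

#' @export
print.eye_biomarkers <- function(x, ...) {
  cat(sprintf("<eye_biomarkers '%s'> %d vessels measured\n", x$eye_id,
              x$n_vessels_measured))
  print(round(x$global, 2))
  invisible(x)
}

#' End-to-end analysis of one volume
#'
#' Convenience wrapper chaining boundary delineation (or supplied/override
#' boundaries), vessel binarization, optic-disc exclusion, labelling,
#' centerline extraction and the sector measurement protocol.
#'
#' @param volume an [oct_volume()].
#' @param seg,bin parameter lists ([seg_params()], [binarization_params()]).
#' @param boundaries optional precomputed `choroid_boundaries` (e.g. ground
#'   truth or manually corrected); skips delineation.
#' @param overrides optional boundary override data frame.
#' @param disc optional optic-disc circle or raster for [mask_optic_disc()].
#' @param central_radius,nasal_side grid options.
#' @param l_min,target_spacing centerline options.
#' @param seed seed for the measurement protocol.
#' @param eye_id,subject_id,group labels carried into the biomarkers.
#' @return List with `boundaries`, `thickness_map`, `mask`, `vasc`,
#'   `centerlines`, `grid` and `biomarkers`.
#' @export
analyze_volume <- function(volume, seg = seg_params(), bin = binarization_params(),
                           boundaries = NULL, overrides = NULL, disc = NULL,
                           central_radius = 2000, nasal_side = NULL,
                           l_min = 100, target_spacing = NULL, seed = 1L,
                           eye_id = volume$id, subject_id = eye_id,
                           group = NA_character_) {
  if (is.null(boundaries)) boundaries <- delineate_choroid(volume, seg)
  if (!is.null(overrides)) boundaries <- apply_boundary_overrides(boundaries, overrides)
  thickness_map <- compute_thickness_map(boundaries, volume$spacing)
  mask <- binarize_vessels(volume, boundaries, bin)
  mask <- mask_optic_disc(mask, disc)
  vasc <- label_vasculature(mask)
  grid <- build_sector_grid(volume, central_radius = central_radius,
                            nasal_side = nasal_side)
  cl <- extract_centerlines(vasc, l_min = l_min, target_spacing = target_spacing)
  bio <- sector_and_global_metrics(vasc, cl, grid, thickness_map = thickness_map,
                                   mask = mask, seed = seed, eye_id = eye_id,
                                   subject_id = subject_id, group = group)
  list(boundaries = boundaries, thickness_map = thickness_map, mask = mask,
       vasc = vasc, centerlines = cl, grid = grid, biomarkers = bio)
}
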