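# Plain-text serialization. Volumes travel as a whitespace-separated value
# stream plus a JSON sidecar (dimensions, spacing, laterality, fovea); no
# binary container is used so artifacts stay inspectable and diffable.

#' Write / read an OCT volume as text + JSON sidecar
#'
#' `<path>` receives the intensity stream (R array order, axial fastest) and
#' `<path>.json` the metadata sidecar.
#'
#' @param volume an [oct_volume()].
#' @param path output file path.
#' @return `write_volume_text` the path, invisibly; `read_volume_text` an
#'   `oct_volume`.
#' @export
write_volume_text <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  meta <- list(dim = dim(volume$intensities), spacing = as.list(volume$spacing),
               laterality = volume$laterality,
               fovea_index = as.list(volume$fovea_index), id = volume$id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  write(signif(as.vector(volume$intensities), 7), file = con, ncolumns = 16)
  invisible(path)
}

#' @rdname write_volume_text
#' @export
read_volume_text <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- scan(path, what = numeric(), quiet = TRUE)
  arr <- array(vals, dim = unlist(meta$dim))
  oct_volume(arr, spacing = unlist(meta$spacing), laterality = meta$laterality,
             fovea_index = unlist(meta$fovea_index), id = meta$id)
}

#' Write / read choroid boundaries as CSV
#'
#' Long format `bscan, ascan, inner_px, outer_px` (fractional pixels), the
#' same schema accepted by [apply_boundary_overrides()].
#'
#' @param boundaries a `choroid_boundaries` object.
#' @param path CSV path.
#' @param n_axial,spacing reconstruction metadata for `read_boundaries_csv`.
#' @return The path / a `choroid_boundaries`.
#' @export
write_boundaries_csv <- function(boundaries, path) {
  stopifnot(inherits(boundaries, "choroid_boundaries"))
  nb <- nrow(boundaries$inner); na_ <- ncol(boundaries$inner)
  df <- data.frame(bscan = rep(seq_len(nb), na_),
                   ascan = rep(seq_len(na_), each = nb),
                   inner_px = as.vector(boundaries$inner),
                   outer_px = as.vector(boundaries$outer))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boundaries_csv
#' @export
read_boundaries_csv <- function(path, n_axial, spacing = c(10, 10, 10)) {
  df <- read.csv(path)
  nb <- max(df$bscan); na_ <- max(df$ascan)
  inner <- matrix(NA_real_, nb, na_); outer <- matrix(NA_real_, nb, na_)
  inner[cbind(df$bscan, df$ascan)] <- df$inner_px
  outer[cbind(df$bscan, df$ascan)] <- df$outer_px
  structure(list(inner = inner, outer = outer, corrected = logical(nb),
                 failed = logical(nb), n_axial = n_axial,
                 spacing = setNames(as.numeric(spacing), c("bscan", "lateral", "axial"))),
            class = "choroid_boundaries")
}

#' Write an eye's biomarkers in the cohort CSV schema
#'
#' @param bio an `eye_biomarkers` object.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_biomarkers_csv <- function(bio, path) {
  stopifnot(inherits(bio, "eye_biomarkers"))
  sec <- bio$sectors
  g <- as.list(bio$global)
  rows <- data.frame(subject_id = bio$subject_id, eye = bio$eye_id,
                     group = bio$group,
                     sector = c("mean", sec$sector),
                     mchvd_um = c(g$mchvd_um, sec$mchvd_um),
                     ivd_um = c(g$ivd_um, sec$ivd_um),
                     cth_um = c(g$cth_um %||% NA_real_, sec$cth_um %||% rep(NA_real_, nrow(sec))),
                     cvi_pct = c(g$cvi_pct %||% NA_real_, sec$cvi_pct %||% rep(NA_real_, nrow(sec))))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table CSV
#'
#' @param path CSV with columns `subject_id, eye, group, sector` plus
#'   biomarker columns.
#' @return Data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "eye", "group", "sector")
  if (!all(need %in% names(df)))
    stopf("cohort CSV needs columns %s", paste(need, collapse = ", "))
  df
}
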