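#' Published group parameters of the choroidal biomarkers
#'
#' Mean and standard deviation of MChVD, IVD, CTh and CVI per sector and per
#' group (chronic CSC eyes, unaffected fellow eyes, healthy controls), as used
#' for the defaults of the synthetic cohort generator. The `"mean"` sector
#' rows hold the global (five-sector mean) summaries. These are generator
#' inputs, not results this package claims to reproduce.
#'
#' Note: the cCSC superior-sector MChVD standard deviation is kept verbatim at
#' 289.94 um even though it is out of line with the sibling sectors; no
#' default simulation depends on it.
#'
#' @return Data frame with columns `group, biomarker, sector, mean, sd`.
#' @export
reference_biomarker_params <- function() {
  sec <- c("mean", "nasal", "temporal", "inferior", "superior", "central")
  build <- function(biomarker, group, means, sds)
    data.frame(group = group, biomarker = biomarker, sector = sec,
               mean = means, sd = sds)
  rbind(
    build("cth_um", "cCSC", c(288.90, 251.49, 276.94, 289.88, 271.54, 364.62),
          c(64.77, 62.73, 63.30, 77.33, 71.68, 77.33)),
    build("cth_um", "fellow", c(269.76, 237.42, 271.27, 244.83, 267.13, 338.94),
          c(71.17, 71.66, 77.97, 63.11, 65.51, 91.12)),
    build("cth_um", "healthy", c(223.97, 204.87, 232.52, 235.18, 205.91, 251.03),
          c(43.40, 62.18, 48.28, 39.29, 45.49, 54.40)),
    build("cvi_pct", "cCSC", c(38.14, 38.83, 39.31, 40.63, 41.81, 39.53),
          c(5.55, 3.64, 2.22, 3.50, 2.30, 2.47)),
    build("cvi_pct", "fellow", c(37.23, 37.33, 38.16, 40.25, 41.27, 39.68),
          c(6.41, 3.00, 2.98, 3.79, 2.74, 2.39)),
    build("cvi_pct", "healthy", c(40.65, 40.58, 40.35, 42.15, 41.12, 40.64),
          c(3.53, 5.35, 4.28, 3.54, 3.63, 3.51)),
    build("mchvd_um", "cCSC", c(362.50, 341.57, 365.82, 376.89, 370.99, 357.26),
          c(83.23, 84.19, 98.78, 91.04, 289.94, 84.50)),
    build("mchvd_um", "fellow", c(276.84, 263.32, 281.72, 289.85, 289.14, 261.05),
          c(26.89, 44.19, 43.39, 38.86, 47.61, 43.30)),
    build("mchvd_um", "healthy", c(233.28, 220.12, 239.93, 250.45, 239.62, 224.93),
          c(28.18, 35.68, 38.35, 41.12, 43.83, 48.52)),
    build("ivd_um", "cCSC", c(196.53, 189.70, 194.30, 192.96, 202.66, 203.02),
          c(23.58, 34.86, 44.57, 36.95, 39.95, 41.90)),
    build("ivd_um", "fellow", c(225.05, 219.20, 235.37, 229.41, 221.23, 200.04),
          c(33.72, 42.89, 51.96, 60.82, 58.98, 41.90)),
    build("ivd_um", "healthy", c(264.13, 255.60, 278.41, 238.76, 259.31, 300.13),
          c(46.06, 70.06, 59.44, 68.04, 71.06, 76.68)))
}

#' Specify a synthetic biomarker cohort
#'
#' Defines groups of eyes with per-sector biomarker means/SDs, a paired-eye
#' structure (affected and fellow eyes of the same subject share a subject
#' random effect), a within-subject correlation for paired eyes, and a latent
#' cross-biomarker coupling between CTh and MChVD. Defaults reproduce the
#' study structure: 30 cCSC eyes of 30 subjects, 22 fellow eyes paired with
#' the first 22 of those subjects, 26 healthy eyes of 26 further subjects.
#'
#' @param params data frame `group, biomarker, sector, mean, sd` (defaults to
#'   [reference_biomarker_params()]). If only `"mean"` sector rows are present
#'   the cohort is generated at the eye level directly.
#' @param n_eyes named integer vector of eyes per group (>= 2 each).
#' @param paired_groups length-2 character: the two groups whose eyes pair up
#'   within a subject (in order affected, fellow); `NULL` disables pairing.
#' @param n_pairs number of paired subjects; default the smaller group size.
#' @param within_subject_corr correlation of paired-eye residuals, in [0, 1].
#' @param sector_loading loading of the shared eye-level factor in each sector
#'   value, in [0, 1]; high values make sectors of one eye move together (the
#'   published sector and global SDs are nearly equal, implying a loading
#'   near 1).
#' @param biomarker_corr latent correlation between CTh and MChVD residuals.
#' @param seed integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(params = reference_biomarker_params(),
                        n_eyes = c(cCSC = 30L, fellow = 22L, healthy = 26L),
                        paired_groups = c("cCSC", "fellow"), n_pairs = NULL,
                        within_subject_corr = 0.5, sector_loading = 0.9,
                        biomarker_corr = 0.55, seed = 1L) {
  need <- c("group", "biomarker", "sector", "mean", "sd")
  if (!all(need %in% names(params))) stopf("params needs columns %s", paste(need, collapse = ", "))
  if (any(params$sd < 0)) stopf("SDs must be >= 0")
  if (is.null(names(n_eyes)) || any(n_eyes < 2)) stopf("n_eyes must be named and >= 2 per group")
  if (!all(names(n_eyes) %in% params$group)) stopf("every group in n_eyes needs rows in params")
  if (within_subject_corr < 0 || within_subject_corr > 1)
    stopf("within_subject_corr must lie in [0, 1]")
  if (sector_loading < 0 || sector_loading > 1) stopf("sector_loading must lie in [0, 1]")
  if (abs(biomarker_corr) > 1) stopf("biomarker_corr must lie in [-1, 1]")
  if (!is.null(paired_groups)) {
    if (!all(paired_groups %in% names(n_eyes))) stopf("paired_groups must name groups in n_eyes")
    n_pairs <- n_pairs %||% min(n_eyes[paired_groups])
    if (n_pairs > min(n_eyes[paired_groups])) stopf("n_pairs exceeds a paired group size")
  }
  structure(list(params = params, n_eyes = n_eyes, paired_groups = paired_groups,
                 n_pairs = n_pairs, within_subject_corr = within_subject_corr,
                 sector_loading = sector_loading, biomarker_corr = biomarker_corr,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic per-eye biomarker cohort
#'
#' Each biomarker value is `mean + sd * z`, where the standardized residual
#' `z` mixes a subject share and an eye share,
#' `z = sqrt(rho) * z_subject + sqrt(1 - rho) * z_eye`, at both the eye level
#' (shared across sectors with loading `sector_loading`) and the sector level,
#' so paired eyes of one subject correlate at exactly `rho =
#' within_subject_corr` in every sector. Cross-biomarker coupling (CTh-MChVD)
#' is injected into all latent factors. The `"mean"` sector row of each eye is
#' the unweighted mean of its five sector rows (or the direct draw when the
#' spec only carries `"mean"` parameters).
#'
#' @param spec a [cohort_spec()].
#' @return Data frame `subject_id, eye, group, sector` plus one column per
#'   biomarker present in the spec.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  canonical <- c("mchvd_um", "ivd_um", "cth_um", "cvi_pct")
  bms <- intersect(canonical, unique(spec$params$biomarker))
  if (!length(bms)) bms <- unique(spec$params$biomarker)
  sectors <- setdiff(unique(spec$params$sector), "mean")
  direct_mean <- length(sectors) == 0
  if (direct_mean) sectors <- "mean"
  nb <- length(bms); ns <- length(sectors)

  # cross-biomarker correlation factor (CTh-MChVD only)
  C <- diag(nb)
  dimnames(C) <- list(bms, bms)
  if (all(c("cth_um", "mchvd_um") %in% bms)) {
    C["cth_um", "mchvd_um"] <- spec$biomarker_corr
    C["mchvd_um", "cth_um"] <- spec$biomarker_corr
  }
  U <- chol(C)
  corr_draw <- function(n) matrix(rnorm(n * nb), n, nb) %*% U

  # eye roster: group, subject id, eye id
  roster <- list()
  pg <- spec$paired_groups
  for (g in names(spec$n_eyes)) {
    n <- spec$n_eyes[[g]]
    for (i in seq_len(n)) {
      subj <- if (!is.null(pg) && g %in% pg && i <= spec$n_pairs)
        sprintf("S%03d", i) else sprintf("%s%03d", g, i)
      roster[[length(roster) + 1L]] <- data.frame(
        group = g, subject_id = subj,
        eye = sprintf("%s_e%03d", g, i))
    }
  }
  roster <- do.call(rbind, roster)
  subjects <- unique(roster$subject_id)
  n_eye <- nrow(roster); n_sub <- length(subjects)
  rho <- spec$within_subject_corr; lam <- spec$sector_loading

  lookup <- function(g, b, s) {
    r <- spec$params[spec$params$group == g & spec$params$biomarker == b &
                       spec$params$sector == s, , drop = FALSE]
    if (nrow(r) != 1) stopf("missing parameter row for (%s, %s, %s)", g, b, s)
    c(r$mean, r$sd)
  }

  with_seed(spec$seed, {
    u_subj <- corr_draw(n_sub); rownames(u_subj) <- subjects
    u_eye <- corr_draw(n_eye)
    e_subj <- array(corr_draw(n_sub * ns), dim = c(n_sub, ns, nb))
    e_eye <- array(corr_draw(n_eye * ns), dim = c(n_eye, ns, nb))

    rows <- vector("list", n_eye)
    for (ei in seq_len(n_eye)) {
      g <- roster$group[ei]; si <- match(roster$subject_id[ei], subjects)
      sect_vals <- matrix(NA_real_, ns, nb, dimnames = list(sectors, bms))
      for (bi in seq_len(nb)) {
        z_eye_shared <- sqrt(rho) * u_subj[si, bi] + sqrt(1 - rho) * u_eye[ei, bi]
        for (sj in seq_len(ns)) {
          z_sec <- sqrt(rho) * e_subj[si, sj, bi] + sqrt(1 - rho) * e_eye[ei, sj, bi]
          z <- lam * z_eye_shared + sqrt(1 - lam^2) * z_sec
          ms <- lookup(g, bms[bi], sectors[sj])
          sect_vals[sj, bi] <- ms[1] + ms[2] * z
        }
      }
      df <- data.frame(subject_id = roster$subject_id[ei], eye = roster$eye[ei],
                       group = g, sector = sectors)
      df <- cbind(df, as.data.frame(sect_vals))
      if (!direct_mean) {
        mrow <- data.frame(subject_id = roster$subject_id[ei], eye = roster$eye[ei],
                           group = g, sector = "mean")
        mrow <- cbind(mrow, as.data.frame(t(colMeans(sect_vals))))
        df <- rbind(mrow, df)
      }
      rows[[ei]] <- df
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
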