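# Cohort statistics: linear mixed models with Bonferroni pairwise contrasts,
# two-way absolute-agreement ICC, Pearson correlations and Fisher exact tests.

#' Linear mixed model comparing eye groups
#'
#' Fits `biomarker ~ group + (1 | subject)` with a restricted-likelihood fit
#' for the estimates, an omnibus Wald F test of the group effect referenced
#' against `n_subjects - n_groups` denominator degrees of freedom (the
#' chi-square likelihood-ratio reference is visibly anticonservative at
#' cohort sizes of a few dozen subjects; see the methods vignette), and the
#' three pairwise group contrasts as t tests on the same degrees of freedom
#' with Bonferroni adjustment (multiplier = number of pairs). Shapiro-Wilk
#' normality is reported per group on the model residuals. When no subject
#' contributes more than one eye the random intercept is unidentifiable and
#' the model falls back to an ordinary linear model (subject = eye), with a
#' note.
#'
#' @param table a cohort data frame (schema of [generate_cohort()]).
#' @param biomarker column to analyse, e.g. `"mchvd_um"`.
#' @param sector sector row to analyse (default `"mean"`, the global value).
#' @return An `lmm_result` list: `estimates` (group means), `omnibus_p`,
#'   `pairwise` (data frame with raw and Bonferroni-adjusted p),
#'   `ranef_variance`, `shapiro` (per-group W and p on residuals), `method`
#'   and `note`.
#' @export
fit_group_lmm <- function(table, biomarker, sector = "mean") {
  df <- table[table$sector == sector & is.finite(table[[biomarker]]), , drop = FALSE]
  if (!nrow(df)) stopf("no rows for sector '%s'", sector)
  df$value <- df[[biomarker]]
  df$group <- factor(df$group)
  df$subject_id <- factor(df$subject_id)
  tab <- table(df$group)
  if (length(tab) < 2 || any(tab < 3))
    stopf("need >= 2 groups with >= 3 eyes each (got %s)",
          paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  groups <- levels(df$group)
  pairs <- utils::combn(groups, 2)
  n_pairs <- ncol(pairs)

  # degenerate: no variance at all -> no group effect by construction
  if (var(df$value) < 1e-12) {
    pw <- data.frame(contrast = paste(pairs[1, ], pairs[2, ], sep = "-"),
                     estimate = 0, p_raw = 1, p_bonferroni = 1)
    return(structure(list(biomarker = biomarker, sector = sector,
                          estimates = vapply(split(df$value, df$group), mean,
                                             numeric(1)),
                          omnibus_p = 1, pairwise = pw, ranef_variance = 0,
                          shapiro = NULL, method = "degenerate",
                          note = "zero variance in response"),
                     class = "lmm_result"))
  }

  paired <- any(duplicated(df$subject_id))
  if (paired) {
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                              calc.derivs = FALSE)
    fit <- lme4::lmer(value ~ group + (1 | subject_id), data = df,
                      REML = TRUE, control = ctrl)
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    vc <- as.data.frame(lme4::VarCorr(fit))
    ranef_var <- vc$vcov[vc$grp == "subject_id"][1]
    resid_vals <- stats::residuals(fit)
    df2 <- max(nlevels(droplevels(df$subject_id)) - length(groups), 1L)
    method <- "lmm"
    note <- NULL
  } else {
    fit <- lm(value ~ group, data = df)
    beta <- stats::coef(fit)
    V <- as.matrix(stats::vcov(fit))
    ranef_var <- NA_real_
    resid_vals <- stats::residuals(fit)
    df2 <- max(nrow(df) - length(groups), 1L)
    method <- "lm"
    note <- "no paired eyes: random intercept unidentifiable, subject = eye"
  }

  # omnibus Wald F on the group effects
  eff <- grep("^group", names(beta))
  Cm <- matrix(0, length(eff), length(beta))
  Cm[cbind(seq_along(eff), eff)] <- 1
  q <- length(eff)
  wald <- drop(t(Cm %*% beta) %*% solve(Cm %*% V %*% t(Cm)) %*% (Cm %*% beta))
  omnibus_p <- pf(wald / q, q, df2, lower.tail = FALSE)

  # group means and pairwise contrasts on the fixed effects
  cn <- names(beta)
  coef_of <- function(g) {
    nm <- paste0("group", g)
    v <- numeric(length(beta)); names(v) <- cn
    v["(Intercept)"] <- 1
    if (nm %in% cn) v[nm] <- 1
    v
  }
  est <- vapply(groups, function(g) sum(coef_of(g) * beta), numeric(1))
  pw <- lapply(seq_len(n_pairs), function(i) {
    cvec <- coef_of(pairs[1, i]) - coef_of(pairs[2, i])
    d <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tt <- d / se
    data.frame(contrast = paste(pairs[1, i], pairs[2, i], sep = "-"),
               estimate = d, se = se,
               p_raw = 2 * stats::pt(-abs(tt), df2))
  })
  pw <- do.call(rbind, pw)
  pw$p_bonferroni <- pmin(1, pw$p_raw * n_pairs)

  shap <- lapply(groups, function(g) {
    r <- resid_vals[df$group == g]
    if (length(unique(round(r, 10))) < 3 || length(r) < 3 || length(r) > 5000)
      return(data.frame(group = g, W = NA_real_, p = NA_real_))
    s <- shapiro.test(r)
    data.frame(group = g, W = unname(s$statistic), p = s$p.value)
  })

  structure(list(biomarker = biomarker, sector = sector, estimates = est,
                 omnibus_p = omnibus_p, pairwise = pw,
                 ranef_variance = ranef_var,
                 shapiro = do.call(rbind, shap), method = method, note = note),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("<lmm_result> %s [%s], omnibus p = %.4g (%s)\n",
              x$biomarker, x$sector, x$omnibus_p, x$method))
  print(x$pairwise[, c("contrast", "estimate", "p_raw", "p_bonferroni")])
  invisible(x)
}

icc_band <- function(icc) {
  if (!is.finite(icc)) return(NA_character_)
  if (icc < 0.50) "poor" else if (icc < 0.75) "moderate"
  else if (icc <= 0.90) "good" else "excellent"
}

#' Intergrader agreement: two-way absolute-agreement ICC
#'
#' Single-rater, two-way random-effects, absolute-agreement intraclass
#' correlation (McGraw-Wong ICC(A,1)) between two graders' paired
#' measurements, with the standard F-distribution 95% confidence bounds and
#' the interpretation band (poor < 0.50 <= moderate < 0.75 <= good <= 0.90 <
#' excellent). The consistency form ICC(C,1) is reported alongside.
#'
#' @param grader1,grader2 equal-length numeric vectors (n >= 5).
#' @param conf confidence level (default 0.95).
#' @return An `icc_result` list: `icc`, `ci95`, `band`, `icc_consistency`, and
#'   the ANOVA mean squares. Zero total variance flags the ICC as undefined.
#' @export
icc_agreement <- function(grader1, grader2, conf = 0.95) {
  if (length(grader1) != length(grader2)) stopf("graders must have equal length")
  ok <- is.finite(grader1) & is.finite(grader2)
  x <- cbind(grader1[ok], grader2[ok])
  n <- nrow(x); k <- 2
  if (n < 5) stopf("need at least 5 paired measurements")
  grand <- mean(x)
  ss_total <- sum((x - grand)^2)
  if (ss_total < 1e-12)
    return(structure(list(icc = NA_real_, ci95 = c(NA_real_, NA_real_),
                          band = NA_character_, icc_consistency = NA_real_,
                          note = "zero total variance: ICC undefined"),
                     class = "icc_result"))
  rowm <- rowMeans(x); colm <- colMeans(x)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- ss_total - k * sum((rowm - grand)^2) - n * sum((colm - grand)^2)
  mse <- max(sse / ((n - 1) * (k - 1)), 0)
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  icc_c <- (msr - mse) / (msr + (k - 1) * mse)
  alpha <- 1 - conf
  if (mse < 1e-12 && msc < 1e-12) {
    ci <- c(1, 1)
  } else {
    a <- k * icc / (n * (1 - icc)); b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(max(-1, lower), min(1, upper))
  }
  structure(list(icc = icc, ci95 = ci, band = icc_band(icc),
                 icc_consistency = icc_c,
                 ms = c(msr = msr, msc = msc, mse = mse), n = n),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (is.na(x$icc)) cat("<icc_result> undefined:", x$note, "\n")
  else cat(sprintf("<icc_result> ICC(A,1) = %.3f [%.3f, %.3f] (%s)\n",
                   x$icc, x$ci95[1], x$ci95[2], x$band))
  invisible(x)
}

#' Pearson correlations between mean biomarkers
#'
#' @param table a cohort data frame (schema of [generate_cohort()]).
#' @param pairs 2-column character matrix (or list of length-2 vectors) of
#'   biomarker column pairs; defaults to all pairs of the four biomarkers
#'   present.
#' @param sector sector row to correlate (default `"mean"`).
#' @param by_group also report per-group correlations.
#' @return Data frame `var1, var2, group, n, r, p`; a zero-variance variable
#'   yields `NA` with a flag column `defined = FALSE`.
#' @export
pearson_matrix <- function(table, pairs = NULL, sector = "mean", by_group = FALSE) {
  df <- table[table$sector == sector, , drop = FALSE]
  bms <- intersect(c("mchvd_um", "ivd_um", "cth_um", "cvi_pct"), names(df))
  if (is.null(pairs)) pairs <- t(utils::combn(bms, 2))
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  one <- function(sub, gname) {
    out <- lapply(seq_len(nrow(pairs)), function(i) {
      xy <- sub[, c(pairs[i, 1], pairs[i, 2])]
      xy <- xy[complete.cases(xy), , drop = FALSE]
      n <- nrow(xy)
      if (n < 3 || var(xy[[1]]) < 1e-12 || var(xy[[2]]) < 1e-12)
        return(data.frame(var1 = pairs[i, 1], var2 = pairs[i, 2], group = gname,
                          n = n, r = NA_real_, p = NA_real_, defined = FALSE))
      ct <- cor.test(xy[[1]], xy[[2]])
      data.frame(var1 = pairs[i, 1], var2 = pairs[i, 2], group = gname, n = n,
                 r = unname(ct$estimate), p = ct$p.value, defined = TRUE)
    })
    do.call(rbind, out)
  }
  res <- one(df, "all")
  if (by_group)
    for (g in unique(df$group)) res <- rbind(res, one(df[df$group == g, ], g))
  rownames(res) <- NULL
  res
}

#' Fisher exact test for categorical variables
#'
#' Exact p-value via the hypergeometric distribution for 2 x 2 tables and the
#' exact network algorithm for larger tables (both through
#' [stats::fisher.test()]); the method used is recorded.
#'
#' @param counts nonnegative integer contingency matrix.
#' @return `list(p, method, table)`.
#' @export
fisher_categorical <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stopf("contingency table has an empty row or column")
  ft <- fisher.test(counts)
  method <- if (all(dim(counts) == 2)) "exact hypergeometric (2x2)"
            else "exact network (r x c)"
  list(p = ft$p.value, method = method, table = counts)
}
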