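# Cohort statistics: LMM, ICC, Pearson, Fisher.

test_that("identical constant groups give zero effect and omnibus p of 1", {
  co <- data.frame(subject_id = sprintf("s%02d", 1:30),
                   eye = sprintf("e%02d", 1:30),
                   group = rep(c("a", "b", "c"), each = 10),
                   sector = "mean", mchvd_um = 250)
  fit <- fit_group_lmm(co, "mchvd_um")
  expect_equal(fit$omnibus_p, 1)
  expect_true(all(fit$pairwise$p_bonferroni == 1))
  expect_equal(unname(fit$estimates), rep(250, 3))
})

test_that("the mixed model detects the published group separation", {
  co <- generate_cohort(cohort_spec(seed = 21L))
  fit <- fit_group_lmm(co, "mchvd_um")
  expect_equal(fit$method, "lmm")
  expect_lt(fit$omnibus_p, 0.001)
  expect_equal(fit$pairwise$p_bonferroni,
               pmin(1, fit$pairwise$p_raw * 3))
  ord <- order(fit$pairwise$p_raw)   # adjustment preserves the ordering
  expect_true(all(diff(fit$pairwise$p_bonferroni[ord]) >= -1e-12))
  expect_true(all(fit$pairwise$p_bonferroni <= 1))
  expect_s3_class(fit$shapiro, "data.frame")
  expect_true(all(fit$shapiro$W <= 1, na.rm = TRUE))
})

test_that("without paired eyes the model falls back to subject = eye", {
  co <- generate_cohort(cohort_spec(paired_groups = NULL, seed = 22L))
  fit <- fit_group_lmm(co, "cth_um")
  expect_equal(fit$method, "lm")
  expect_match(fit$note, "subject = eye")
  expect_lt(fit$omnibus_p, 0.05)
})

test_that("ICC(A,1) matches the ANOVA oracle and behaves under offsets", {
  set.seed(31)
  g1 <- rnorm(40, 100, 15)

  # duplicated graders
  r <- icc_agreement(g1, g1)
  expect_equal(r$icc, 1)
  expect_equal(r$ci95, c(1, 1))
  expect_equal(r$band, "excellent")

  # worked 6-row table against the independent mean-squares oracle
  a <- c(10, 12, 14, 20, 22, 30)
  b <- c(11, 14, 13, 22, 21, 33)
  r6 <- icc_agreement(a, b)
  expect_equal(r6$icc, icc_a1_oracle(a, b), tolerance = 1e-10)
  expect_true(r6$ci95[1] <= r6$icc && r6$icc <= r6$ci95[2])

  # constant offset: absolute agreement < consistency
  g2 <- g1 + 30
  ro <- icc_agreement(g1, g2)
  expect_lt(ro$icc, ro$icc_consistency)
  expect_equal(ro$icc, icc_a1_oracle(g1, g2), tolerance = 1e-10)

  # noise ladder: ICC decreases as independent noise grows
  iccs <- vapply(c(1, 5, 15, 40), function(s) {
    set.seed(32)
    icc_agreement(g1, g1 + rnorm(40, 0, s))$icc
  }, numeric(1))
  expect_true(all(diff(iccs) < 0))

  # degenerate input
  z <- icc_agreement(rep(5, 10), rep(5, 10))
  expect_true(is.na(z$icc))
  expect_error(icc_agreement(1:3, 1:3), "at least 5")
  expect_error(icc_agreement(1:10, 1:9), "equal length")
})

test_that("Pearson correlations: exact lines, orthogonal pairs, flags", {
  x <- seq(1, 20)
  set.seed(51)
  ortho <- unname(resid(lm(rnorm(20) ~ x)))   # exactly orthogonal to x
  co <- data.frame(subject_id = sprintf("s%02d", x), eye = sprintf("e%02d", x),
                   group = "g", sector = "mean",
                   mchvd_um = 2 * x + 1, cth_um = x,
                   ivd_um = ortho, cvi_pct = 40)
  pm <- pearson_matrix(co, pairs = rbind(c("mchvd_um", "cth_um"),
                                         c("ivd_um", "cth_um"),
                                         c("cvi_pct", "cth_um")))
  expect_equal(pm$r[1], 1)
  expect_lt(abs(pm$r[2]), 1e-8)
  expect_false(pm$defined[3])   # zero variance flagged, not fabricated
})

test_that("the generator's latent CTh-MChVD coupling is recovered", {
  params <- reference_biomarker_params()
  sp <- cohort_spec(params = params,
                    n_eyes = c(cCSC = 5000L, fellow = 2L, healthy = 2L),
                    paired_groups = NULL, biomarker_corr = 0.55, seed = 41L)
  co <- generate_cohort(sp)
  pm <- pearson_matrix(co[co$group == "cCSC", ],
                       pairs = rbind(c("cth_um", "mchvd_um")))
  expect_lt(abs(pm$r[1] - 0.55), 0.03)
  expect_lt(pm$p[1], 0.001)
})

test_that("Fisher exact tests match the enumeration oracles", {
  expect_equal(fisher_categorical(matrix(c(5, 5, 5, 5), 2))$p, 1)
  p0 <- fisher_categorical(matrix(c(0, 10, 10, 0), 2))$p
  expect_equal(p0, 2 / choose(20, 10), tolerance = 1e-9)

  f23 <- matrix(c(2, 3, 4, 1, 5, 2), nrow = 2, byrow = TRUE)
  got <- fisher_categorical(f23)
  expect_equal(got$method, "exact network (r x c)")
  expect_equal(got$p, fisher_oracle_2xc(f23), tolerance = 1e-7)

  # the pseudophakia-style table from the demographic comparison
  demo <- matrix(c(2, 28, 3, 19, 4, 22), nrow = 2)
  expect_equal(fisher_categorical(demo)$p, fisher_oracle_2xc(demo),
               tolerance = 1e-7)

  expect_error(fisher_categorical(matrix(c(0, 0, 3, 4), 2)), "empty")
  expect_error(fisher_categorical(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("two seeded automated graders agree with ICC above 0.9", {
  spec <- sector_phantom_spec(seed = 3L)
  ph <- generate_phantom(spec)
  vasc <- label_vasculature(truth_mask(ph))
  cl <- extract_centerlines(vasc)
  grid <- build_sector_grid(ph$volume)
  b1 <- sector_and_global_metrics(vasc, cl, grid, seed = 101L)
  b2 <- sector_and_global_metrics(vasc, cl, grid, seed = 202L)
  m1 <- aggregate(diameter_um ~ sector + vessel_rank, b1$measurements, mean)
  m2 <- aggregate(diameter_um ~ sector + vessel_rank, b2$measurements, mean)
  key <- paste(m1$sector, m1$vessel_rank)
  m2 <- m2[match(key, paste(m2$sector, m2$vessel_rank)), ]
  r <- icc_agreement(m1$diameter_um, m2$diameter_um)
  expect_gt(r$icc, 0.9)
})
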