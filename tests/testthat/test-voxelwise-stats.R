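test_that("the mass-univariate engine matches per-voxel lmer fits", {
  skip_if_not_installed("lmerTest")
  set.seed(42)
  meta <- make_meta(24)
  meta <- meta[-sample(nrow(meta), 8), ] # attrition-like imbalance
  n <- nrow(meta)
  subj_eff <- rnorm(24, 0, 0.5)
  names(subj_eff) <- sprintf("s%02d", 1:24)
  Y <- t(vapply(1:4, function(v) {
    0.2 + 0.001 * meta$dpi * (meta$group == "PFF") +
      subj_eff[meta$subject_id] + rnorm(n, 0, 0.3)
  }, numeric(n)))
  fit <- fit_voxelwise_lme(Y, meta)
  for (v in 1:4) {
    lf <- lmerTest::lmer(
      y ~ group * sex * dpi + (1 | subject_id),
      data = dplyr::mutate(meta, y = Y[v, ],
                           group = factor(group, c("PBS", "PFF")),
                           sex = factor(sex, c("F", "M"))),
      REML = TRUE
    )
    sm <- summary(lf)$coefficients
    mine <- dplyr::filter(fit$table, voxel == v)
    expect_equal(mine$estimate, unname(sm[mine$term, "Estimate"]), tolerance = 5e-3)
    expect_equal(mine$std.error, unname(sm[mine$term, "Std. Error"]), tolerance = 2e-2)
    expect_equal(mine$statistic, unname(sm[mine$term, "t value"]), tolerance = 3e-2)
    # within-subject terms: between-within df agree with Satterthwaite
    within <- grepl("dpi", mine$term)
    expect_equal(mine$df[within], unname(sm[mine$term[within], "df"]),
                 tolerance = 0.05)
  }
})

test_that("degenerate designs are rejected with informative errors", {
  meta <- make_meta(8)
  Y <- matrix(rnorm(nrow(meta) * 3), 3)
  # aliased covariate: group duplicated as a numeric copy
  meta_bad <- dplyr::mutate(meta, gdup = as.numeric(group == "PFF"))
  err <- expect_error(fit_voxelwise_lme(Y, meta_bad, ~ group * sex + gdup),
                      class = "dbmcov_lme_error")
  expect_match(conditionMessage(err), "gdup")
  # one observation per subject: random intercept inestimable
  meta1 <- meta[!duplicated(meta$subject_id), ]
  expect_error(fit_voxelwise_lme(Y[, seq_len(nrow(meta1))], meta1),
               class = "dbmcov_lme_error")
  expect_error(fit_voxelwise_lme(Y, meta[1:5, ]), class = "dbmcov_lme_error")
})

test_that("flagged voxels are reported, not dropped", {
  meta <- make_meta(8)
  Y <- rbind(rnorm(nrow(meta)), 0) # second voxel constant -> degenerate
  expect_message(fit <- fit_voxelwise_lme(Y, meta), class = "dbmcov_lme_failed")
  expect_equal(fit$n_failed, 1L)
  expect_true(all(is.na(dplyr::filter(fit$table, voxel == 2)$p.value)))
  mp <- fdr_map(fit, "groupPFF:dpi")
  expect_equal(attr(mp, "term"), "groupPFF:dpi")
  expect_false(mp$significant[2])
})

test_that("BH correction matches hand computation and brute force", {
  one <- fdr_correct(0.001)
  expect_equal(one$q, 0.001)
  # hand BH: thresholds i*q/m = 0.0167, 0.0333, 0.05
  hand <- fdr_correct(c(0.01, 0.02, 0.5), q_level = 0.05)
  expect_equal(hand$significant, c(TRUE, TRUE, FALSE))
  expect_equal(hand$q, c(0.03, 0.03, 0.5))
  expect_true(all(!fdr_correct(rep(1, 10), 0.05)$significant))
  expect_error(fdr_correct(numeric(0)), class = "dbmcov_fdr_error")
  expect_error(fdr_correct(c(0.5, 0)), class = "dbmcov_fdr_error")
  expect_error(fdr_correct(1.2), class = "dbmcov_fdr_error")

  # brute-force step-up enumeration oracle on a grid, all lengths <= 8
  grid <- c(0.001, 0.005, 0.01, 0.02, 0.04, 0.049, 0.05, 0.2, 0.5, 1)
  set.seed(18)
  for (m in 1:8) {
    for (rep in 1:40) {
      p <- sample(grid, m, replace = TRUE)
      for (q in c(0.01, 0.05, 0.1)) {
        expect_identical(fdr_correct(p, q)$significant, bh_bruteforce(p, q))
      }
    }
  }
  expect_identical(fdr_correct(grid, 0.05)$significant, bh_bruteforce(grid, 0.05))
})

test_that("q-values never undercut their p-values and are monotone", {
  set.seed(19)
  p <- runif(50)^2
  out <- fdr_correct(p, 0.05)
  expect_true(all(out$q >= p - 1e-15))
  o <- order(p)
  expect_true(all(diff(out$q[o]) >= -1e-15))
})

test_that("Cohen's d follows its tagged pooling formula and sign convention", {
  expect_equal(as.numeric(cohens_d(c(1, 2, 3), c(1, 2, 3))), 0)
  # means 1 vs 0, both groups unit sample SD -> d = 1
  a <- c(0, 1, 2); b <- c(-1, 0, 1)
  expect_equal(as.numeric(cohens_d(a, b)), 1)
  # hand pooled-SD computation: means 1 vs 2, pooled s^2 = (2 + 2)/2 = 2
  expect_equal(as.numeric(cohens_d(c(0, 2), c(1, 3))), -1 / sqrt(2))
  # population variant: s^2 = (2 + 2)/4 = 1 -> d = -1
  expect_equal(as.numeric(cohens_d(c(0, 2), c(1, 3), variant = "population")), -1)
  expect_equal(attr(cohens_d(a, b), "variant"), "pooled")
  expect_error(cohens_d(c(1, 1), c(2, 2)), class = "dbmcov_effect_error")
  expect_error(cohens_d(1, c(1, 2)), class = "dbmcov_effect_error")
})

test_that("subject-weight GLMs detect planted contrasts", {
  set.seed(20)
  n <- 40
  meta <- tibble::tibble(group = rep(c("PBS", "PFF"), n / 2),
                         sex = rep(c("F", "F", "M", "M"), n / 4))
  # planted: females shifted by 2 SD
  w <- rnorm(n, sd = 1) + 2 * (meta$sex == "F")
  H <- rbind(w, rnorm(n))
  g <- subject_weight_glm(H, 1, meta)
  sex_p <- g$coefficients$p.value[g$coefficients$term == "sexM"]
  expect_lt(sex_p, 0.01)
  d_sex <- g$cohens_d$d[g$cohens_d$contrast == "sex_M_minus_F"]
  expect_equal(d_sex, -2, tolerance = 0.4)

  # identical weights: all effects zero, p ~ 1
  H0 <- rbind(rep(0.7, n), rnorm(n))
  g0 <- subject_weight_glm(H0, 1, meta)
  non_int <- g0$coefficients[g0$coefficients$term != "(Intercept)", ]
  expect_true(all(non_int$estimate == 0))
  expect_true(all(non_int$p.value == 1))

  # empty cell: interaction dropped with a warning
  meta2 <- meta
  meta2$sex[meta2$group == "PFF"] <- "F"
  expect_warning(g2 <- subject_weight_glm(H, 1, meta2),
                 class = "dbmcov_empty_cell")
  expect_false(any(grepl(":", g2$coefficients$term)))
  expect_error(subject_weight_glm(H, 5, meta), class = "dbmcov_glm_error")
})

test_that("interaction p-values are calibrated under a group-only effect", {
  set.seed(21)
  n <- 40
  meta <- tibble::tibble(group = rep(c("PBS", "PFF"), n / 2),
                         sex = rep(c("F", "F", "M", "M"), n / 4))
  ps <- replicate(150, {
    w <- rnorm(n) + 1.5 * (meta$group == "PFF") # no interaction
    g <- subject_weight_glm(rbind(w), 1, meta)
    g$coefficients$p.value[g$coefficients$term == "groupPFF:sexM"]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("planted voxel effects are recovered with controlled error", {
  # high-SNR blob: sensitivity inside, specificity outside at 1% FDR
  spec <- cohort_spec(n_per_cell = 10, grid_shape = c(14, 14, 14), seed = 23)
  comps <- generate_components(spec, k0 = 1)
  lmld <- default_loadings_model(1)
  lmld[] <- 0
  lmld[1, "group_dpi"] <- 0.02
  truth <- ground_truth(comps, loadings_model = lmld, noise_sd = 0.05,
                        hazard_model = c(baseline = 1e-9, group = 0, sex = 0,
                                         group_sex = 0))
  cohort <- generate_cohort(spec, truth)
  imgs <- generate_jacobians(cohort, truth, spec)
  dm <- assemble_matrix(imgs, comps$mask, zscore = FALSE)
  meta <- dplyr::left_join(dm$column_meta,
                           dplyr::distinct(cohort, subject_id, sex, group),
                           by = "subject_id")
  fit <- fit_voxelwise_lme(dm, meta)
  mp <- fdr_map(fit, "groupPFF:dpi", q_level = 0.01)
  inside <- dm$voxel_index %in% which(comps$fields[[1]] > 0.2)
  outside <- dm$voxel_index %in% which(comps$fields[[1]] == 0)
  expect_gt(mean(mp$significant[inside]), 0.8)
  expect_lt(mean(mp$significant[outside]), 0.01)
})
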