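hand_trials <- function() {
  tibble::tibble(
    subject_id = sprintf("m%02d", 1:6),
    sex = rep(c("F", "M"), 3),
    group = rep(c("PBS", "PFF"), each = 3),
    task = rep(c("wirehang", "pole"), each = 3),
    dpi = 90,
    trial = rep(1:3, 2),
    latency_s = c(150, 42.5, 150, 120, 11, 30),
    outcome = c("success", "failure", "success", "failure", "success", "success"),
    weight_g = c(24, 25, 30, 31, 23, 29)
  )
}

test_that("task encoding reproduces hand-coded event and censor flags", {
  tr <- hand_trials()
  wh <- encode_task(tr, "wirehang")
  # wire hang: fall = event; reaching the 150 s cap = censored success
  expect_equal(wh$event, c(0L, 1L, 0L))
  expect_equal(wh$time, c(150, 42.5, 150))
  po <- encode_task(tr, "pole")
  # pole: successful descent = event; 120 s failure = censored
  expect_equal(po$event, c(0L, 1L, 1L))
  expect_equal(po$time, c(120, 11, 30))
  # conservation: events + censored = records, per task
  for (enc in list(wh, po)) {
    expect_equal(sum(enc$event) + sum(enc$event == 0), nrow(enc))
  }
  expect_true(all(c("trial", "weight_g") %in% names(wh)))
  # cap violations are generator contract violations
  bad <- tr
  bad$latency_s[5] <- 130
  expect_error(encode_task(bad, "pole"), class = "dbmcov_encode_error")
  expect_error(encode_task(tr[0, ], "pole"), class = "dbmcov_encode_error")
})

test_that("an all-censored task cannot be modeled", {
  tr <- hand_trials()
  tr <- tr[tr$task == "wirehang", ]
  tr$latency_s <- 150
  tr$outcome <- "success"
  rec <- encode_task(tr, "wirehang")
  expect_equal(sum(rec$event), 0)
  expect_error(fit_cox(rec, survival::Surv(time, event) ~ group),
               class = "dbmcov_cox_error")
})

test_that("a toy Cox fit matches the hand-evaluated partial likelihood", {
  rec <- tibble::tibble(
    time = c(1, 2, 3, 4),
    event = c(1L, 1L, 0L, 1L),
    x = c(1, 0, 1, 0)
  )
  fit <- fit_cox(rec, survival::Surv(time, event) ~ x)
  # independent oracle: direct maximization of the partial likelihood
  # (no ties, so the risk-set products are written out explicitly)
  neg_pl <- function(b) {
    eta <- exp(b * rec$x)
    risk <- function(i) sum(eta[rec$time >= rec$time[i]])
    -sum(log(eta[rec$event == 1] /
               vapply(which(rec$event == 1), risk, numeric(1))))
  }
  opt <- optimize(neg_pl, c(-10, 10))
  expect_equal(fit$coefficients$estimate, opt$minimum, tolerance = 1e-4)
  expect_equal(fit$coefficients$hazard_ratio,
               exp(fit$coefficients$estimate))
})

test_that("a planted hazard ratio of 2 is recovered from capped latencies", {
  st <- tiny_study(seed = 29, n_per_cell = 50, grid = 14, k0 = 1)
  bm <- default_behavior_model()
  bm$wirehang <- list(family = "exponential", rate = 1 / 200,
                      loghr_group = log(2), cap = 150)
  truth <- ground_truth(st$truth$components, behavior_model = bm)
  beh <- generate_behavior(dplyr::filter(st$cohort, dpi == 90), truth,
                           seed = 6, tasks = "wirehang")
  rec <- encode_task(beh, "wirehang")
  fit <- fit_cox(rec, survival::Surv(time, event) ~ group)
  expect_lt(abs(fit$coefficients$estimate[1] - log(2)), 0.25)
})

test_that("Cox p-values are uniform when the covariate is independent", {
  set.seed(30)
  ps <- replicate(120, {
    n <- 60
    rec <- tibble::tibble(time = rexp(n, 1 / 100),
                          event = rbinom(n, 1, 0.8),
                          x = rbinom(n, 1, 0.5))
    rec$time <- pmin(rec$time, 250)
    fit <- fit_cox(rec, survival::Surv(time, event) ~ x)
    fit$coefficients$p.value[1]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("survival analysis detects planted sex-specific hazard and exports KM curves", {
  spec <- cohort_spec(n_per_cell = 100, grid_shape = c(14, 14, 14), seed = 33)
  comps <- generate_components(spec, k0 = 1)
  truth <- ground_truth(comps, hazard_model = c(baseline = 1e-3, group = 0.3,
                                                sex = 0, group_sex = 2.2))
  cohort <- generate_cohort(spec, truth)
  sa <- fit_survival(cohort)
  co <- sa$cox$coefficients
  inter <- co[co$term == "groupPFF:sexM", ]
  expect_gt(inter$estimate, 0)
  expect_lt(inter$p.value, 0.05)
  km <- sa$km
  expect_true(all(km$surv >= 0 & km$surv <= 1))
  for (cell in split(km, paste(km$group, km$sex))) {
    expect_true(all(diff(cell$surv[order(cell$time)]) <= 1e-12))
  }
  # no events at all -> error
  none <- dplyr::mutate(cohort, event_flag = 0L)
  expect_error(fit_survival(none), class = "dbmcov_cox_error")
})

test_that("longitudinal mixed models recover planted weight trajectories", {
  spec <- cohort_spec(n_per_cell = 20, grid_shape = c(14, 14, 14), seed = 35)
  comps <- generate_components(spec, k0 = 1)
  wm <- c(base_female = 24, base_male = 30, growth_per_day = 0.015,
          pff_bump = 1.2, subject_sd = 1.5, resid_sd = 0.4)
  truth <- ground_truth(comps, weight_model = wm,
                        hazard_model = c(baseline = 1e-9, group = 0, sex = 0,
                                         group_sex = 0))
  cohort <- generate_cohort(spec, truth)
  tab <- fit_longitudinal_lme(cohort, "weight", dpi_coding = "quadratic")
  q <- tab[tab$term == "groupPFF:dpi2", ]
  # inverted-U excursion in PFF mice: negative curvature interaction
  expect_lt(q$estimate, 0)
  expect_lt(q$p.value, 0.05)

  # flat null: behavior latencies without group effects
  bm0 <- default_behavior_model()
  bm0$rotarod$shift_group_dpi <- 0
  truth0 <- ground_truth(comps, behavior_model = bm0,
                         hazard_model = c(baseline = 1e-9, group = 0, sex = 0,
                                          group_sex = 0))
  beh0 <- generate_behavior(cohort, truth0, seed = 8)
  rtab <- fit_longitudinal_lme(beh0, "rotarod")
  g <- rtab[rtab$term == "groupPFF:dpi", ]
  expect_gt(g$p.value, 0.01)

  one <- dplyr::filter(cohort, subject_id == cohort$subject_id[1])
  expect_error(fit_longitudinal_lme(one, "weight"), class = "dbmcov_lme_error")
})

test_that("motor-onset GLM estimates a planted sex shift", {
  spec <- cohort_spec(n_per_cell = 60, grid_shape = c(14, 14, 14), seed = 37)
  comps <- generate_components(spec, k0 = 1)
  truth <- ground_truth(comps, onset_model = c(mean = 80, sd = 6, male_shift = 10),
                        hazard_model = c(baseline = 1e-9, group = 0, sex = 0,
                                         group_sex = 0))
  cohort <- generate_cohort(spec, truth)
  g <- suppressWarnings(motor_onset_glm(cohort))
  sexeff <- g$coefficients[g$coefficients$term == "sexM", ]
  expect_equal(sexeff$estimate, 10, tolerance = 3 * sexeff$std.error / 10 + 0.15)

  # identical onsets: zero effects
  c0 <- dplyr::mutate(cohort,
                      motor_onset_dpi = ifelse(is.na(motor_onset_dpi), NA, 50))
  g0 <- suppressWarnings(motor_onset_glm(c0))
  expect_true(all(abs(g0$coefficients$estimate[g0$coefficients$term != "(Intercept)"]) < 1e-10))

  # no symptomatic mice -> error
  expect_error(motor_onset_glm(dplyr::mutate(cohort, motor_onset_dpi = NA_real_)),
               class = "dbmcov_onset_error")
})

test_that("Bonferroni uses strict inequality and brute-force adjustment", {
  out <- bonferroni(0.001, m = 8)
  expect_true(out$significant)
  expect_equal(out$p_adjusted, 0.008)
  # boundary: p = alpha/m is NOT significant under strict <
  expect_false(bonferroni(0.05, m = 1)$significant)
  expect_equal(bonferroni(1, m = 8)$p_adjusted, 1)
  expect_error(bonferroni(0.01, m = 0), class = "dbmcov_bonferroni_error")
  set.seed(38)
  p <- runif(30)
  expect_equal(bonferroni(p, m = 8)$p_adjusted, pmin(1, 8 * p))
  expect_equal(bonferroni(p, m = 8)$significant, p < 0.05 / 8)
})
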