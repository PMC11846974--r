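test_that("cohort specifications are validated", {
  expect_error(cohort_spec(n_per_cell = 1), class = "dbmcov_spec_error")
  expect_error(cohort_spec(timepoints_dpi = c(30, 30, 90)), class = "dbmcov_spec_error")
  expect_error(cohort_spec(grid_shape = c(4, 16, 16)), class = "dbmcov_spec_error")
  expect_error(cohort_spec(end_dpi = 100), class = "dbmcov_spec_error")
  expect_s3_class(cohort_spec(), "cohort_spec")
})

test_that("planted components are smooth, in-mask, reproducible and disjoint", {
  spec <- cohort_spec(grid_shape = c(16, 16, 16), seed = 3)
  one <- generate_components(spec, k0 = 1)
  frac <- mean(one$fields[[1]] > 0)
  expect_gt(frac, 0)
  expect_lt(frac, 0.5)
  expect_true(all(one$fields[[1]] >= 0))
  expect_true(all(one$fields[[1]][!one$mask] == 0))

  spec4 <- cohort_spec(grid_shape = c(24, 24, 24), seed = 5)
  a <- generate_components(spec4, k0 = 4, seed = 99)
  b <- generate_components(spec4, k0 = 4, seed = 99)
  expect_identical(a$fields, b$fields)

  supports <- lapply(a$fields, function(f) which(f > 0))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_length(intersect(supports[[i]], supports[[j]]), 0)
    }
  }
})

test_that("impossible placements raise a placement error", {
  spec <- cohort_spec(grid_shape = c(8, 8, 8), seed = 1)
  expect_error(generate_components(spec, k0 = 30, max_tries = 50),
               class = "dbmcov_placement_error")
})

test_that("cohort size, balance and attrition follow the design", {
  st <- tiny_study(n_per_cell = 2, grid = 16)
  subj <- dplyr::distinct(st$cohort, subject_id, sex, group)
  expect_equal(nrow(subj), 8)
  expect_true(all(table(subj$sex, subj$group) == 2))
  expect_true(all(st$cohort$dpi <= st$cohort$survival_dpi))
  expect_true(all(st$cohort$survival_dpi <= st$spec$end_dpi))
  on <- st$cohort$motor_onset_dpi
  expect_true(all(is.na(on) | on <= st$cohort$survival_dpi))
  # determinism
  again <- generate_cohort(st$spec, st$truth)
  expect_identical(st$cohort, again)
})

test_that("zero hazard coefficients give the exponential baseline event rate", {
  spec <- cohort_spec(n_per_cell = 100, grid_shape = c(16, 16, 16), seed = 21)
  comps <- generate_components(spec, k0 = 1)
  base <- 5e-3
  truth <- ground_truth(comps, hazard_model = c(baseline = base, group = 0,
                                                sex = 0, group_sex = 0))
  subj <- dplyr::distinct(generate_cohort(spec, truth),
                          subject_id, group, sex, survival_dpi, event_flag)
  # closed form: P(event before end) = 1 - exp(-rate * end)
  p_event <- 1 - exp(-base * spec$end_dpi)
  expect_equal(mean(subj$event_flag), p_event,
               tolerance = 3 * sqrt(p_event * (1 - p_event) / nrow(subj)) / p_event)
  expect_true(all(subj$survival_dpi[subj$event_flag == 0] == spec$end_dpi))
})

test_that("a strong male-PFF hazard shortens male-PFF survival", {
  spec <- cohort_spec(n_per_cell = 100, grid_shape = c(16, 16, 16), seed = 22)
  comps <- generate_components(spec, k0 = 1)
  truth <- ground_truth(comps, hazard_model = c(baseline = 1e-3, group = 0.5,
                                                sex = 0, group_sex = 2.5))
  subj <- dplyr::distinct(generate_cohort(spec, truth),
                          subject_id, group, sex, survival_dpi)
  pff <- subj[subj$group == "PFF", ]
  expect_lt(median(pff$survival_dpi[pff$sex == "M"]),
            median(pff$survival_dpi[pff$sex == "F"]))
})

test_that("jacobian synthesis obeys the planted construction", {
  st <- tiny_study(k0 = 1)
  spec <- st$spec
  # null case: zero noise, zero loadings -> identically zero volumes
  lm0 <- st$truth$loadings_model
  lm0[] <- 0
  truth0 <- ground_truth(st$truth$components, loadings_model = lm0, noise_sd = 0)
  imgs0 <- generate_jacobians(st$cohort, truth0, spec)
  expect_true(all(vapply(imgs0, function(im) all(im$data == 0), logical(1))))

  # construction: loading exactly 1 for PFF at any dpi -> volume = -component
  lm1 <- lm0
  lm1[1, "group"] <- 1
  truth1 <- ground_truth(st$truth$components, loadings_model = lm1, noise_sd = 0)
  imgs1 <- generate_jacobians(st$cohort, truth1, spec)
  pff_scan <- which(st$cohort$group == "PFF")[1]
  pbs_scan <- which(st$cohort$group == "PBS")[1]
  expect_equal(imgs1[[pff_scan]]$data, -truth1$components$fields[[1]])
  expect_true(all(imgs1[[pbs_scan]]$data == 0))

  # absolute flavor differs from relative by a per-subject constant
  abs1 <- generate_jacobians(st$cohort, truth1, spec, flavor = "absolute",
                             seed = 77)
  diffs <- abs1[[pff_scan]]$data - imgs1[[pff_scan]]$data
  expect_lt(diff(range(diffs)), 1e-12)

  # scans after survival are a contract violation
  bad <- st$cohort
  bad$survival_dpi[1] <- bad$dpi[1] - 1
  expect_error(generate_jacobians(bad, truth1, spec),
               class = "dbmcov_attrition_error")
})

test_that("planted group-by-dpi voxel slopes are recovered by OLS", {
  spec <- cohort_spec(n_per_cell = 10, grid_shape = c(16, 16, 16), seed = 31)
  comps <- generate_components(spec, k0 = 1)
  lm0 <- default_loadings_model(1)
  lm0[] <- 0
  lm0[1, "group_dpi"] <- 0.02
  truth <- ground_truth(comps, loadings_model = lm0, noise_sd = 0.05,
                        hazard_model = c(baseline = 1e-9, group = 0, sex = 0,
                                         group_sex = 0))
  cohort <- generate_cohort(spec, truth)
  imgs <- generate_jacobians(cohort, truth, spec)
  vox <- which(comps$fields[[1]] == max(comps$fields[[1]]))[1]
  y <- vapply(imgs, function(im) im$data[vox], numeric(1))
  x <- (cohort$group == "PFF") * cohort$dpi
  fit <- lm(y ~ x + cohort$dpi)
  est <- coef(summary(fit))["x", ]
  # log-Jacobian = -loading * field; at the field peak the slope is -0.02
  expect_lt(abs(est["Estimate"] - (-0.02)), 3 * est["Std. Error"])
})

test_that("behavioral trials honor task caps, scoring and attrition", {
  st <- tiny_study(seed = 13)
  beh <- generate_behavior(st$cohort, st$truth, seed = 2)
  counts <- dplyr::count(beh, subject_id, task, dpi)
  expect_true(all(counts$n == 3))
  expect_true(all(beh$latency_s[beh$task == "pole"] <= 120))
  expect_true(all(beh$latency_s[beh$task == "wirehang"] <= 150))
  wh <- beh[beh$task == "wirehang", ]
  expect_true(all(wh$outcome[wh$latency_s >= 150] == "success"))
  expect_true(all(wh$outcome[wh$latency_s < 150] == "failure"))
  # no trials beyond survival
  joined <- dplyr::left_join(beh,
                             dplyr::distinct(st$cohort, subject_id, survival_dpi),
                             by = "subject_id")
  expect_true(all(joined$dpi <= joined$survival_dpi))
  expect_identical(beh, generate_behavior(st$cohort, st$truth, seed = 2))
  expect_error(generate_behavior(st$cohort, st$truth, tasks = "beamwalk"),
               class = "dbmcov_task_error")
})

test_that("extreme task parameters drive all trials to their ceiling or floor", {
  st <- tiny_study(seed = 17)
  bm <- default_behavior_model()
  bm$wirehang$meanlog <- log(1e6)
  bm$pole$fail_base <- 50 # certain failure
  truth <- ground_truth(st$truth$components, behavior_model = bm)
  beh <- generate_behavior(st$cohort, truth, seed = 3)
  wh <- beh[beh$task == "wirehang", ]
  expect_true(all(wh$latency_s == 150 & wh$outcome == "success"))
  po <- beh[beh$task == "pole", ]
  expect_true(all(po$latency_s == 120 & po$outcome == "failure"))
})
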