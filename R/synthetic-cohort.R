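#' Specify a synthetic longitudinal cohort
#'
#' A cohort specification fixes the design of a simulated study of
#' fibril-induced neurodegeneration in transgenic mice: balanced
#' sex-by-injection-group cells, a longitudinal scanning schedule in days
#' post-injection (dpi), a voxel grid for the simulated log-Jacobian
#' volumes, and the master RNG seed from which every downstream generator
#' derives its randomness.
#'
#' @param n_per_cell Subjects per sex-by-injection-group cell (>= 2). The
#'   default of 15 gives ~30 mice per injection group at baseline.
#' @param timepoints_dpi Strictly increasing integer scan times in dpi;
#'   negative values are pre-injection baselines.
#' @param grid_shape Integer voxel counts per axis (each >= 8).
#' @param voxel_size_mm Voxel spacing in mm per axis (recycled to length 3).
#' @param end_dpi Administrative censoring time for survival (experimental
#'   endpoint), in dpi.
#' @param seed Integer master seed.
#'
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_per_cell = 4, grid_shape = c(12, 12, 12))
#' spec
#' @export
cohort_spec <- function(n_per_cell = 15,
                        timepoints_dpi = c(-7, 30, 90, 120),
                        grid_shape = c(24, 24, 24),
                        voxel_size_mm = c(0.1, 0.1, 0.1),
                        end_dpi = 130,
                        seed = 1L) {
  n_per_cell <- as.integer(n_per_cell)
  grid_shape <- as.integer(rep(grid_shape, length.out = 3))
  voxel_size_mm <- rep(as.numeric(voxel_size_mm), length.out = 3)
  if (n_per_cell < 2L) {
    stop_dbmcov("`n_per_cell` must be >= 2.", "dbmcov_spec_error")
  }
  if (length(timepoints_dpi) < 1L || any(diff(timepoints_dpi) <= 0)) {
    stop_dbmcov("`timepoints_dpi` must be strictly increasing.", "dbmcov_spec_error")
  }
  if (any(grid_shape < 8L)) {
    stop_dbmcov("All grid dimensions must be >= 8.", "dbmcov_spec_error")
  }
  if (any(voxel_size_mm <= 0)) {
    stop_dbmcov("`voxel_size_mm` must be positive.", "dbmcov_spec_error")
  }
  if (end_dpi <= max(timepoints_dpi)) {
    stop_dbmcov("`end_dpi` must exceed the last timepoint.", "dbmcov_spec_error")
  }
  structure(
    list(
      n_per_cell = n_per_cell,
      timepoints_dpi = as.numeric(timepoints_dpi),
      grid_shape = grid_shape,
      voxel_size_mm = voxel_size_mm,
      end_dpi = as.numeric(end_dpi),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat("  subjects: ", 4L * x$n_per_cell, " (", x$n_per_cell, " per sex x group cell)\n", sep = "")
  cat("  timepoints (dpi):", paste(x$timepoints_dpi, collapse = ", "), "\n")
  cat("  grid:", paste(x$grid_shape, collapse = " x "),
      " voxels of ", paste(x$voxel_size_mm, collapse = " x "), " mm\n")
  cat("  endpoint:", x$end_dpi, "dpi; seed:", x$seed, "\n")
  invisible(x)
}

#' Default brain mask for a cohort specification
#'
#' A centred ellipsoid occupying roughly a third of the grid, standing in
#' for the brain mask that delimits all voxel-wise analyses.
#'
#' @param spec A [cohort_spec()].
#' @return A logical 3-D array.
#' @export
default_mask <- function(spec) {
  d <- spec$grid_shape
  ellipsoid_mask(d, centre = (d + 1) / 2, semi_axes = 0.42 * d)
}

#' Plant smooth, spatially disjoint atrophy components
#'
#' Generates `k0` non-negative smooth 3-D fields with pairwise disjoint
#' supports inside the brain mask. Each component is a Gaussian-smoothed
#' ellipsoid indicator; disjointness mirrors the voxel-exclusivity of the
#' orthogonal factorization the downstream decomposition recovers, so
#' recovery is well-posed.
#'
#' @param spec A [cohort_spec()].
#' @param k0 Number of components (>= 1).
#' @param seed RNG seed; defaults to `spec$seed + 1`.
#' @param mask Logical 3-D array; defaults to [default_mask()].
#' @param smooth_sigma_vox SD (voxels) of the smoothing applied to each
#'   indicator blob.
#' @param max_tries Placement retries before giving up.
#'
#' @return An object of class `planted_components`: list with `fields`
#'   (list of 3-D arrays), `mask`, and `spec`.
#' @examples
#' comps <- generate_components(cohort_spec(grid_shape = c(16, 16, 16)), k0 = 2)
#' length(comps$fields)
#' @export
generate_components <- function(spec, k0, seed = spec$seed + 1L,
                                mask = default_mask(spec),
                                smooth_sigma_vox = 1, max_tries = 2000L) {
  if (k0 < 1L) stop_dbmcov("`k0` must be >= 1.", "dbmcov_spec_error")
  d <- spec$grid_shape
  with_seed(seed, {
    fields <- vector("list", k0)
    occupied <- array(FALSE, dim = d)
    placed <- 0L
    tries <- 0L
    while (placed < k0) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop_dbmcov(
          sprintf("Could not place %d disjoint components in the mask after %d tries; enlarge the grid or reduce `k0`.",
                  k0, max_tries),
          "dbmcov_placement_error"
        )
      }
      # shrink the target blob as retries accumulate so crowded masks
      # still admit a disjoint placement
      shrink <- max(0.5, 1 - tries / max_tries)
      radii <- runif(3, 0.07, 0.13) * d * shrink
      centre <- runif(3, 0.28, 0.72) * d
      blob <- ellipsoid_mask(d, centre, radii)
      smoothed <- blur_array(blob + 0, rep(smooth_sigma_vox, 3))
      smoothed[smoothed < 0.05 * max(smoothed)] <- 0
      smoothed[!mask] <- 0 # components live inside the brain mask
      support <- smoothed > 0
      # reject placements that vanish or touch an earlier component
      if (sum(support) < 8L || any(support & occupied)) next
      smoothed <- smoothed / max(smoothed)
      placed <- placed + 1L
      fields[[placed]] <- smoothed
      occupied <- occupied | support
    }
    structure(list(fields = fields, mask = mask, spec = spec),
              class = "planted_components")
  })
}

#' @export
print.planted_components <- function(x, ...) {
  fr <- vapply(x$fields, function(f) mean(f > 0), numeric(1))
  cat("<planted_components> k0 =", length(x$fields),
      "| support fractions:", paste(signif(fr, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Assemble the ground truth for a synthetic study
#'
#' Bundles the planted spatial components with the linear model that maps
#' subject covariates to per-component loadings, the voxel noise level, the
#' proportional-hazards model generating survival, and the behavioral task
#' models. The defaults emulate the effect structure of a striatal-fibril
#' injection study: atrophy loadings grow with dpi in injected (PFF) mice,
#' faster in males; male PFF mice carry excess hazard; injected mice show a
#' mid-course weight peak and worsening task latencies.
#'
#' @param components A [generate_components()] result.
#' @param loadings_model Numeric matrix, one row per component, columns
#'   `intercept`, `group`, `sex`, `dpi`, `group_dpi`, `group_sex_dpi`.
#'   Codings: `group` = 1 for PFF, `sex` = 1 for male; `dpi` in days
#'   (negative baseline allowed). Loading for subject s at time t on
#'   component c is the linear predictor with these coefficients.
#' @param noise_sd Voxel-wise Gaussian noise SD (> 0 unless `exact`).
#' @param hazard_model Named vector `baseline` (events/day), `group`,
#'   `sex`, `group_sex` (log hazard ratios) of the exponential
#'   proportional-hazards survival generator.
#' @param onset_model Named vector `mean`, `sd`, `male_shift` (days) of the
#'   motor-onset time for PFF mice.
#' @param weight_model Named vector `base_female`, `base_male` (g),
#'   `growth_per_day` (g/day), `pff_bump` (scale of the inverted-U weight
#'   excursion in PFF mice), `subject_sd`, `resid_sd` (g).
#' @param behavior_model Per-task latency models; see
#'   [default_behavior_model()].
#'
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(components,
                         loadings_model = default_loadings_model(length(components$fields)),
                         noise_sd = 0.05,
                         hazard_model = c(baseline = 1e-4, group = 1.4, sex = 0, group_sex = 1.9),
                         onset_model = c(mean = 95, sd = 10, male_shift = 0),
                         weight_model = c(base_female = 24, base_male = 30,
                                          growth_per_day = 0.015, pff_bump = 0.5,
                                          subject_sd = 1.5, resid_sd = 0.4),
                         behavior_model = default_behavior_model()) {
  stopifnot(inherits(components, "planted_components"))
  loadings_model <- as.matrix(loadings_model)
  needed <- c("intercept", "group", "sex", "dpi", "group_dpi", "group_sex_dpi")
  if (nrow(loadings_model) != length(components$fields) ||
      !all(needed %in% colnames(loadings_model))) {
    stop_dbmcov("`loadings_model` needs one row per component and columns intercept/group/sex/dpi/group_dpi/group_sex_dpi.",
                "dbmcov_spec_error")
  }
  if (noise_sd < 0) stop_dbmcov("`noise_sd` must be >= 0.", "dbmcov_spec_error")
  structure(
    list(
      components = components,
      loadings_model = loadings_model[, needed, drop = FALSE],
      noise_sd = noise_sd,
      hazard_model = hazard_model,
      onset_model = onset_model,
      weight_model = weight_model,
      behavior_model = behavior_model
    ),
    class = "ground_truth"
  )
}

#' Default per-component loading coefficients
#'
#' Component 1 carries the group-by-dpi atrophy effect with a male excess
#' (the sex-specific disease pattern); component 2 a sex-shared group-by-dpi
#' effect; remaining components carry normative structure (aging drift, sex
#' dimorphism) so the decomposition has non-disease patterns to separate.
#'
#' @param k0 Number of components.
#' @return Coefficient matrix (see [ground_truth()]).
#' @export
default_loadings_model <- function(k0) {
  m <- matrix(0, nrow = k0, ncol = 6,
              dimnames = list(NULL, c("intercept", "group", "sex", "dpi",
                                      "group_dpi", "group_sex_dpi")))
  m[, "intercept"] <- 0.15
  if (k0 >= 1) m[1, c("group_dpi", "group_sex_dpi")] <- c(0.004, 0.002)
  if (k0 >= 2) m[2, "group_dpi"] <- 0.003
  if (k0 >= 3) m[3, "dpi"] <- 0.001
  if (k0 >= 4) m[4, "sex"] <- 0.2
  m
}

#' Default behavioral task models
#'
#' Latency generators per task. `lognormal` tasks draw
#' `exp(meanlog + shift_group_dpi * PFF * max(dpi, 0) + sdlog * z)`;
#' `exponential` tasks draw a proportional-hazards exponential latency with
#' log hazard ratios (`loghr_*`), which gives the generator a well-defined
#' planted hazard ratio. Caps: a pole trial at/over 120 s is a failure
#' recorded at 120 s; a wire-hang trial at/over the cap is a success
#' recorded at the cap (default 150 s); the accelerating rotarod has no cap.
#' `fail_base`/`fail_group_dpi` give the logit of an outright pole failure
#' (inability to turn downward).
#'
#' @param wirehang_cap Wire-hang success cap in seconds.
#' @return Named list of per-task parameter lists.
#' @export
default_behavior_model <- function(wirehang_cap = 150) {
  list(
    pole = list(family = "lognormal", meanlog = log(9), sdlog = 0.35,
                shift_group_dpi = 0.006, fail_base = -4, fail_group_dpi = 0.035,
                cap = 120),
    wirehang = list(family = "lognormal", meanlog = log(170), sdlog = 0.45,
                    shift_group_dpi = -0.011, cap = wirehang_cap),
    rotarod = list(family = "lognormal", meanlog = log(60), sdlog = 0.4,
                   shift_group_dpi = -0.004, cap = Inf)
  )
}

#' Default ground truth for a specification
#'
#' @param spec A [cohort_spec()].
#' @param k0 Number of planted components.
#' @param ... Passed to [ground_truth()].
#' @return A `ground_truth` object.
#' @export
default_ground_truth <- function(spec, k0 = 4L, ...) {
  ground_truth(generate_components(spec, k0 = k0), ...)
}

#' Generate a synthetic cohort table
#'
#' Draws a balanced sex-by-injection-group cohort, exponential
#' proportional-hazards survival censored at the experimental endpoint,
#' motor-onset times for injected mice, and per-timepoint body weights, and
#' applies hazard-linked attrition: a subject contributes scans only at
#' timepoints up to its survival time.
#'
#' @param spec A [cohort_spec()].
#' @param truth A [ground_truth()] object.
#' @param seed RNG seed; defaults to `spec$seed + 2`.
#'
#' @return A tibble with one row per retained subject-timepoint scan:
#'   `subject_id`, `sex` (`F`/`M`), `group` (`PBS`/`PFF`), `dpi`,
#'   `weight_g`, and subject-level `survival_dpi`, `event_flag`
#'   (1 = humane endpoint before `end_dpi`, 0 = censored),
#'   `motor_onset_dpi` (NA when never symptomatic).
#' @examples
#' spec <- cohort_spec(n_per_cell = 2, grid_shape = c(16, 16, 16))
#' cohort <- generate_cohort(spec, default_ground_truth(spec, k0 = 1))
#' dplyr::n_distinct(cohort$subject_id)
#' @export
generate_cohort <- function(spec, truth, seed = spec$seed + 2L) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "ground_truth"))
  hz <- truth$hazard_model
  on <- truth$onset_model
  wm <- truth$weight_model
  with_seed(seed, {
    subjects <- tidyr::expand_grid(
      sex = c("F", "M"), group = c("PBS", "PFF"),
      replicate = seq_len(spec$n_per_cell)
    ) |>
      dplyr::mutate(subject_id = sprintf("sub_%s_%s_%02d", .data$sex, .data$group,
                                         .data$replicate)) |>
      dplyr::select("subject_id", "sex", "group")

    male <- as.numeric(subjects$sex == "M")
    pff <- as.numeric(subjects$group == "PFF")
    rate <- hz[["baseline"]] *
      exp(hz[["group"]] * pff + hz[["sex"]] * male + hz[["group_sex"]] * pff * male)
    t_death <- rexp(nrow(subjects), rate = rate)
    subjects$survival_dpi <- pmin(t_death, spec$end_dpi)
    subjects$event_flag <- as.integer(t_death <= spec$end_dpi)

    onset <- rnorm(nrow(subjects), mean = on[["mean"]] + on[["male_shift"]] * male,
                   sd = on[["sd"]])
    onset[onset < 1] <- 1
    onset <- ifelse(pff == 1 & onset <= subjects$survival_dpi, onset, NA_real_)
    subjects$motor_onset_dpi <- onset

    base_w <- ifelse(subjects$sex == "M", wm[["base_male"]], wm[["base_female"]]) +
      rnorm(nrow(subjects), sd = wm[["subject_sd"]])

    scans <- tidyr::expand_grid(subjects, dpi = spec$timepoints_dpi) |>
      dplyr::filter(.data$dpi <= .data$survival_dpi)
    sb <- base_w[match(scans$subject_id, subjects$subject_id)]
    pff_s <- as.numeric(scans$group == "PFF")
    # inverted-U weight excursion in PFF mice: zero at baseline, peaks
    # mid-course, returns toward zero by the endpoint
    bump <- wm[["pff_bump"]] * (scans$dpi + 7) * (spec$end_dpi + 3 - scans$dpi) / 1000
    scans$weight_g <- sb + wm[["growth_per_day"]] * (scans$dpi + 7) +
      pff_s * bump + rnorm(nrow(scans), sd = wm[["resid_sd"]])
    scans |>
      dplyr::select("subject_id", "sex", "group", "dpi", "weight_g",
                    "survival_dpi", "event_flag", "motor_onset_dpi") |>
      tibble::as_tibble()
  })
}

#' Per-scan component loadings implied by the ground truth
#'
#' @param cohort A cohort scan table (see [generate_cohort()]).
#' @param truth A [ground_truth()] object.
#' @return Matrix of loadings, one row per scan row, one column per
#'   component.
#' @export
true_loadings <- function(cohort, truth) {
  pff <- as.numeric(cohort$group == "PFF")
  male <- as.numeric(cohort$sex == "M")
  dpi <- cohort$dpi
  design <- cbind(intercept = 1, group = pff, sex = male, dpi = dpi,
                  group_dpi = pff * dpi, group_sex_dpi = pff * male * dpi)
  design %*% t(truth$loadings_model)
}

#' Generate per-scan log-Jacobian volumes
#'
#' Each retained scan receives a log-Jacobian field
#' `-sum_c loading(subject, dpi, c) * component_c + noise`; atrophy
#' (positive loading) contracts volume, hence the negative sign. The
#' `absolute` flavor additionally carries a per-subject global brain-size
#' offset; the `relative` flavor models only the focal (nonlinear) signal.
#'
#' @param cohort Cohort scan table from [generate_cohort()].
#' @param truth A [ground_truth()] object.
#' @param spec A [cohort_spec()].
#' @param flavor `"relative"` or `"absolute"`.
#' @param seed RNG seed; defaults to `spec$seed + 3` (+4 for absolute), so
#'   the two flavors share no noise.
#' @param global_size_sd SD of the per-subject global log-size offset used
#'   by the absolute flavor.
#'
#' @return Named list of [jacobian_image()] objects
#'   (`"<subject>_<dpi>"`), already on the log scale.
#' @export
generate_jacobians <- function(cohort, truth, spec,
                               flavor = c("relative", "absolute"),
                               seed = NULL, global_size_sd = 0.02) {
  flavor <- match.arg(flavor)
  stopifnot(inherits(truth, "ground_truth"), inherits(spec, "cohort_spec"))
  if (!all(cohort$dpi <= cohort$survival_dpi)) {
    stop_dbmcov("Cohort contains scans after a subject's survival time.",
                "dbmcov_attrition_error")
  }
  if (is.null(seed)) seed <- spec$seed + if (flavor == "relative") 3L else 4L
  comps <- truth$components$fields
  d <- spec$grid_shape
  load <- true_loadings(cohort, truth)
  with_seed(seed, {
    subj <- unique(cohort$subject_id)
    gsize <- setNames(rnorm(length(subj), sd = global_size_sd), subj)
    imgs <- vector("list", nrow(cohort))
    names(imgs) <- sprintf("%s_%d", cohort$subject_id, as.integer(cohort$dpi))
    for (i in seq_len(nrow(cohort))) {
      vol <- array(0, dim = d)
      for (c_i in seq_along(comps)) {
        vol <- vol - load[i, c_i] * comps[[c_i]]
      }
      if (truth$noise_sd > 0) {
        vol <- vol + array(rnorm(prod(d), sd = truth$noise_sd), dim = d)
      }
      if (flavor == "absolute") vol <- vol + gsize[[cohort$subject_id[i]]]
      imgs[[i]] <- jacobian_image(vol, voxel_size_mm = spec$voxel_size_mm,
                                  flavor = flavor,
                                  subject_id = cohort$subject_id[i],
                                  dpi = cohort$dpi[i], is_log = TRUE)
    }
    imgs
  })
}

#' Generate behavioral trial tables
#'
#' Three trials per retained subject-timepoint for each task, with latencies
#' drawn from the task models in the ground truth and scored with the task
#' cutoff semantics: a pole failure records the 120 s maximum; a wire-hang
#' latency at or beyond the cap records a success at the cap; the rotarod
#' records the fall latency with no cap.
#'
#' @param cohort Cohort scan table from [generate_cohort()].
#' @param truth A [ground_truth()] object.
#' @param seed RNG seed.
#' @param tasks Character subset of `c("pole", "wirehang", "rotarod")`.
#'
#' @return Tibble: `subject_id`, `task`, `dpi`, `trial`, `latency_s`,
#'   `outcome` (`success`/`failure`), `weight_g`, plus `sex`, `group`.
#' @export
generate_behavior <- function(cohort, truth, seed = 5L,
                              tasks = c("pole", "wirehang", "rotarod")) {
  stopifnot(inherits(truth, "ground_truth"))
  unknown <- setdiff(tasks, names(truth$behavior_model))
  if (length(unknown) > 0) {
    stop_dbmcov(paste0("Unknown task(s): ", paste(unknown, collapse = ", ")),
                "dbmcov_task_error")
  }
  with_seed(seed, {
    grid <- tidyr::expand_grid(cohort, task = tasks, trial = 1:3)
    pff <- as.numeric(grid$group == "PFF")
    male <- as.numeric(grid$sex == "M")
    dpi_pos <- pmax(grid$dpi, 0)
    lat <- numeric(nrow(grid))
    outcome <- character(nrow(grid))
    for (tk in tasks) {
      p <- truth$behavior_model[[tk]]
      idx <- which(grid$task == tk)
      if (identical(p$family, "exponential")) {
        lp <- (p$loghr_group %||% 0) * pff[idx] +
          (p$loghr_sex %||% 0) * male[idx] +
          (p$loghr_group_dpi %||% 0) * pff[idx] * dpi_pos[idx]
        draw <- rexp(length(idx), rate = p$rate * exp(lp))
      } else {
        mu <- p$meanlog + (p$shift_group_dpi %||% 0) * pff[idx] * dpi_pos[idx]
        draw <- rlnorm(length(idx), meanlog = mu, sdlog = p$sdlog)
      }
      if (tk == "pole") {
        p_fail <- plogis((p$fail_base %||% -Inf) +
                           (p$fail_group_dpi %||% 0) * pff[idx] * dpi_pos[idx])
        hard_fail <- runif(length(idx)) < p_fail
        fail <- hard_fail | draw >= p$cap
        lat[idx] <- ifelse(fail, p$cap, draw)
        outcome[idx] <- ifelse(fail, "failure", "success")
      } else if (tk == "wirehang") {
        reached <- draw >= p$cap
        lat[idx] <- ifelse(reached, p$cap, draw)
        outcome[idx] <- ifelse(reached, "success", "failure")
      } else {
        lat[idx] <- draw
        outcome[idx] <- "failure" # rotarod: latency to fall, no cap
      }
    }
    grid |>
      dplyr::mutate(latency_s = lat, outcome = outcome) |>
      dplyr::select("subject_id", "sex", "group", "task", "dpi", "trial",
                    "latency_s", "outcome", "weight_g") |>
      tibble::as_tibble()
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining component planting, cohort sampling,
#' Jacobian synthesis (both flavors) and behavioral trials under one master
#' seed.
#'
#' @param spec A [cohort_spec()].
#' @param truth A [ground_truth()]; default planted structure if missing.
#' @param flavors Jacobian flavors to synthesize.
#' @return List with `spec`, `truth`, `mask`, `cohort`, `behavior`, and one
#'   image list per flavor (`images_relative`, `images_absolute`).
#' @export
simulate_study <- function(spec, truth = default_ground_truth(spec),
                           flavors = c("relative", "absolute")) {
  cohort <- generate_cohort(spec, truth)
  out <- list(spec = spec, truth = truth, mask = truth$components$mask,
              cohort = cohort,
              behavior = generate_behavior(cohort, truth, seed = spec$seed + 5L))
  for (fl in flavors) {
    out[[paste0("images_", fl)]] <- generate_jacobians(cohort, truth, spec, flavor = fl)
  }
  out
}
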