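# End-to-end orchestration: simulate -> prep -> decompose -> overlap ->
# voxel-wise trajectories -> behavior/survival, with a machine-readable
# report.

#' Build a pipeline configuration
#'
#' All stage parameters and every RNG seed live in one list, serialized
#' verbatim next to the outputs, so a run is reproducible from its config
#' alone.
#'
#' @param out_dir Output directory.
#' @param seed Master seed (propagated to every random stage).
#' @param n_per_cell,timepoints_dpi,grid_shape,voxel_size_mm Cohort design
#'   (see [cohort_spec()]).
#' @param k0 Planted components in the synthetic study.
#' @param fwhm_mm Smoothing kernel FWHM (mm).
#' @param k_list Granularities for the stability analysis.
#' @param n_splits Split-half replicates per granularity.
#' @param q_level Voxel-wise FDR level.
#' @param analysis_dpi Timepoint of the cross-sectional decomposition.
#' @param behavior_dpis Timepoints at which the cutoff-limited tasks are
#'   modeled.
#' @param wirehang_cap Wire-hang success cap (s).
#' @param write_images Write every per-scan NIfTI volume (off by default;
#'   component/statistic maps and the mask are always written).
#' @param inputs Optional named list of paths (`mask`, `images_dir`,
#'   `cohort_csv`, `behavior_csv`) to run on existing data instead of
#'   simulating.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("dbmcov_run_"), seed = 1L,
                       n_per_cell = 8L, timepoints_dpi = c(-7, 30, 90, 120),
                       grid_shape = c(16, 16, 16), voxel_size_mm = c(0.1, 0.1, 0.1),
                       k0 = 3L, fwhm_mm = 0.17, k_list = seq(2L, 8L, 2L),
                       n_splits = 5L, q_level = 0.01, analysis_dpi = 90,
                       behavior_dpis = c(90, 120), wirehang_cap = 150,
                       write_images = FALSE, inputs = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with `run_config()` fields.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_dbmcov(paste0("No such config: ", path), "dbmcov_io_error")
  }
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_dbmcov(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)),
                "dbmcov_stage_error", parent = e)
  })
}

load_inputs <- function(cfg) {
  inp <- cfg$inputs
  for (nm in c("mask", "cohort_csv", "behavior_csv")) {
    if (is.null(inp[[nm]]) || !file.exists(inp[[nm]])) {
      stop_dbmcov(sprintf("Missing input '%s': %s", nm,
                          inp[[nm]] %||% "<unset>"), "dbmcov_io_error")
    }
  }
  mask_img <- read_nifti(inp$mask)
  cohort <- utils::read.csv(inp$cohort_csv, stringsAsFactors = FALSE) |>
    tibble::as_tibble()
  behavior <- utils::read.csv(inp$behavior_csv, stringsAsFactors = FALSE) |>
    tibble::as_tibble()
  files <- list.files(inp$images_dir, pattern = "\\.nii(\\.gz)?$",
                      full.names = TRUE)
  rel <- lapply(files[grepl("relative", files)], read_nifti, flavor = "relative")
  abs_ <- lapply(files[grepl("absolute", files)], read_nifti, flavor = "absolute")
  name_of <- function(im) sprintf("%s_%d", im$subject_id, as.integer(im$dpi))
  names(rel) <- vapply(rel, name_of, character(1))
  names(abs_) <- vapply(abs_, name_of, character(1))
  list(mask = array(mask_img$data > 0.5, dim = dim(mask_img$data)),
       cohort = cohort, behavior = behavior,
       images_relative = rel, images_absolute = abs_,
       voxel_size_mm = mask_img$voxel_size_mm)
}

#' Run the full analysis pipeline
#'
#' Executes synthesis (or input loading), preprocessing, the orthogonal
#' factorization with stability-based granularity selection (all subjects
#' and per sex), Dice overlap of the sex-specific disease patterns,
#' voxel-wise trajectory mapping with FDR, and the survival/motor
#' statistics, writing CSV/NIfTI artifacts and a JSON report to
#' `config$out_dir`. The run is deterministic under a fixed config.
#'
#' @param config A [run_config()] (or a YAML path).
#' @return The report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_plain <- lapply(unclass(cfg), function(x) x)
  yaml::write_yaml(cfg_plain, file.path(cfg$out_dir, "config.yaml"))
  # hash covers the analysis parameters, not output location or side outputs
  hashed <- cfg_plain[setdiff(names(cfg_plain), c("out_dir", "write_images"))]
  report <- list(config_hash = rlang::hash(hashed))

  if (is.null(cfg$inputs)) {
    sim <- run_stage("simulate", {
      spec <- cohort_spec(n_per_cell = cfg$n_per_cell,
                          timepoints_dpi = cfg$timepoints_dpi,
                          grid_shape = cfg$grid_shape,
                          voxel_size_mm = cfg$voxel_size_mm, seed = cfg$seed)
      truth <- ground_truth(
        generate_components(spec, k0 = cfg$k0),
        behavior_model = default_behavior_model(wirehang_cap = cfg$wirehang_cap)
      )
      simulate_study(spec, truth)
    })
    mask <- sim$mask
    cohort <- sim$cohort
    behavior <- sim$behavior
    images_rel <- sim$images_relative
    images_abs <- sim$images_absolute
    vs <- cfg$voxel_size_mm
    utils::write.csv(cohort, file.path(cfg$out_dir, "cohort.csv"), row.names = FALSE)
    utils::write.csv(behavior, file.path(cfg$out_dir, "behavior.csv"), row.names = FALSE)
    write_nifti(mask, file.path(cfg$out_dir, "mask.nii.gz"), voxel_size_mm = vs)
    if (isTRUE(cfg$write_images)) {
      img_dir <- file.path(cfg$out_dir, "images")
      dir.create(img_dir, showWarnings = FALSE)
      for (nm in names(images_rel)) {
        write_nifti(images_rel[[nm]], file.path(img_dir, paste0(nm, "_relative.nii.gz")))
        write_nifti(images_abs[[nm]], file.path(img_dir, paste0(nm, "_absolute.nii.gz")))
      }
    }
  } else {
    loaded <- run_stage("load", load_inputs(cfg))
    mask <- loaded$mask
    cohort <- loaded$cohort
    behavior <- loaded$behavior
    images_rel <- loaded$images_relative
    images_abs <- loaded$images_absolute
    vs <- loaded$voxel_size_mm
  }

  prep <- run_stage("prep", {
    blur_all <- function(imgs) lapply(imgs, gaussian_blur, fwhm_mm = cfg$fwhm_mm)
    rel_b <- blur_all(images_rel)
    abs_b <- blur_all(images_abs)
    dm_rel <- assemble_matrix(rel_b, mask)
    cross <- abs_b[vapply(abs_b, function(im) im$dpi == cfg$analysis_dpi, logical(1))]
    dm_abs <- assemble_matrix(cross, mask)
    list(dm_rel = dm_rel, dm_abs = dm_abs)
  })
  dm_abs <- prep$dm_abs
  meta_abs <- dplyr::left_join(
    dm_abs$column_meta,
    dplyr::distinct(cohort, .data$subject_id, .data$sex, .data$group),
    by = "subject_id"
  )

  nmf <- run_stage("opnmf", {
    strata <- paste(meta_abs$group, meta_abs$sex)
    profile <- stability_analysis(dm_abs, k_list = cfg$k_list,
                                  n_splits = cfg$n_splits, seed = cfg$seed,
                                  strata = strata)
    k_sel <- select_k(profile)
    fit_all <- opnmf(dm_abs, k_sel)
    sub_fit <- function(keep) {
      sub <- dm_abs
      sub$values <- sub$values[, keep, drop = FALSE]
      sub$column_meta <- sub$column_meta[keep, ]
      opnmf(sub, min(k_sel, sum(keep)))
    }
    fit_male <- sub_fit(meta_abs$sex == "M")
    fit_female <- sub_fit(meta_abs$sex == "F")
    for (ci in seq_len(fit_all$k)) {
      write_map_nifti(fit_all$W[, ci], dm_abs$voxel_index, dm_abs$grid_shape,
                      file.path(cfg$out_dir, sprintf("component_%02d.nii.gz", ci)),
                      voxel_size_mm = vs)
    }
    utils::write.csv(tibble::as_tibble(profile),
                     file.path(cfg$out_dir, "stability_profile.csv"),
                     row.names = FALSE)
    list(profile = profile, k = k_sel, fit_all = fit_all,
         fit_male = fit_male, fit_female = fit_female)
  })
  report$selected_k <- nmf$k
  report$stability <- as.list(tibble::as_tibble(nmf$profile))

  overlap <- run_stage("overlap", {
    sex_overlap_report(
      nmf$fit_all, nmf$fit_male, nmf$fit_female,
      meta_all = meta_abs,
      meta_male = meta_abs[meta_abs$sex == "M", ],
      meta_female = meta_abs[meta_abs$sex == "F", ]
    )
  })
  utils::write.csv(overlap, file.path(cfg$out_dir, "dice_overlap.csv"),
                   row.names = FALSE)
  report$dice <- setNames(as.list(overlap$kappa), overlap$comparison)
  report$dice_components <- setNames(as.list(overlap$component_1), overlap$comparison)

  vox <- run_stage("voxelwise", {
    meta_rel <- dplyr::left_join(
      prep$dm_rel$column_meta,
      dplyr::distinct(cohort, .data$subject_id, .data$sex, .data$group),
      by = "subject_id"
    )
    fit <- fit_voxelwise_lme(prep$dm_rel, meta = meta_rel)
    key_terms <- intersect(c("groupPFF:dpi", "groupPFF:sexM:dpi"), fit$terms)
    maps <- lapply(key_terms, function(tm) {
      mp <- fdr_map(fit, tm, q_level = cfg$q_level)
      write_map_nifti(mp$statistic, fit$voxel_index, fit$grid_shape,
                      file.path(cfg$out_dir,
                                paste0("tmap_", gsub("[^a-zA-Z0-9]", "_", tm), ".nii.gz")),
                      voxel_size_mm = vs)
      mp
    })
    names(maps) <- key_terms
    list(fit = fit, maps = maps)
  })
  report$voxelwise <- list(
    formula = vox$fit$formula,
    n_voxels = length(vox$fit$theta),
    n_failed = vox$fit$n_failed,
    n_significant = lapply(vox$maps, function(mp) sum(mp$significant))
  )

  behav <- run_stage("behavior", {
    # small cohorts can have no events or separated cells; record the
    # failure instead of aborting the run
    surv <- tryCatch(fit_survival(cohort), error = function(e) e)
    if (!inherits(surv, "error")) {
      utils::write.csv(surv$km, file.path(cfg$out_dir, "km_curves.csv"),
                       row.names = FALSE)
    }
    task_fits <- list()
    for (task in c("wirehang", "pole")) {
      for (d in cfg$behavior_dpis) {
        rec <- encode_task(dplyr::filter(behavior, .data$dpi == d), task,
                           caps = c(pole = 120, wirehang = cfg$wirehang_cap))
        nm <- sprintf("%s_%d", task, d)
        task_fits[[nm]] <- tryCatch(fit_cox(rec), error = function(e) e)
      }
    }
    ok <- !vapply(task_fits, inherits, logical(1), "error")
    p_group <- vapply(task_fits[ok], function(f) {
      f$coefficients$p.value[f$coefficients$term == "groupPFF"]
    }, numeric(1))
    bonf <- bonferroni(p_group, m = 2 * length(cfg$behavior_dpis))
    weight_lme <- fit_longitudinal_lme(cohort, "weight", dpi_coding = "quadratic")
    rotarod_lme <- fit_longitudinal_lme(behavior, "rotarod")
    onset <- tryCatch(suppressWarnings(motor_onset_glm(cohort)),
                      error = function(e) e)
    list(surv = surv, task_fits = task_fits, p_group = p_group, bonf = bonf,
         weight_lme = weight_lme, rotarod_lme = rotarod_lme, onset = onset)
  })
  coef_list <- function(tab) {
    setNames(as.list(tab$estimate), tab$term)
  }
  report$survival <- if (inherits(behav$surv, "error")) {
    list(error = conditionMessage(behav$surv))
  } else {
    list(
      coefficients = coef_list(behav$surv$cox$coefficients),
      p = setNames(as.list(behav$surv$cox$coefficients$p.value),
                   behav$surv$cox$coefficients$term),
      n_events = behav$surv$cox$n_event
    )
  }
  report$motor_tasks <- list(
    group_p = as.list(behav$p_group),
    bonferroni_significant = setNames(as.list(behav$bonf$significant),
                                      names(behav$p_group)),
    failed_fits = names(behav$task_fits)[vapply(behav$task_fits, inherits,
                                                logical(1), "error")]
  )
  report$weight_lme <- coef_list(behav$weight_lme)
  report$rotarod_lme <- coef_list(behav$rotarod_lme)
  if (!inherits(behav$onset, "error")) {
    report$motor_onset <- coef_list(behav$onset$coefficients)
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
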