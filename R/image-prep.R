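#' A per-scan Jacobian determinant volume
#'
#' Wraps one subject-timepoint 3-D Jacobian determinant field from
#' deformation-based morphometry, with its voxel spacing and semantics:
#' `relative` fields model only the nonlinear (focal) deformations,
#' `absolute` fields additionally carry residual global size differences.
#'
#' @param data 3-D numeric array.
#' @param voxel_size_mm Voxel spacing in mm (recycled to length 3).
#' @param flavor `"relative"` or `"absolute"`.
#' @param subject_id,dpi Scan identity.
#' @param is_log Whether `data` is already log-transformed.
#' @return An object of class `jacobian_image`.
#' @export
jacobian_image <- function(data, voxel_size_mm = c(0.1, 0.1, 0.1),
                           flavor = c("relative", "absolute"),
                           subject_id = NA_character_, dpi = NA_real_,
                           is_log = FALSE) {
  flavor <- match.arg(flavor)
  data <- unclass(data)
  if (length(dim(data)) != 3L) {
    stop_dbmcov("`data` must be a 3-D array.", "dbmcov_image_error")
  }
  structure(
    list(data = data, voxel_size_mm = rep(as.numeric(voxel_size_mm), length.out = 3),
         flavor = flavor, subject_id = subject_id, dpi = as.numeric(dpi),
         is_log = isTRUE(is_log)),
    class = "jacobian_image"
  )
}

#' @export
print.jacobian_image <- function(x, ...) {
  cat("<jacobian_image> ", x$subject_id, " @ ", x$dpi, " dpi | ",
      paste(dim(x$data), collapse = "x"), " voxels (",
      paste(x$voxel_size_mm, collapse = "x"), " mm) | ", x$flavor,
      if (x$is_log) " | log scale" else "", "\n", sep = "")
  invisible(x)
}

#' Natural-log transform of a Jacobian volume
#'
#' Log-Jacobians are symmetric around zero (expansion positive, contraction
#' negative) and better conform to the normality assumptions of the
#' downstream voxel-wise statistics.
#'
#' @param img A [jacobian_image()] with `is_log = FALSE`.
#' @param mask Optional logical array; only in-mask voxels must be positive
#'   and are transformed (out-of-mask voxels are set to 0).
#' @return The log-transformed `jacobian_image` (`is_log = TRUE`).
#' @export
log_transform <- function(img, mask = NULL) {
  stopifnot(inherits(img, "jacobian_image"))
  if (img$is_log) {
    stop_dbmcov("Volume is already log-transformed.", "dbmcov_image_error")
  }
  v <- img$data
  if (is.null(mask)) mask <- array(TRUE, dim = dim(v))
  bad <- which(mask & !(is.finite(v) & v > 0))
  if (length(bad) > 0) {
    ijk <- arrayInd(bad[1], dim(v))
    stop_dbmcov(
      sprintf("Non-positive Jacobian at voxel (%d, %d, %d) (%d offending voxel(s) in mask).",
              ijk[1], ijk[2], ijk[3], length(bad)),
      "dbmcov_image_error"
    )
  }
  out <- array(0, dim = dim(v))
  out[mask] <- log(v[mask])
  img$data <- out
  img$is_log <- TRUE
  img
}

#' Gaussian smoothing of a Jacobian volume
#'
#' Separable Gaussian blur specified by its full width at half maximum in
#' mm, converted per axis to voxel units
#' (`sigma = fwhm / (2 * sqrt(2 * log(2)))`). Reflective boundaries
#' conserve the volume mean.
#'
#' @param img A [jacobian_image()].
#' @param fwhm_mm Kernel FWHM in mm (> 0). The study-scale default for
#'   mouse DBM is ~0.085 mm.
#' @return The smoothed `jacobian_image`.
#' @export
gaussian_blur <- function(img, fwhm_mm = 0.085) {
  stopifnot(inherits(img, "jacobian_image"))
  if (fwhm_mm <= 0) stop_dbmcov("`fwhm_mm` must be > 0.", "dbmcov_image_error")
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / img$voxel_size_mm
  if (fwhm_mm < 0.1 * min(img$voxel_size_mm)) {
    warn(sprintf("FWHM %.4g mm is below a tenth of a voxel; returning input unchanged.",
                 fwhm_mm), class = "dbmcov_blur_warning")
    return(img)
  }
  img$data <- blur_array(img$data, sigma_vox)
  img
}

#' Assemble the voxel-by-subject analysis matrix
#'
#' Stacks in-mask voxels of log-Jacobian volumes as columns, optionally
#' inverts the sign so atrophy (contraction) is positive, z-scores each
#' voxel across scans, drops zero-variance voxels, and applies a single
#' global scalar shift so the minimum is exactly zero — the non-negative
#' input the orthogonal factorization requires. The shift and the per-voxel
#' mean/SD are recorded so the transform can be undone.
#'
#' @param images List of [jacobian_image()] objects on a common grid,
#'   common flavor, all log-transformed.
#' @param mask Logical 3-D array defining the analysis voxels.
#' @param invert Multiply by -1 before z-scoring (atrophy positive).
#' @param zscore Z-score each voxel across scans.
#' @return An object of class `data_matrix`: `values` (m x n, min 0),
#'   `voxel_index` (linear indices of retained in-mask voxels, R
#'   column-major order), `column_meta` (tibble `subject_id`, `dpi`),
#'   `zshift` (the scalar added), `row_mean`, `row_sd`, `inverted`,
#'   `zscored`, `n_dropped`, `grid_shape`, `voxel_size_mm`, `flavor`.
#' @export
assemble_matrix <- function(images, mask, invert = TRUE, zscore = TRUE) {
  if (length(images) < 3L) {
    stop_dbmcov("At least 3 scans are required to assemble a matrix.",
                "dbmcov_matrix_error")
  }
  stopifnot(all(vapply(images, inherits, logical(1), "jacobian_image")))
  dims <- vapply(images, function(x) dim(x$data), integer(3))
  if (any(dims != dims[, 1])) {
    stop_dbmcov("All images must share one voxel grid.", "dbmcov_matrix_error")
  }
  if (!identical(dim(mask), dim(images[[1]]$data))) {
    stop_dbmcov("Mask grid does not match the image grid.", "dbmcov_matrix_error")
  }
  flavors <- unique(vapply(images, `[[`, character(1), "flavor"))
  if (length(flavors) != 1L) {
    stop_dbmcov("Mixed Jacobian flavors in one matrix.", "dbmcov_matrix_error")
  }
  if (!all(vapply(images, `[[`, logical(1), "is_log"))) {
    stop_dbmcov("All images must be log-transformed.", "dbmcov_matrix_error")
  }
  voxel_index <- which(mask)
  values <- vapply(images, function(x) x$data[voxel_index],
                   numeric(length(voxel_index)))
  if (!all(is.finite(values))) {
    stop_dbmcov("Non-finite values inside the mask.", "dbmcov_matrix_error")
  }
  if (invert) values <- -values
  n <- ncol(values)
  row_mean <- rowMeans(values)
  row_sd <- sqrt(rowSums((values - row_mean)^2) / (n - 1))
  keep <- row_sd > 0
  n_dropped <- sum(!keep)
  if (!any(keep)) {
    stop_dbmcov("No variable voxels: every in-mask voxel has zero variance across scans.",
                "dbmcov_matrix_error")
  }
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d zero-variance voxel(s) of %d.", n_dropped,
                   length(keep)), class = "dbmcov_dropped_voxels")
  }
  values <- values[keep, , drop = FALSE]
  row_mean <- row_mean[keep]
  row_sd <- row_sd[keep]
  voxel_index <- voxel_index[keep]
  if (zscore) values <- (values - row_mean) / row_sd
  zshift <- -min(values)
  values <- values + zshift
  column_meta <- tibble::tibble(
    subject_id = vapply(images, `[[`, character(1), "subject_id"),
    dpi = vapply(images, `[[`, numeric(1), "dpi")
  )
  structure(
    list(values = values, voxel_index = voxel_index, column_meta = column_meta,
         zshift = zshift, row_mean = row_mean, row_sd = row_sd,
         inverted = invert, zscored = zscore, n_dropped = n_dropped,
         grid_shape = dim(mask), voxel_size_mm = images[[1]]$voxel_size_mm,
         flavor = flavors),
    class = "data_matrix"
  )
}

#' @export
print.data_matrix <- function(x, ...) {
  cat("<data_matrix> ", nrow(x$values), " voxels x ", ncol(x$values),
      " scans | ", x$flavor,
      if (x$inverted) " | inverted", if (x$zscored) " | z-scored",
      " | shift ", signif(x$zshift, 4), "\n", sep = "")
  invisible(x)
}

#' Undo the z-score and non-negativity shift
#'
#' Inverse of the normalization in [assemble_matrix()]: subtracts the
#' global shift, multiplies back the per-voxel SD and adds the mean (and
#' undoes the sign inversion), recovering the blurred log-Jacobian values.
#'
#' @param dm A `data_matrix`.
#' @return Matrix on the original (inverted log-Jacobian) scale.
#' @export
unassemble_matrix <- function(dm) {
  stopifnot(inherits(dm, "data_matrix"))
  v <- dm$values - dm$zshift
  if (dm$zscored) v <- v * dm$row_sd + dm$row_mean
  if (dm$inverted) v <- -v
  v
}

#' Write a per-voxel statistic back onto the volume grid
#'
#' @param dm A `data_matrix` (supplies the voxel index map and grid).
#' @param values One value per retained voxel.
#' @param fill Value for voxels outside the retained set.
#' @return A 3-D array on the original grid.
#' @export
map_to_volume <- function(dm, values, fill = 0) {
  stopifnot(inherits(dm, "data_matrix"), length(values) == length(dm$voxel_index))
  vol <- array(fill, dim = dm$grid_shape)
  vol[dm$voxel_index] <- values
  vol
}
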