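# NIfTI-1 reading and writing (RNifti backend).

#' Read a Jacobian volume from NIfTI
#'
#' @param path Path to a `.nii` or `.nii.gz` file. When `subject_id`/`dpi`
#'   are missing they are parsed from a `{subject}_{dpi}.nii[.gz]`
#'   filename.
#' @param flavor Jacobian flavor to record.
#' @param subject_id,dpi Scan identity (optional).
#' @param is_log Whether the stored field is already log-transformed.
#' @return A [jacobian_image()].
#' @export
read_nifti <- function(path, flavor = c("relative", "absolute"),
                       subject_id = NULL, dpi = NULL, is_log = TRUE) {
  flavor <- match.arg(flavor)
  if (!file.exists(path)) {
    stop_dbmcov(paste0("No such file: ", path), "dbmcov_io_error")
  }
  nii <- RNifti::readNifti(path)
  if (length(dim(nii)) != 3L) {
    stop_dbmcov(sprintf("%s is %d-D; a 3-D volume is required.",
                        path, length(dim(nii))), "dbmcov_io_error")
  }
  stem <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (is.null(subject_id) || is.null(dpi)) {
    parts <- strsplit(stem, "_")[[1]]
    parsed_dpi <- suppressWarnings(as.numeric(parts[length(parts)]))
    if (is.null(dpi)) dpi <- parsed_dpi
    if (is.null(subject_id)) {
      subject_id <- if (!is.na(parsed_dpi) && length(parts) > 1) {
        paste(parts[-length(parts)], collapse = "_")
      } else stem
    }
  }
  img <- jacobian_image(as.array(nii),
                        voxel_size_mm = RNifti::pixdim(nii)[1:3],
                        flavor = flavor, subject_id = subject_id,
                        dpi = dpi, is_log = is_log)
  attr(img, "xform") <- RNifti::xform(nii)
  img
}

#' Write a volume to NIfTI
#'
#' Accepts a [jacobian_image()] or a bare 3-D array. Data are stored as
#' 64-bit floats, so a write-read round trip preserves values to floating
#' precision and the affine exactly.
#'
#' @param img `jacobian_image`, or 3-D array/logical mask.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Spacing when `img` is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, voxel_size_mm = c(0.1, 0.1, 0.1)) {
  if (inherits(img, "jacobian_image")) {
    arr <- img$data
    voxel_size_mm <- img$voxel_size_mm
  } else {
    arr <- img + 0 # logical masks become numeric
  }
  if (length(dim(arr)) != 3L) {
    stop_dbmcov("Only 3-D volumes are written.", "dbmcov_io_error")
  }
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- voxel_size_mm
  RNifti::writeNifti(nii, path, datatype = "double")
  invisible(path)
}

#' Check that two NIfTI-backed volumes share an affine
#'
#' @param a,b `jacobian_image`s carrying an `xform` attribute (as from
#'   [read_nifti()]), or paths.
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_same_space <- function(a, b) {
  xf <- function(x) {
    if (is.character(x)) x <- read_nifti(x)
    attr(x, "xform") %||% diag(4)
  }
  if (!isTRUE(all.equal(unclass(xf(a)), unclass(xf(b)), tolerance = 1e-5,
                        check.attributes = FALSE))) {
    stop_dbmcov("Affines differ between volumes; images are not in the same space.",
                "dbmcov_io_error")
  }
  invisible(TRUE)
}

#' Write a component map or statistic map as NIfTI
#'
#' @param values Per-voxel values (length of `voxel_index`).
#' @param voxel_index Linear indices into the grid.
#' @param grid_shape Grid dimensions.
#' @param path Output path.
#' @param voxel_size_mm Spacing.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(values, voxel_index, grid_shape, path,
                            voxel_size_mm = c(0.1, 0.1, 0.1)) {
  vol <- array(0, dim = grid_shape)
  vol[voxel_index] <- values
  write_nifti(vol, path, voxel_size_mm = voxel_size_mm)
}
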