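# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# 1-D Gaussian blur along the rows of a matrix, symmetric (reflective)
# boundary. Kernel is normalized so total mass is conserved.
blur_axis <- function(mat, sigma) {
  n <- nrow(mat)
  if (sigma <= 0 || n == 1L) return(mat)
  r <- min(max(1L, as.integer(ceiling(4 * sigma))), n - 1L)
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  top <- mat[r:1, , drop = FALSE]
  bot <- mat[n:(n - r + 1L), , drop = FALSE]
  padded <- rbind(top, mat, bot)
  out <- matrix(0, n, ncol(mat))
  for (j in seq_len(2L * r + 1L)) {
    out <- out + k[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

# Separable 3-D Gaussian blur; sigma_vox gives the SD in voxels per axis.
blur_array <- function(a, sigma_vox) {
  d <- dim(a)
  stopifnot(length(d) == 3L, length(sigma_vox) == 3L)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) {
      perm <- c(ax, setdiff(1:3, ax))
      m <- matrix(aperm(a, perm), nrow = d[ax])
      m <- blur_axis(m, sigma_vox[ax])
      a <- aperm(array(m, d[perm]), order(perm))
    }
  }
  a
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Ellipsoid indicator on a voxel grid: centre and semi-axes in voxel units.
ellipsoid_mask <- function(grid_shape, centre, semi_axes) {
  ax <- lapply(1:3, function(i) (seq_len(grid_shape[i]) - centre[i]) / semi_axes[i])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  array(d2 <= 1, dim = grid_shape)
}
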