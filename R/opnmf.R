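# Orthogonal projective NMF of a non-negative voxel x subject matrix.

as_values_matrix <- function(X) {
  if (inherits(X, "data_matrix")) X$values else as.matrix(X)
}

#' Orthogonal projective non-negative matrix factorization
#'
#' Decomposes a non-negative m-voxel by n-subject matrix `X` into a
#' component matrix `W` (m x k, spatial patterns) and a subject-weight
#' matrix `H` (k x n) whose product reconstructs `X` as well as possible in
#' the Frobenius sense. The projective variant ties `H = W'X`, and the
#' multiplicative update
#' `W <- W * (X X' W) / (W W' X X' W)`
#' drives `W` toward a non-negative, near-orthogonal basis, so each voxel
#' effectively belongs to one component.
#'
#' Updates run with an optimal global rescaling of `W` each iteration and a
#' monotone guard: an iteration that would increase the reconstruction
#' error is rolled back and the algorithm stops, so the recorded error
#' trace is nonincreasing. At the end, columns of `W` are normalized to
#' unit Euclidean norm with the scale carried into `H` (the reconstruction
#' `W H` is unchanged).
#'
#' @param X A [assemble_matrix()] result or non-negative matrix.
#' @param k Number of components, `1 <= k <= min(m, n)`.
#' @param max_iter Maximum multiplicative updates.
#' @param tol Relative change in reconstruction error below which the
#'   algorithm is declared converged.
#' @param init `"nndsvd"` (deterministic, SVD-based, the default) or
#'   `"random"` (seeded uniform).
#' @param seed Seed for `init = "random"`; recorded either way.
#' @return Object of class `opnmf_fit`: `W`, `H`, `k`, `error_trace`
#'   (Frobenius error per iteration, nonincreasing), `n_iter`,
#'   `converged`, `init`, `seed`, plus the voxel/grid bookkeeping of `X`
#'   when it was a `data_matrix`.
#' @examples
#' X <- matrix(rexp(60), 10, 6)
#' fit <- opnmf(X, k = 2)
#' fit$converged
#' @export
opnmf <- function(X, k, max_iter = 10000L, tol = 1e-5,
                  init = c("nndsvd", "random"), seed = 1L) {
  init <- match.arg(init)
  Xv <- as_values_matrix(X)
  m <- nrow(Xv); n <- ncol(Xv)
  if (k < 1 || k > min(m, n)) {
    stop_dbmcov(sprintf("`k` must lie in [1, %d].", min(m, n)), "dbmcov_opnmf_error")
  }
  if (any(Xv < 0)) stop_dbmcov("`X` must be non-negative.", "dbmcov_opnmf_error")
  eps <- 1e-12
  W <- if (init == "nndsvd") nndsvd_init(Xv, k) else
    with_seed(seed, matrix(runif(m * k, 0.1, 1), m, k))
  W[W < eps] <- eps

  x_sq <- sum(Xv^2)
  err_of <- function(W) {
    S <- crossprod(W, Xv)           # k x n
    G <- crossprod(W)               # k x k
    sqrt(max(x_sq - 2 * sum(S * S) + sum(S * (G %*% S)), 0))
  }
  # optimal global scale of W for the projective reconstruction W W' X
  rescale <- function(W) {
    S <- crossprod(W, Xv)
    G <- crossprod(W)
    denom <- sum(S * (G %*% S))
    if (denom > 0) W * (sum(S * S) / denom)^0.25 else W
  }
  # exact solve on the current argmax-ownership partition: with disjoint
  # supports the projective objective separates, and the optimal column on
  # each support block is the block's dominant left singular vector
  polish <- function(W) {
    lab <- max.col(W, ties.method = "first")
    on <- W[cbind(seq_len(m), lab)] > 0
    Wp <- matrix(0, m, k)
    for (ci in seq_len(k)) {
      rows <- which(lab == ci & on)
      if (length(rows) == 0L) next
      u <- svd(Xv[rows, , drop = FALSE], nu = 1, nv = 0)$u[, 1]
      if (sum(u) < 0) u <- -u
      u[u < 0] <- 0 # Perron vector of a nonneg block; clip numeric noise
      nu2 <- sqrt(sum(u^2))
      if (nu2 > 0) Wp[rows, ci] <- u / nu2
    }
    Wp
  }

  W <- rescale(W)
  err <- err_of(W)
  trace <- numeric(max_iter + 16L)
  trace[1L] <- err
  converged <- FALSE
  it <- 0L
  phase_done <- FALSE
  rounds <- 0L
  while (it < max_iter && !phase_done) {
    it <- it + 1L
    # symmetric projective update for ||X - W W'X||_F^2:
    # W <- W * (2 XX'W) / (W W'XX'W + XX'W W'W), with the k x k identities
    # W'XX'W = S'S and X'(W W'W) = S G  (S = X'W, G = W'W)
    S <- crossprod(Xv, W)                       # n x k  (X'W)
    G <- crossprod(W)                           # k x k
    ratio <- (2 * (Xv %*% S) + eps) /
      (W %*% crossprod(S) + Xv %*% (S %*% G) + eps)
    if (!all(is.finite(ratio))) {
      stop_dbmcov(sprintf("Non-finite update at iteration %d.", it),
                  "dbmcov_opnmf_error")
    }
    accepted <- FALSE
    damp <- 1
    for (try in 1:4) {
      W_new <- rescale(W * ratio^damp)
      err_new <- err_of(W_new)
      if (err_new <= err * (1 + 1e-12)) {
        accepted <- TRUE
        break
      }
      damp <- damp / 2 # damped retry keeps the error trace nonincreasing
    }
    stalled <- FALSE
    if (accepted) {
      W <- W_new
      trace[it + 1L] <- min(err_new, err)
      rel <- if (err > eps) (err - err_new) / err else 0
      err <- min(err_new, err)
      stalled <- rel < tol
    } else {
      it <- it - 1L
      stalled <- TRUE
    }
    if (stalled || it %% 250L == 0L) {
      # periodically (and at stall) try the exact partition solve
      Wp <- rescale(polish(W))
      err_p <- err_of(Wp)
      if (err_p < err * (1 - 1e-12)) {
        W <- Wp
        err <- err_p
        it <- it + 1L
        trace[it + 1L] <- err_p
      } else if (stalled) {
        converged <- TRUE
        phase_done <- TRUE
      }
    }
  }
  trace <- trace[seq_len(it + 1L)]
  nrm <- sqrt(colSums(W^2))
  nrm[nrm == 0] <- 1
  W_out <- sweep(W, 2, nrm, `/`)
  H_out <- sweep(crossprod(W_out, Xv), 1, nrm^2, `*`)
  ord <- order(rowSums(H_out^2), decreasing = TRUE)
  out <- list(W = W_out[, ord, drop = FALSE], H = H_out[ord, , drop = FALSE],
              k = as.integer(k), error_trace = trace, n_iter = it,
              converged = converged, init = init, seed = seed)
  if (inherits(X, "data_matrix")) {
    out$column_meta <- X$column_meta
    out$voxel_index <- X$voxel_index
    out$grid_shape <- X$grid_shape
    out$voxel_size_mm <- X$voxel_size_mm
  }
  structure(out, class = "opnmf_fit")
}

# Non-negative double SVD initialization (deterministic).
nndsvd_init <- function(X, k) {
  sv <- svd(X, nu = k, nv = k)
  m <- nrow(X)
  W <- matrix(0, m, k)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      n_up <- sqrt(sum(up^2)); n_vp <- sqrt(sum(vp^2))
      n_un <- sqrt(sum(un^2)); n_vn <- sqrt(sum(vn^2))
      if (n_up * n_vp >= n_un * n_vn) {
        W[, j] <- sqrt(sv$d[j] * n_up * n_vp) * up / max(n_up, 1e-12)
      } else {
        W[, j] <- sqrt(sv$d[j] * n_un * n_vn) * un / max(n_un, 1e-12)
      }
    }
  }
  W[W < 1e-9] <- mean(abs(X)) * 1e-4
  W
}

#' @export
print.opnmf_fit <- function(x, ...) {
  cat("<opnmf_fit> k =", x$k, "|", nrow(x$W), "voxels x", ncol(x$H), "scans |",
      x$n_iter, "iterations |",
      if (x$converged) "converged" else "max_iter reached",
      "| error", signif(tail(x$error_trace, 1), 6), "\n")
  invisible(x)
}

#' Frobenius reconstruction error
#'
#' The Frobenius norm of the element-wise difference between the input and
#' its reconstruction `W H`.
#'
#' @param X Input matrix (or `data_matrix`).
#' @param W m x k component matrix.
#' @param H k x n weight matrix.
#' @return Non-negative scalar.
#' @export
reconstruction_error <- function(X, W, H) {
  Xv <- as_values_matrix(X)
  W <- as.matrix(W); H <- as.matrix(H)
  if (nrow(W) != nrow(Xv) || ncol(H) != ncol(Xv) || ncol(W) != nrow(H)) {
    stop_dbmcov("Shapes of X, W, H are not conformable.", "dbmcov_opnmf_error")
  }
  sqrt(sum((Xv - W %*% H)^2))
}

#' Off-diagonal energy ratio of W'W
#'
#' Orthogonality diagnostic: the ratio of off-diagonal to diagonal energy
#' of the component Gram matrix; near 0 for an orthogonal basis.
#'
#' @param W Component matrix or `opnmf_fit`.
#' @return Scalar in `[0, Inf)`.
#' @export
orthogonality_defect <- function(W) {
  if (inherits(W, "opnmf_fit")) W <- W$W
  G <- crossprod(W)
  diag_e <- sum(diag(G)^2)
  (sum(G^2) - diag_e) / diag_e
}

#' @rdname opnmf
#' @param x An `opnmf_fit`.
#' @param ... Unused.
#' @details `tidy()` returns the subject weights in long form (one row per
#'   scan per component); `glance()` a one-row fit summary.
#' @export
tidy.opnmf_fit <- function(x, ...) {
  meta <- x$column_meta %||%
    tibble::tibble(subject_id = paste0("col", seq_len(ncol(x$H))), dpi = NA_real_)
  out <- tidyr::expand_grid(component = seq_len(x$k), col = seq_len(ncol(x$H)))
  out$weight <- x$H[cbind(out$component, out$col)]
  dplyr::bind_cols(out[, c("component", "weight")], meta[out$col, ])
}

#' @rdname opnmf
#' @export
glance.opnmf_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_iter = x$n_iter, converged = x$converged,
    final_error = tail(x$error_trace, 1),
    orthogonality_defect = orthogonality_defect(x)
  )
}
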