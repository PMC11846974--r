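# Split-half stability analysis and granularity selection.

# O(n^3) Hungarian algorithm (Jonker-Volgenant potentials) minimizing total
# cost of a square assignment. No assignment-problem solver ships with the
# installed stack, so this is implemented here; brute-force enumeration
# cross-checks it in the tests.
hungarian_solve <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1L)     # column potentials, slot n+1 = virtual column 0
  p <- integer(n + 1L)     # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assignment <- integer(n)          # assignment[row] = column
  for (j in seq_len(n)) assignment[p[j]] <- j
  assignment
}

cosine_matrix <- function(W1, W2) {
  n1 <- sqrt(colSums(W1^2)); n2 <- sqrt(colSums(W2^2))
  n1[n1 == 0] <- 1; n2[n2 == 0] <- 1
  crossprod(W1, W2) / outer(n1, n2)
}

#' Match components of two decompositions
#'
#' One-to-one assignment of the columns of `W1` to the columns of `W2`
#' maximizing total cosine similarity (optimal bipartite matching). For
#' non-negative inputs every cosine lies in `[0, 1]`, so the mean matched
#' similarity does too.
#'
#' @param W1,W2 m x k component matrices (or `opnmf_fit`s) on the same
#'   voxel space with equal `k`.
#' @return List: `assignment` (for each column of `W1`, its match in
#'   `W2`), `similarity` (matched cosines), `mean_similarity`.
#' @export
match_components <- function(W1, W2) {
  if (inherits(W1, "opnmf_fit")) W1 <- W1$W
  if (inherits(W2, "opnmf_fit")) W2 <- W2$W
  if (nrow(W1) != nrow(W2)) {
    stop_dbmcov("Component matrices live on different voxel spaces.",
                "dbmcov_match_error")
  }
  if (ncol(W1) != ncol(W2)) {
    stop_dbmcov("Component matrices have different k.", "dbmcov_match_error")
  }
  C <- cosine_matrix(W1, W2)
  assignment <- hungarian_solve(-C)
  sims <- C[cbind(seq_len(ncol(W1)), assignment)]
  list(assignment = assignment, similarity = sims,
       mean_similarity = mean(sims))
}

# Split columns into two disjoint halves, stratified by `strata` when
# given (alternating assignment within each shuffled stratum).
split_halves <- function(n, strata = NULL) {
  if (is.null(strata)) strata <- rep(1L, n)
  strata <- as.factor(strata)
  h1 <- integer(0)
  for (lev in levels(strata)) {
    idx <- sample(which(strata == lev))
    h1 <- c(h1, idx[seq_len(floor(length(idx) / 2))])
  }
  list(sort(h1), sort(setdiff(seq_len(n), h1)))
}

#' Split-half stability analysis across granularities
#'
#' For each candidate number of components `k`, subjects are repeatedly
#' split into two disjoint halves (stratified by `strata` when supplied,
#' e.g. sex-by-group cells), the factorization is run on each half, and the
#' two half-sample component sets are compared by optimal-matching cosine
#' similarity; the mean matched similarity over splits is the stability at
#' `k`. Alongside, the factorization runs on the full matrix at each `k`
#' and the change in Frobenius reconstruction error from the previous
#' granularity is recorded.
#'
#' @param X `data_matrix` or non-negative matrix (>= 6 columns).
#' @param k_list Increasing granularities (default 2 to 20 by 2).
#' @param n_splits Subject splits per granularity.
#' @param seed Seed for the splits.
#' @param strata Optional per-column stratification (vector, length
#'   `ncol(X)`).
#' @param max_iter,tol,init Passed to [opnmf()].
#' @return A tibble of class `stability_profile`: `k`, `stability`,
#'   `error` (full-matrix reconstruction error), `error_gradient`
#'   (`error(k) - error(previous k)`, NA for the first entry).
#' @export
stability_analysis <- function(X, k_list = seq(2L, 20L, 2L), n_splits = 5L,
                               seed = 1L, strata = NULL, max_iter = 10000L,
                               tol = 1e-5, init = "nndsvd") {
  Xv <- as_values_matrix(X)
  n <- ncol(Xv)
  if (n < 6L) {
    stop_dbmcov("Need at least 6 columns for split-half stability.",
                "dbmcov_stability_error")
  }
  k_list <- as.integer(k_list)
  if (any(diff(k_list) <= 0)) {
    stop_dbmcov("`k_list` must be strictly increasing.", "dbmcov_stability_error")
  }
  if (max(k_list) > floor(n / 2)) {
    stop_dbmcov("Largest k exceeds the half-sample size.", "dbmcov_stability_error")
  }
  splits <- with_seed(seed, lapply(seq_len(n_splits), function(s) split_halves(n, strata)))
  stability <- numeric(length(k_list))
  error <- numeric(length(k_list))
  for (i in seq_along(k_list)) {
    k <- k_list[i]
    sims <- vapply(splits, function(sp) {
      f1 <- opnmf(Xv[, sp[[1]], drop = FALSE], k, max_iter = max_iter,
                  tol = tol, init = init)
      f2 <- opnmf(Xv[, sp[[2]], drop = FALSE], k, max_iter = max_iter,
                  tol = tol, init = init)
      match_components(f1$W, f2$W)$mean_similarity
    }, numeric(1))
    stability[i] <- mean(sims)
    fit <- opnmf(Xv, k, max_iter = max_iter, tol = tol, init = init)
    error[i] <- tail(fit$error_trace, 1)
  }
  out <- tibble::tibble(
    k = k_list, stability = stability, error = error,
    error_gradient = c(NA_real_, diff(error))
  )
  attr(out, "n_splits") <- n_splits
  attr(out, "seed") <- seed
  class(out) <- c("stability_profile", class(out))
  out
}

#' Select the number of components from a stability profile
#'
#' The default rule balances high stability, a low reconstruction-error
#' gradient and low `k`: it returns the smallest granularity whose
#' stability is within 90% of the maximum and for which the error gradient
#' of the step *leaving* it (the gain from increasing `k` further) is at
#' most the median absolute gradient — i.e. the first compact, stable
#' granularity beyond which extra components buy little accuracy. If no
#' granularity satisfies both, the smallest one within 90% of maximum
#' stability is returned. Supplying `rule` (a function
#' `profile -> k`) replaces the default.
#'
#' @param profile A [stability_analysis()] result.
#' @param rule Optional replacement selection function.
#' @return The selected `k` (integer).
#' @export
select_k <- function(profile, rule = NULL) {
  if (!inherits(profile, "stability_profile") || nrow(profile) == 0L) {
    stop_dbmcov("`profile` must be a non-empty stability_profile.",
                "dbmcov_stability_error")
  }
  if (!is.null(rule)) return(rule(profile))
  if (nrow(profile) == 1L) return(profile$k[1])
  grad <- profile$error_gradient
  # gradient of the step leaving k; the last k keeps its own (backward) step
  grad_out <- c(grad[-1], grad[length(grad)])
  med <- median(abs(grad), na.rm = TRUE)
  stab_ok <- profile$stability >= 0.9 * max(profile$stability)
  grad_ok <- is.na(grad_out) | abs(grad_out) <= med
  cand <- which(stab_ok & grad_ok)
  if (length(cand) == 0L) cand <- which(stab_ok)
  profile$k[min(cand)]
}

#' @rdname stability_analysis
#' @param object A `stability_profile`.
#' @param ... Unused.
#' @export
glance.stability_profile <- function(object, ...) {
  tibble::tibble(
    n_granularities = nrow(object),
    n_splits = attr(object, "n_splits"),
    selected_k = select_k(object),
    max_stability = max(object$stability)
  )
}

#' Plot a stability profile
#'
#' Stability and reconstruction-error gradient against granularity, with
#' the selected `k` marked.
#'
#' @param object A `stability_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_profile <- function(object, ...) {
  sel <- select_k(object)
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[, c("k", "stability", "error_gradient")],
                              -"k", names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = sel, linetype = "dashed") +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "granularity k", y = NULL,
                  title = sprintf("Split-half stability profile (selected k = %d)", sel)) +
    ggplot2::theme_minimal()
}
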