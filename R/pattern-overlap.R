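# Binarized component maps and Dice overlap.

#' Binarize component maps by voxel ownership
#'
#' Assigns each voxel to the component with the largest weight (ties broken
#' toward the lowest component index, counted and reported), consistent
#' with the voxel-exclusivity of the orthogonal factorization: a voxel can
#' belong to only one component. Voxels whose weights are all zero get
#' label `NA` and are counted.
#'
#' @param W m x k component matrix or `opnmf_fit`.
#' @return Integer vector of length m (component label per voxel, `NA` for
#'   all-zero rows), with attributes `n_zero_rows` and `n_ties`.
#' @export
binarize_components <- function(W) {
  if (inherits(W, "opnmf_fit")) W <- W$W
  W <- as.matrix(W)
  labels <- max.col(W, ties.method = "first")
  rmax <- W[cbind(seq_len(nrow(W)), labels)]
  n_ties <- sum(rowSums(W == rmax) > 1L & rmax > 0)
  zero <- rmax <= 0
  labels[zero] <- NA_integer_
  if (any(zero)) {
    inform(sprintf("%d voxel(s) with all-zero weights excluded from binarization.",
                   sum(zero)), class = "dbmcov_zero_rows")
  }
  if (n_ties > 0) {
    inform(sprintf("%d tied voxel(s) assigned to the lowest component index.",
                   n_ties), class = "dbmcov_binarize_ties")
  }
  structure(labels, n_zero_rows = sum(zero), n_ties = n_ties)
}

#' Binarized voxel set of one component
#'
#' @param W Component matrix or `opnmf_fit`.
#' @param component Component index (1-based).
#' @return Logical vector over the voxel space: voxel owned by `component`.
#' @export
binarize <- function(W, component) {
  if (inherits(W, "opnmf_fit")) W <- W$W
  if (component < 1 || component > ncol(W)) {
    stop_dbmcov("`component` out of range.", "dbmcov_overlap_error")
  }
  labels <- suppressMessages(binarize_components(W))
  !is.na(labels) & labels == component
}

#' Dice similarity coefficient of two binarized patterns
#'
#' `kappa = 2a / (2a + b + c)` where `a` is the number of voxels common to
#' both patterns and `b`, `c` the counts unique to each. A value of 1 is
#' perfect overlap, 0 none; two empty patterns are defined to have
#' `kappa = 0`.
#'
#' @param A,B Logical vectors over the same mask space.
#' @return One-row tibble of class `dice_result`: `a`, `b`, `c`, `kappa`.
#' @examples
#' dice_kappa(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE))$kappa
#' @export
dice_kappa <- function(A, B) {
  A <- as.logical(A); B <- as.logical(B)
  if (length(A) != length(B)) {
    stop_dbmcov("Patterns live on mismatched mask spaces.", "dbmcov_overlap_error")
  }
  if (anyNA(A) || anyNA(B)) {
    stop_dbmcov("Patterns must not contain NA.", "dbmcov_overlap_error")
  }
  a <- sum(A & B)
  b <- sum(A & !B)
  cc <- sum(!A & B)
  kappa <- if (2 * a + b + cc == 0) 0 else 2 * a / (2 * a + b + cc)
  if ((a + b == 0 || a + cc == 0) && (a + b + cc > 0)) {
    warn("One pattern is empty; kappa is 0.", class = "dbmcov_empty_pattern")
  }
  out <- tibble::tibble(a = a, b = b, c = cc, kappa = kappa)
  class(out) <- c("dice_result", class(out))
  out
}

# Component whose subject-weight GLM injection-group effect is most
# significant; the decomposition's "disease" component.
select_group_component <- function(fit, meta) {
  ps <- vapply(seq_len(fit$k), function(ci) {
    g <- suppressWarnings(subject_weight_glm(fit, ci, meta))
    p <- g$coefficients$p.value[g$coefficients$term == "groupPFF"]
    if (length(p) == 0 || is.na(p)) 1 else p
  }, numeric(1))
  which.min(ps)
}

#' Overlap of sex-specific and all-subject disease patterns
#'
#' For each of three decompositions (all subjects, males only, females
#' only) the group-differentiating component is identified as the one
#' whose subject-weight GLM injection-group effect has the smallest
#' p-value (or taken from `components`), binarized by voxel ownership, and
#' the Dice coefficients between the three binarized patterns are
#' reported. A large all-vs-one-sex kappa indicates that the pooled
#' pattern is driven by that sex.
#'
#' @param fit_all,fit_male,fit_female `opnmf_fit`s on the same voxel space.
#' @param meta_all,meta_male,meta_female Per-column metadata tibbles
#'   (`group`, `sex`) for the corresponding fits; only needed when
#'   `components` is NULL.
#' @param components Optional named integer vector
#'   (`all`, `male`, `female`) of pre-selected components.
#' @return Tibble: `comparison`, selected `component_1`/`component_2`,
#'   `a`, `b`, `c`, `kappa`.
#' @export
sex_overlap_report <- function(fit_all, fit_male, fit_female,
                               meta_all = NULL, meta_male = NULL,
                               meta_female = NULL, components = NULL) {
  fits <- list(all = fit_all, male = fit_male, female = fit_female)
  m <- vapply(fits, function(f) nrow(f$W), integer(1))
  if (length(unique(m)) != 1L) {
    stop_dbmcov("Decompositions are not on the same voxel space.",
                "dbmcov_overlap_error")
  }
  if (is.null(components)) {
    metas <- list(all = meta_all, male = meta_male, female = meta_female)
    if (any(vapply(metas, is.null, logical(1)))) {
      stop_dbmcov("Component selection requires metadata (or pass `components`).",
                  "dbmcov_overlap_error")
    }
    components <- vapply(names(fits), function(nm) {
      select_group_component(fits[[nm]], metas[[nm]])
    }, integer(1))
  } else if (!all(c("all", "male", "female") %in% names(components))) {
    stop_dbmcov("`components` must name all, male and female entries.",
                "dbmcov_overlap_error")
  }
  sets <- lapply(names(fits), function(nm) binarize(fits[[nm]], components[[nm]]))
  names(sets) <- names(fits)
  pairs <- list(c("all", "male"), c("all", "female"), c("male", "female"))
  purrr::map_dfr(pairs, function(pr) {
    d <- dice_kappa(sets[[pr[1]]], sets[[pr[2]]])
    tibble::tibble(
      comparison = paste(pr, collapse = "_vs_"),
      component_1 = as.integer(components[[pr[1]]]),
      component_2 = as.integer(components[[pr[2]]]),
      a = d$a, b = d$b, c = d$c, kappa = d$kappa
    )
  })
}
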