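# Fixtures shared across test files; everything is generated in code.

# Exact low-rank matrix with k0 orthogonal (disjoint-support) non-negative
# components; noise = 0 gives the analytic oracle case.
make_block_matrix <- function(m = 120, n = 30, k0 = 3, noise = 0, seed = 1) {
  set.seed(seed)
  W0 <- matrix(0, m, k0)
  blocks <- split(seq_len(m), rep(seq_len(k0), length.out = m))
  for (c in seq_len(k0)) W0[blocks[[c]], c] <- runif(length(blocks[[c]]), 0.5, 1)
  H0 <- matrix(rexp(k0 * n), k0, n)
  X <- W0 %*% H0
  if (noise > 0) X <- pmax(X + matrix(rnorm(m * n, 0, noise), m, n), 0)
  list(X = X, W0 = W0, H0 = H0, blocks = blocks)
}

# Balanced longitudinal metadata: n_subj subjects x 4 timepoints, half PFF,
# sexes alternating.
make_meta <- function(n_subj = 24, tps = c(-7, 30, 90, 120)) {
  stopifnot(n_subj %% 4 == 0)
  meta <- tidyr::expand_grid(subject_id = sprintf("s%02d", seq_len(n_subj)),
                             dpi = tps)
  per <- length(tps)
  meta$group <- rep(rep(c("PBS", "PFF"), each = per), n_subj / 2)
  meta$sex <- rep(rep(c("F", "M"), each = 2 * per), n_subj / 4)
  meta
}

# Independent brute-force Benjamini-Hochberg step-up: find the largest i
# with p_(i) <= i*q/m; reject all p <= that threshold.
bh_bruteforce <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thr <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(thr) > 0) rej[p <= ps[max(thr)]] <- TRUE
  rej
}

# Brute-force optimal assignment by enumeration of all k! pairings.
assignment_bruteforce <- function(sim) {
  k <- nrow(sim)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL
  best_val <- -Inf
  for (pm in perms(seq_len(k))) {
    val <- sum(sim[cbind(seq_len(k), pm)])
    if (val > best_val) {
      best_val <- val
      best <- pm
    }
  }
  list(assignment = best, total = best_val)
}

# A tiny complete synthetic study used by several test files.
tiny_study <- function(seed = 11, n_per_cell = 3, grid = 14, k0 = 2) {
  spec <- cohort_spec(n_per_cell = n_per_cell, grid_shape = rep(grid, 3),
                      seed = seed)
  truth <- default_ground_truth(spec, k0 = k0)
  list(spec = spec, truth = truth,
       cohort = generate_cohort(spec, truth))
}
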