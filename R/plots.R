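# autoplot methods for the remaining result types.

#' Plot subject weights of a decomposition
#'
#' Boxplots of subject weights per component, split by injection group and
#' sex when metadata is supplied — the visual counterpart of the post-hoc
#' subject-weight GLMs.
#'
#' @param object An `opnmf_fit`.
#' @param meta Optional per-column metadata with `group` and `sex`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.opnmf_fit <- function(object, meta = NULL, ...) {
  td <- tidy(object)
  if (!is.null(meta)) {
    meta <- prepare_meta(meta)
    td$group <- rep(meta$group, times = object$k)
    td$sex <- rep(meta$sex, times = object$k)
    p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$group, y = .data$weight,
                                          fill = .data$sex))
  } else {
    p <- ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$component),
                                          y = .data$weight))
  }
  p + ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~component, labeller = ggplot2::label_both) +
    ggplot2::labs(y = "subject weight",
                  title = "Subject weights by spatial component") +
    ggplot2::theme_minimal()
}

#' Plot a voxel-wise statistic map
#'
#' Mid-axial slice of the t-statistic map when the voxel-grid bookkeeping
#' is available, otherwise a histogram of the statistics, with FDR-passing
#' voxels marked.
#'
#' @param object A [fdr_map()] result.
#' @param slice Axial slice index (default: middle of the grid).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.voxel_stat_map <- function(object, slice = NULL, ...) {
  grid_shape <- attr(object, "grid_shape")
  voxel_index <- attr(object, "voxel_index")
  term <- attr(object, "term")
  if (is.null(grid_shape) || is.null(voxel_index)) {
    return(
      ggplot2::ggplot(object, ggplot2::aes(x = .data$statistic,
                                           fill = .data$significant)) +
        ggplot2::geom_histogram(bins = 40) +
        ggplot2::labs(x = "t statistic", title = term) +
        ggplot2::theme_minimal()
    )
  }
  if (is.null(slice)) slice <- ceiling(grid_shape[3] / 2)
  ijk <- arrayInd(voxel_index, grid_shape)
  keep <- ijk[, 3] == slice
  df <- tibble::tibble(x = ijk[keep, 1], y = ijk[keep, 2],
                       t = object$statistic[keep],
                       significant = object$significant[keep])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$t)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$significant, ], shape = ".", color = "black") +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s (axial slice %d)", term, slice),
                  fill = "t") +
    ggplot2::theme_minimal()
}
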