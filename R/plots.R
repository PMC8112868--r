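#' Plot helpers
#'
#' Thin ggplot2 wrappers over the tabular outputs; every figure is backed by
#' a table the pipeline also writes, so plots are reproducible from
#' artifacts.
#'
#' @param mds result of [mds_samples()].
#' @param color optional vector of per-sample annotations.
#' @return a ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @export
plot_mds <- function(mds, color = NULL) {
  df <- as.data.frame(mds$coords)
  df$sample <- rownames(df)
  if (!is.null(color)) df$color <- color
  p <- ggplot2::ggplot(df, ggplot2::aes(x = MDS1, y = MDS2)) +
    ggplot2::geom_point(if (!is.null(color))
      ggplot2::aes(color = color) else NULL, size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = sample), vjust = -1,
                       size = 3) +
    ggplot2::theme_minimal()
  p
}

#' @rdname plots
#' @param overlay result of [feature_overlay()].
#' @export
plot_embedding <- function(overlay) {
  ggplot2::ggplot(overlay, ggplot2::aes(x = x, y = y,
                                        color = value)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param elbow result of [elbow_data()].
#' @export
plot_elbow <- function(elbow) {
  ggplot2::ggplot(elbow, ggplot2::aes(x = K, y = delta)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = "relative change in consensus CDF area") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param vd result of [volcano_data()].
#' @export
plot_volcano <- function(vd) {
  ggplot2::ggplot(vd, ggplot2::aes(x = log2fc, y = neg_log10_fdr,
                                   color = significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "red")) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param ab an `AbundanceTable`.
#' @param samples sample table with a grouping column.
#' @param group_col grouping column name.
#' @export
plot_abundance_box <- function(ab, samples, group_col) {
  props <- ab$proportions
  df <- data.frame(
    sample = rep(rownames(props), ncol(props)),
    population = rep(colnames(props), each = nrow(props)),
    proportion = as.vector(props))
  df$group <- samples[[group_col]][match(df$sample, samples$sample_id)]
  ggplot2::ggplot(df, ggplot2::aes(x = population,
                                   y = proportion,
                                   fill = group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

utils::globalVariables(c("MDS1", "MDS2", "K", "delta", "x", "y", "value",
                         "log2fc", "neg_log10_fdr", "significant",
                         "population", "proportion", "group"))
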