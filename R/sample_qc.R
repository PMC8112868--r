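#' Per-sample median marker expression
#'
#' Stage-1 QC summary: the median of each transformed marker over the cells
#' of each sample. Feeds the sample MDS plot and the sample heatmap, both of
#' which are used to spot batch effects and staining anomalies.
#'
#' @param exp an [Experiment].
#' @param which marker set: `"all"`, `"clustering"` or `"reduction"` flags.
#' @return numeric matrix samples x markers (rownames = sample ids).
#' @export
per_sample_medians <- function(exp, which = "all") {
  m <- marker_matrix(exp, which)
  sample_ids <- exp@samples$sample_id
  have <- vapply(sample_ids, function(s) any(exp@cell_sample == s), TRUE)
  if (any(!have)) {
    cs_warn(sprintf("samples with zero cells excluded from medians: %s",
                    paste(sample_ids[!have], collapse = ", ")))
    sample_ids <- sample_ids[have]
  }
  out <- t(vapply(sample_ids, function(s) {
    apply(m[exp@cell_sample == s, , drop = FALSE], 2, median)
  }, numeric(ncol(m))))
  rownames(out) <- sample_ids
  colnames(out) <- colnames(m)
  out
}

#' Classical multidimensional scaling of samples
#'
#' Principal-coordinates analysis of the Euclidean distances between
#' per-sample median profiles: double-centre `B = -1/2 J D^2 J`, take the top
#' eigenpairs, scale eigenvectors by the square root of their eigenvalues.
#' Axes are ordered by decreasing eigenvalue and sign-fixed so that each
#' axis' largest-magnitude coordinate is positive, making runs reproducible.
#' Negative eigenvalues (non-Euclidean input) are truncated to zero with a
#' warning, following common PCoA practice.
#'
#' @param medians samples x markers matrix (from [per_sample_medians()]) or
#'   anything coercible to a numeric matrix.
#' @param n_dim number of output dimensions (< number of samples).
#' @return list with `coords` (samples x n_dim) and `eigenvalues`.
#' @export
mds_samples <- function(medians, n_dim = 2) {
  x <- as.matrix(medians)
  n <- nrow(x)
  if (n < 3) {
    cs_stop("mds_samples requires at least 3 samples", "value_error")
  }
  if (n_dim >= n) {
    cs_stop("n_dim must be smaller than the number of samples", "value_error")
  }
  d2 <- as.matrix(dist(x))^2
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% d2 %*% j
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  ev <- eg$values
  if (any(ev < -1e-8 * max(abs(ev)))) {
    cs_warn("negative eigenvalues truncated to zero (non-Euclidean distances)")
  }
  ev[ev < 0] <- 0
  coords <- eg$vectors[, seq_len(n_dim), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_dim)]), n_dim)
  for (j2 in seq_len(n_dim)) {
    i_max <- which.max(abs(coords[, j2]))
    if (coords[i_max, j2] < 0) coords[, j2] <- -coords[, j2]
  }
  rownames(coords) <- rownames(x)
  colnames(coords) <- paste0("MDS", seq_len(n_dim))
  list(coords = coords, eigenvalues = ev)
}

#' Sample-level expression heatmap data
#'
#' Optional per-marker scaling, hierarchical clustering orders (Euclidean,
#' average linkage) and sample-metadata annotation tracks; returns the data
#' behind the rendered figure so plots are reproducible from artifacts.
#'
#' @param medians samples x markers matrix.
#' @param scale `"none"`, `"zero_one"` (per-marker min-max) or `"zscore"`.
#' @param cluster_rows,cluster_cols hierarchically order rows/columns?
#' @param annotations optional data.frame of sample annotations or an
#'   [Experiment]/sample table to pull columns from.
#' @param annotation_cols which annotation columns to join.
#' @param plot if `TRUE`, render with \pkg{pheatmap}.
#' @param filename optional output image path (png/pdf), implies `plot`.
#' @return list with `matrix` (scaled), `row_order`, `col_order`,
#'   `annotations`.
#' @export
sample_heatmap <- function(medians, scale = c("none", "zero_one", "zscore"),
                           cluster_rows = TRUE, cluster_cols = TRUE,
                           annotations = NULL, annotation_cols = NULL,
                           plot = FALSE, filename = NULL) {
  scale <- match.arg(scale)
  m <- as.matrix(medians)
  sm <- switch(scale,
    none = m,
    zero_one = apply(m, 2, function(v) {
      r <- range(v)
      if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
    }),
    zscore = base::scale(m)
  )
  sm <- matrix(as.numeric(sm), nrow(m), ncol(m),
               dimnames = dimnames(m))
  row_order <- seq_len(nrow(sm))
  col_order <- seq_len(ncol(sm))
  if (cluster_rows && nrow(sm) > 1) {
    row_order <- hclust(dist(sm), method = "average")$order
  }
  if (cluster_cols && ncol(sm) > 1) {
    col_order <- hclust(dist(t(sm)), method = "average")$order
  }
  ann <- NULL
  if (!is.null(annotations)) {
    tbl <- if (is(annotations, "Experiment")) annotations@samples else
      as.data.frame(annotations)
    if (!is.null(annotation_cols)) {
      miss <- setdiff(annotation_cols, names(tbl))
      if (length(miss)) {
        cs_stop(sprintf("metadata error: unknown annotation column(s): %s",
                        paste(miss, collapse = ", ")), "metadata_error")
      }
      tbl <- tbl[, c("sample_id", annotation_cols), drop = FALSE]
    }
    rn <- tbl$sample_id %||% rownames(tbl)
    ann <- tbl[match(rownames(sm), rn), setdiff(names(tbl), "sample_id"),
               drop = FALSE]
    rownames(ann) <- rownames(sm)
  }
  if (plot || !is.null(filename)) {
    pheatmap::pheatmap(sm, cluster_rows = cluster_rows,
                       cluster_cols = cluster_cols,
                       annotation_row = ann,
                       filename = filename %||% NA, silent = !is.null(filename))
  }
  list(matrix = sm, row_order = row_order, col_order = col_order,
       annotations = ann)
}
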