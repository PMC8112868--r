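#' Per-cluster median marker expression
#'
#' Median of each transformed marker within each cluster (or named cell-type
#' label); the data behind cluster identification heatmaps.
#'
#' @param exp an [Experiment].
#' @param clustering clustering layer name (with `k`), or `NULL` when
#'   `labels` is given.
#' @param k number of metaclusters K to pull labels for.
#' @param labels alternatively, a `cell_labels` layer name or a per-cell
#'   label vector.
#' @param scale `"none"` or `"zero_one"` (each marker column rescaled to
#'   `[0, 1]` across clusters).
#' @param which marker set passed to [marker_matrix()].
#' @return numeric matrix clusters x markers; empty clusters give NA rows
#'   with a warning.
#' @export
cluster_medians <- function(exp, clustering = NULL, k = NULL, labels = NULL,
                            scale = c("none", "zero_one"), which = "all") {
  scale <- match.arg(scale)
  lab <- resolve_labels(exp, clustering, k, labels)
  m <- marker_matrix(exp, which)
  lev <- if (is.numeric(lab)) sort(unique(lab)) else sort(unique(as.character(lab)))
  if (!is.null(k)) lev <- seq_len(k)
  out <- matrix(NA_real_, length(lev), ncol(m),
                dimnames = list(as.character(lev), colnames(m)))
  for (i in seq_along(lev)) {
    sel <- lab == lev[i]
    if (!any(sel)) next
    out[i, ] <- apply(m[sel, , drop = FALSE], 2, median)
  }
  empty <- rownames(out)[apply(out, 1, function(r) all(is.na(r)))]
  if (length(empty)) {
    cs_warn(sprintf("empty cluster(s) give NA rows: %s",
                    paste(empty, collapse = ", ")))
  }
  if (scale == "zero_one") {
    out <- apply(out, 2, function(v) {
      r <- range(v, na.rm = TRUE)
      if (diff(r) == 0) return(rep(0, length(v)))
      (v - r[1]) / diff(r)
    })
  }
  out
}

resolve_labels <- function(exp, clustering = NULL, k = NULL, labels = NULL) {
  if (!is.null(labels)) {
    if (length(labels) == 1 && is.character(labels)) {
      if (!labels %in% names(exp@cell_labels)) {
        cs_stop(sprintf("no cell_labels layer '%s'", labels), "state_error")
      }
      return(exp@cell_labels[[labels]])
    }
    if (length(labels) != n_cells(exp)) {
      cs_stop("label vector must have one entry per cell", "alignment_error")
    }
    return(labels)
  }
  if (is.null(clustering) || is.null(k)) {
    cs_stop("supply either a labels layer/vector or clustering + k",
            "value_error")
  }
  cluster_labels(exp, clustering, k)
}

#' Ranked-expression table (IMC rank heatmap)
#'
#' For each marker independently, clusters are ranked ascending by median
#' expression (1 = lowest, n_clusters = highest); ties receive the average
#' (mid) rank. Designed for lower-resolution IMC data, where the ordering of
#' clusters per marker is more trustworthy than the raw medians; ranks are
#' invariant under any strictly monotone per-marker transform.
#'
#' @param medians clusters x markers matrix from [cluster_medians()].
#' @return rank matrix of the same shape (integer or half-integer on ties).
#' @export
imc_rank <- function(medians) {
  m <- as.matrix(medians)
  if (nrow(m) < 2) {
    cs_stop("imc_rank needs at least 2 clusters to rank", "value_error")
  }
  out <- apply(m, 2, function(v) rank(v, ties.method = "average",
                                      na.last = "keep"))
  dimnames(out) <- dimnames(m)
  out
}

#' Merge clusters into named cell types, reproducibly
#'
#' Table-driven collapsing of an over-clustered K into biological cell
#' types. The original integer labels are retained untouched; the merge
#' table (with the clustering name and K) is stored in provenance so the
#' annotation is versionable and the merge can be undone exactly. Applying a
#' second table on top supports higher-level population annotation.
#'
#' @param exp an [Experiment].
#' @param clustering clustering layer name.
#' @param k the K whose labels the table refers to.
#' @param merge two-column data.frame (`cluster`, `cell_type`) or a named
#'   character vector `cluster -> cell_type`; must cover every cluster
#'   present at K exactly once, names nonempty.
#' @param name name of the new `cell_labels` layer.
#' @return the [Experiment] with `cell_labels[[name]]` added.
#' @export
merge_clusters <- function(exp, clustering, k, merge, name = "cell_type") {
  lab <- cluster_labels(exp, clustering, k)
  if (is.data.frame(merge)) {
    if (!all(c("cluster", "cell_type") %in% names(merge))) {
      cs_stop("merge table needs 'cluster' and 'cell_type' columns",
              "value_error")
    }
    map <- setNames(as.character(merge$cell_type), as.character(merge$cluster))
  } else {
    map <- setNames(as.character(merge), names(merge))
  }
  if (anyDuplicated(names(map))) {
    cs_stop("merge table lists a cluster more than once", "value_error")
  }
  if (any(!nzchar(map))) {
    cs_stop("cell-type names must be nonempty", "value_error")
  }
  present <- sort(unique(lab))
  missing <- setdiff(as.character(present), names(map))
  if (length(missing)) {
    cs_stop(sprintf(
      "completeness error: merge table missing cluster(s): %s",
      paste(missing, collapse = ", ")), "completeness_error")
  }
  exp@cell_labels[[name]] <- unname(map[as.character(lab)])
  add_provenance(exp, "merge_clusters",
                 list(clustering = clustering, k = k, layer = name,
                      merge_table = as.list(map)))
}

#' Undo a table-driven merge using stored provenance
#'
#' @param exp an [Experiment].
#' @param name the `cell_labels` layer created by [merge_clusters()].
#' @return the original integer labels the merge was built from.
#' @export
unmerge_clusters <- function(exp, name = "cell_type") {
  recs <- Filter(function(r) r$command == "merge_clusters" &&
                   identical(r$params$layer, name), exp@provenance)
  if (!length(recs)) {
    cs_stop(sprintf("no merge_clusters provenance for layer '%s'", name),
            "state_error")
  }
  rec <- recs[[length(recs)]]
  cluster_labels(exp, rec$params$clustering, rec$params$k)
}

#' Biaxial plot data: two markers with density contours
#'
#' Transformed expression of two markers over a cell subset, with 2-D
#' Gaussian-KDE contour polylines at the stated density quantiles -- the
#' data behind a manual-gating-style biaxial dot plot.
#'
#' @param exp an [Experiment].
#' @param marker_x,marker_y marker names (or channel ids).
#' @param cells,samples,labels,label_layer optional subset filters passed to
#'   [subset_experiment()].
#' @param levels density quantile levels for the contours.
#' @return list with `points` (data.frame x, y, sample), `contours`
#'   (list of polyline data.frames with a `level` column) and `levels`.
#' @export
biaxial_data <- function(exp, marker_x, marker_y, cells = NULL,
                         samples = NULL, labels = NULL, label_layer = NULL,
                         levels = c(0.25, 0.5, 0.75, 0.9)) {
  if (!is.null(cells) || !is.null(samples) || !is.null(labels)) {
    exp <- subset_experiment(exp, cells = cells, samples = samples,
                             labels = labels, label_layer = label_layer)
  }
  ix <- match_marker(exp, marker_x)
  iy <- match_marker(exp, marker_y)
  pts <- data.frame(x = exp@transformed[, ix], y = exp@transformed[, iy],
                    sample = exp@cell_sample)
  contours <- list()
  if (nrow(pts) >= 10 && sd(pts$x) > 0 && sd(pts$y) > 0) {
    k2 <- MASS::kde2d(pts$x, pts$y, n = 64)
    lv <- quantile(k2$z[k2$z > 0], probs = levels)
    cl <- grDevices::contourLines(k2$x, k2$y, k2$z, levels = lv)
    contours <- lapply(cl, function(c1) {
      data.frame(x = c1$x, y = c1$y, level = c1$level)
    })
  }
  list(points = pts, contours = contours, levels = levels)
}

match_marker <- function(exp, marker) {
  i <- match(marker, exp@panel$marker_name)
  if (is.na(i)) i <- match(marker, exp@panel$channel_id)
  if (is.na(i)) {
    cs_stop(sprintf("panel error: unknown marker '%s'", marker), "panel_error")
  }
  i
}

#' Per-cell overlay values aligned to an embedding
#'
#' Values (marker expression, a metadata column, or a label layer) for the
#' cells present in a stored reduction, for coloring embedding scatter
#' plots. Cells without coordinates (dropped by embedding-stage
#' downsampling) are excluded.
#'
#' @param exp an [Experiment].
#' @param reduction reduction layer name.
#' @param feature a marker name, a sample-metadata column, a `cell_labels`
#'   layer name, or `"sample"`.
#' @return data.frame with `x`, `y`, `value` (one row per embedded cell).
#' @export
feature_overlay <- function(exp, reduction, feature) {
  if (!reduction %in% names(exp@reductions)) {
    cs_stop(sprintf("no reduction layer '%s'", reduction), "state_error")
  }
  coords <- exp@reductions[[reduction]]
  value <- if (feature %in% c(exp@panel$marker_name, exp@panel$channel_id)) {
    exp@transformed[, match_marker(exp, feature)]
  } else if (identical(feature, "sample")) {
    exp@cell_sample
  } else if (feature %in% names(exp@cell_labels)) {
    exp@cell_labels[[feature]]
  } else if (feature %in% names(exp@samples)) {
    vals <- exp@samples[[feature]]
    vals[match(exp@cell_sample, exp@samples$sample_id)]
  } else if (feature %in% names(exp@cell_meta)) {
    exp@cell_meta[[feature]]
  } else {
    cs_stop(sprintf("unknown overlay feature '%s'", feature), "value_error")
  }
  ok <- stats::complete.cases(coords)
  data.frame(x = coords[ok, 1], y = coords[ok, 2], value = value[ok])
}
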