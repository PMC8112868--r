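#' The Experiment container
#'
#' Central data container for a cytometry analysis, mirroring the layered
#' single-cell container design used across the field: a raw and a transformed
#' cells x channels assay, a per-cell sample map, panel metadata with
#' use-flags, sample metadata, and named layers of 2-D reductions, clusterings
#' and per-cell text labels. Cells are rows (cells x markers orientation).
#'
#' @slot raw numeric matrix, cells x channels, untransformed intensities.
#' @slot transformed numeric matrix, same shape as `raw`; equal to `raw` until
#'   a transform is applied.
#' @slot cell_sample character vector, sample id per cell.
#' @slot panel data.frame with columns `channel_id`, `marker_name`, `role`,
#'   `use_clustering`, `use_reduction` (see [create_panel()]).
#' @slot samples data.frame of sample metadata, one row per sample, with a
#'   `sample_id` column (see [create_sample_table()]).
#' @slot cell_meta data.frame of per-cell provenance/metadata (source file,
#'   original row, ...); zero columns allowed.
#' @slot reductions named list of cells x 2 coordinate matrices (NA rows for
#'   cells dropped by embedding-stage downsampling).
#' @slot clusterings named list of `ClusterAssignments` (see [cluster_assignments()]) objects.
#' @slot cell_labels named list of character vectors (one label per cell).
#' @slot provenance list of records appended by pipeline operations.
#'
#' @name Experiment-class
#' @aliases Experiment
#' @export
setClass("Experiment", representation(
  raw         = "matrix",
  transformed = "matrix",
  cell_sample = "character",
  panel       = "data.frame",
  samples     = "data.frame",
  cell_meta   = "data.frame",
  reductions  = "list",
  clusterings = "list",
  cell_labels = "list",
  provenance  = "list"
))

setValidity("Experiment", function(object) {
  n <- nrow(object@raw)
  p <- ncol(object@raw)
  if (!all(dim(object@transformed) == c(n, p))) {
    return("raw and transformed assays must have identical shape")
  }
  if (length(object@cell_sample) != n) {
    return("cell_sample must have one entry per cell")
  }
  if (nrow(object@panel) != p) {
    return("panel must have one row per channel")
  }
  if (!all(object@cell_sample %in% object@samples$sample_id)) {
    return("every cell_sample value must exist in the sample table")
  }
  for (nm in names(object@reductions)) {
    if (nrow(object@reductions[[nm]]) != n) {
      return(sprintf("reduction '%s' is not aligned to cells", nm))
    }
  }
  for (nm in names(object@cell_labels)) {
    if (length(object@cell_labels[[nm]]) != n) {
      return(sprintf("cell_labels layer '%s' is not aligned to cells", nm))
    }
  }
  TRUE
})

#' Build a panel metadata table
#'
#' @param channel_id character, unique FCS `$PnN` channel identifiers.
#' @param marker_name display names; defaults to `channel_id`.
#' @param role one of `"lineage"`, `"functional"`, `"none"` per channel.
#' @param use_clustering,use_reduction logical use-flags per channel.
#' @return a validated panel `data.frame`.
#' @export
create_panel <- function(channel_id,
                         marker_name = channel_id,
                         role = "none",
                         use_clustering = TRUE,
                         use_reduction = use_clustering) {
  channel_id <- as.character(channel_id)
  if (anyDuplicated(channel_id)) {
    cs_stop("panel channel_id values must be unique", "panel_error")
  }
  role <- rep_len(as.character(role), length(channel_id))
  bad <- setdiff(unique(role), c("lineage", "functional", "none"))
  if (length(bad)) {
    cs_stop(sprintf("unknown panel role(s): %s", paste(bad, collapse = ", ")),
            "panel_error")
  }
  data.frame(
    channel_id     = channel_id,
    marker_name    = rep_len(as.character(marker_name), length(channel_id)),
    role           = role,
    use_clustering = rep_len(as.logical(use_clustering), length(channel_id)),
    use_reduction  = rep_len(as.logical(use_reduction), length(channel_id)),
    stringsAsFactors = FALSE
  )
}

#' Build a sample metadata table
#'
#' @param sample_id unique sample identifiers.
#' @param ... named covariate vectors (condition, timepoint, ...), each of
#'   length `length(sample_id)`.
#' @return a `data.frame` with `sample_id` first.
#' @export
create_sample_table <- function(sample_id, ...) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    cs_stop("sample_id values must be unique", "metadata_error")
  }
  covs <- list(...)
  if (length(covs)) {
    lens <- vapply(covs, length, 1L)
    if (any(lens != length(sample_id))) {
      cs_stop("every covariate must have one value per sample", "metadata_error")
    }
  }
  do.call(data.frame,
          c(list(sample_id = sample_id, stringsAsFactors = FALSE), covs))
}

#' Construct an Experiment
#'
#' @param raw numeric cells x channels matrix.
#' @param cell_sample sample id per cell (row of `raw`).
#' @param panel panel metadata from [create_panel()]; `panel$channel_id` must
#'   match `colnames(raw)` in count (column names are set from the panel).
#' @param samples sample table from [create_sample_table()].
#' @param cell_meta optional per-cell metadata data.frame.
#' @return an [Experiment] with `transformed` initialised equal to `raw` and
#'   empty reduction/clustering/label layers.
#' @export
build_experiment <- function(raw, cell_sample, panel, samples,
                             cell_meta = NULL) {
  raw <- as.matrix(raw)
  storage.mode(raw) <- "double"
  cell_sample <- as.character(cell_sample)
  if (ncol(raw) != nrow(panel)) {
    cs_stop(sprintf(
      "alignment error: raw has %d channels (columns) but panel describes %d",
      ncol(raw), nrow(panel)), "alignment_error")
  }
  if (nrow(raw) != length(cell_sample)) {
    cs_stop(sprintf(
      "alignment error: raw has %d cells (rows) but cell_sample has %d entries",
      nrow(raw), length(cell_sample)), "alignment_error")
  }
  unknown <- setdiff(unique(cell_sample), samples$sample_id)
  if (length(unknown)) {
    cs_stop(sprintf("metadata error: cell_sample ids not in sample table: %s",
                    paste(unknown, collapse = ", ")), "metadata_error")
  }
  colnames(raw) <- panel$channel_id
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = seq_len(nrow(raw)))
  }
  if (nrow(cell_meta) != nrow(raw)) {
    cs_stop("alignment error: cell_meta rows must match cells", "alignment_error")
  }
  new("Experiment",
      raw = raw, transformed = raw, cell_sample = cell_sample,
      panel = panel, samples = samples, cell_meta = cell_meta,
      reductions = list(), clusterings = list(), cell_labels = list(),
      provenance = list())
}

#' @export
setMethod("show", "Experiment", function(object) {
  cat(sprintf("Experiment: %d cells x %d channels, %d samples\n",
              nrow(object@raw), ncol(object@raw), nrow(object@samples)))
  if (length(object@reductions)) {
    cat("  reductions: ", paste(names(object@reductions), collapse = ", "), "\n")
  }
  if (length(object@clusterings)) {
    cat("  clusterings:", paste(names(object@clusterings), collapse = ", "), "\n")
  }
  if (length(object@cell_labels)) {
    cat("  labels:     ", paste(names(object@cell_labels), collapse = ", "), "\n")
  }
})

#' Number of cells / channels in an Experiment
#' @param exp an [Experiment].
#' @return integer count.
#' @export
n_cells <- function(exp) nrow(exp@raw)

#' @rdname n_cells
#' @export
n_channels <- function(exp) ncol(exp@raw)

#' Subset an Experiment by cells
#'
#' All per-cell layers (assays, reductions, cluster labels, text labels,
#' cell metadata) are subset consistently; panel and sample table are kept.
#'
#' @param exp an [Experiment].
#' @param cells logical mask of length `n_cells(exp)`, or integer indices.
#' @param samples character sample ids to keep.
#' @param labels character label values to keep from `label_layer`.
#' @param label_layer which `cell_labels` layer `labels` refers to; defaults
#'   to the first layer.
#' @return the subset [Experiment].
#' @export
subset_experiment <- function(exp, cells = NULL, samples = NULL,
                              labels = NULL, label_layer = NULL) {
  n <- n_cells(exp)
  keep <- rep(TRUE, n)
  if (!is.null(cells)) {
    if (is.logical(cells)) {
      if (length(cells) != n) {
        cs_stop("alignment error: logical cell mask must have one entry per cell",
                "alignment_error")
      }
      keep <- keep & cells
    } else {
      keep <- keep & (seq_len(n) %in% cells)
    }
  }
  if (!is.null(samples)) {
    unknown <- setdiff(samples, exp@samples$sample_id)
    if (length(unknown)) {
      cs_stop(sprintf("metadata error: unknown sample id(s): %s",
                      paste(unknown, collapse = ", ")), "metadata_error")
    }
    keep <- keep & (exp@cell_sample %in% samples)
  }
  if (!is.null(labels)) {
    if (!length(exp@cell_labels)) {
      cs_stop("no cell_labels layer present in experiment", "state_error")
    }
    if (is.null(label_layer)) label_layer <- names(exp@cell_labels)[1]
    if (!label_layer %in% names(exp@cell_labels)) {
      cs_stop(sprintf("no cell_labels layer '%s'", label_layer), "state_error")
    }
    keep <- keep & (exp@cell_labels[[label_layer]] %in% labels)
  }
  if (!any(keep)) {
    cs_stop("empty selection: no cells match the requested subset",
            "empty_selection_error")
  }
  idx <- which(keep)
  out <- exp
  out@raw <- exp@raw[idx, , drop = FALSE]
  out@transformed <- exp@transformed[idx, , drop = FALSE]
  out@cell_sample <- exp@cell_sample[idx]
  out@cell_meta <- exp@cell_meta[idx, , drop = FALSE]
  out@reductions <- lapply(exp@reductions, function(m) m[idx, , drop = FALSE])
  out@cell_labels <- lapply(exp@cell_labels, function(v) v[idx])
  out@clusterings <- lapply(exp@clusterings, function(ca) {
    ca$labels_by_k <- lapply(ca$labels_by_k, function(v) v[idx])
    if (!is.null(ca$node_of_cell)) ca$node_of_cell <- ca$node_of_cell[idx]
    ca
  })
  out
}

#' Extract the marker matrix for a given analysis stage
#'
#' Returns the transformed assay restricted to the channels flagged for the
#' requested use, in panel order.
#'
#' @param exp an [Experiment].
#' @param which `"clustering"` (use_clustering flags), `"reduction"`
#'   (use_reduction flags) or `"all"`.
#' @return numeric matrix with `marker_name` column names.
#' @export
marker_matrix <- function(exp, which = c("clustering", "reduction", "all")) {
  which <- match.arg(which)
  sel <- switch(which,
    clustering = exp@panel$use_clustering,
    reduction  = exp@panel$use_reduction,
    all        = rep(TRUE, nrow(exp@panel))
  )
  if (!any(sel)) {
    cs_stop(sprintf("configuration error: no panel channels flagged for '%s'",
                    which), "configuration_error")
  }
  m <- exp@transformed[, sel, drop = FALSE]
  colnames(m) <- exp@panel$marker_name[sel]
  m
}

#' A set of cluster assignments over a range of K
#'
#' Plain list with class `ClusterAssignments`: fields `algorithm` (one of
#' `som_consensus`, `graph_community`, `kmeans`), `params` (list),
#' `labels_by_k` (named list, key `"K"` -> integer labels in `1..K`, ordered
#' by decreasing cluster size), optional `node_of_cell` (SOM node per cell)
#' and optional `model` (SOM codes / consensus results).
#'
#' @param algorithm,params,labels_by_k,node_of_cell,model see description.
#' @return a `ClusterAssignments` object.
#' @export
cluster_assignments <- function(algorithm, params, labels_by_k,
                                node_of_cell = NULL, model = NULL) {
  algorithm <- match.arg(algorithm,
                         c("som_consensus", "graph_community", "kmeans"))
  for (k in names(labels_by_k)) {
    lab <- labels_by_k[[k]]
    kk <- as.integer(k)
    if (any(!is.na(lab) & (lab < 1L | lab > kk))) {
      cs_stop(sprintf("labels for K=%s outside 1..%s", k, k), "label_error")
    }
  }
  structure(list(algorithm = algorithm, params = params,
                 labels_by_k = labels_by_k, node_of_cell = node_of_cell,
                 model = model),
            class = "ClusterAssignments")
}

#' Fetch stored cluster labels for a given K
#' @param exp an [Experiment].
#' @param name clustering layer name.
#' @param k number of metaclusters K.
#' @return integer label vector (one per cell).
#' @export
cluster_labels <- function(exp, name, k) {
  if (!name %in% names(exp@clusterings)) {
    cs_stop(sprintf("no clustering layer '%s'", name), "state_error")
  }
  lk <- exp@clusterings[[name]]$labels_by_k
  key <- as.character(k)
  if (!key %in% names(lk)) {
    cs_stop(sprintf("clustering '%s' has no labels for K=%s (stored: %s)",
                    name, k, paste(names(lk), collapse = ",")), "state_error")
  }
  lk[[key]]
}

# relabel integer labels 1..K by decreasing cluster size (stable names on rerun)
relabel_by_size <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- setNames(seq_along(tab), names(tab))
  as.integer(map[as.character(labels)])
}

#' Content checksum of an Experiment
#'
#' md5 digest of the canonical serialized content of the container, with
#' provenance timestamps stripped, so identical command sequences with
#' identical seeds give identical checksums.
#'
#' @param exp an [Experiment].
#' @return a character md5 checksum.
#' @export
experiment_checksum <- function(exp) {
  prov <- lapply(exp@provenance, function(rec) {
    rec$timestamp <- NULL
    rec
  })
  content <- list(
    raw = exp@raw, transformed = exp@transformed,
    cell_sample = exp@cell_sample, panel = exp@panel, samples = exp@samples,
    cell_meta = exp@cell_meta, reductions = exp@reductions,
    clusterings = exp@clusterings, cell_labels = exp@cell_labels,
    provenance = prov
  )
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(content, con, version = 3, xdr = TRUE)
  close(con)
  unname(tools::md5sum(tf))
}

# append a provenance record (command, params, seed, timestamp)
add_provenance <- function(exp, command, params = list(), seed = NULL) {
  rec <- list(command = command, params = params, seed = seed,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  exp@provenance <- c(exp@provenance, list(rec))
  exp
}
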