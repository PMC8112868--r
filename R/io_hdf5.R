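#' Save / load an Experiment as a single HDF5 container
#'
#' One-file portability for a whole analysis: groups `/assays/{raw,
#' transformed}`, `/cell_sample`, `/cell_meta`, `/sample_meta`, `/panel`,
#' `/reductions/<name>`, `/clusterings/<name>` (labels for every K, node
#' map, SOM codes, consensus matrices, elbow areas), `/cell_labels/<name>`
#' and a JSON `/provenance` log. Loading reconstructs the [Experiment];
#' model sub-objects are restored to the extent they are persisted (codes,
#' consensus matrices, elbow statistics).
#'
#' @param exp an [Experiment].
#' @param path HDF5 file path (overwritten if present).
#' @return `path` (save) or the loaded [Experiment] (load).
#' @export
save_experiment <- function(exp, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  h5w <- function(obj, name) rhdf5::h5write(obj, path, name)
  rhdf5::h5createGroup(path, "assays")
  h5w(exp@raw, "assays/raw")
  h5w(exp@transformed, "assays/transformed")
  h5w(exp@cell_sample, "cell_sample")
  h5w(df_sanitize(exp@samples), "sample_meta")
  h5w(df_sanitize(exp@panel), "panel")
  if (ncol(exp@cell_meta) > 0) h5w(df_sanitize(exp@cell_meta), "cell_meta")
  if (length(exp@reductions)) {
    rhdf5::h5createGroup(path, "reductions")
    for (nm in names(exp@reductions)) {
      h5w(exp@reductions[[nm]], paste0("reductions/", nm))
    }
  }
  if (length(exp@cell_labels)) {
    rhdf5::h5createGroup(path, "cell_labels")
    for (nm in names(exp@cell_labels)) {
      h5w(exp@cell_labels[[nm]], paste0("cell_labels/", nm))
    }
  }
  if (length(exp@clusterings)) {
    rhdf5::h5createGroup(path, "clusterings")
    for (nm in names(exp@clusterings)) {
      ca <- exp@clusterings[[nm]]
      g <- paste0("clusterings/", nm)
      rhdf5::h5createGroup(path, g)
      h5w(ca$algorithm, paste0(g, "/algorithm"))
      h5w(as.character(jsonlite::toJSON(ca$params, auto_unbox = TRUE,
                                        digits = NA)),
          paste0(g, "/params"))
      ks <- as.integer(names(ca$labels_by_k))
      h5w(ks, paste0(g, "/k_values"))
      labmat <- do.call(cbind, ca$labels_by_k)
      h5w(labmat, paste0(g, "/labels"))
      if (!is.null(ca$node_of_cell)) {
        h5w(as.integer(ca$node_of_cell), paste0(g, "/node_of_cell"))
      }
      if (!is.null(ca$model$som$codes)) {
        h5w(ca$model$som$codes, paste0(g, "/codes"))
      }
      if (!is.null(ca$model$centroids)) {
        h5w(ca$model$centroids, paste0(g, "/codes"))
      }
      cr <- ca$model$consensus_result
      if (!is.null(cr)) {
        h5w(unname(cr$area), paste0(g, "/area"))
        h5w(unname(cr$delta), paste0(g, "/delta"))
        rhdf5::h5createGroup(path, paste0(g, "/consensus"))
        for (k in names(cr$consensus)) {
          h5w(cr$consensus[[k]], paste0(g, "/consensus/K", k))
        }
      }
    }
  }
  h5w(as.character(jsonlite::toJSON(exp@provenance, auto_unbox = TRUE,
                                    digits = NA, null = "null")),
      "provenance")
  invisible(path)
}

#' @rdname save_experiment
#' @export
load_experiment <- function(path) {
  if (!file.exists(path)) {
    cs_stop(sprintf("container not found: %s", path), "io_error")
  }
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls0 <- rhdf5::h5ls(path)
  has <- function(name) name %in% paste0(ls0$group, "/", ls0$name) |
    name %in% paste0(sub("^/", "", paste0(ls0$group, "/", ls0$name)))
  h5r <- function(name) rhdf5::h5read(path, name)
  top <- ls0$name[ls0$group == "/"]

  raw <- h5r("assays/raw")
  transformed <- h5r("assays/transformed")
  panel <- df_restore(h5r("panel"))
  panel$use_clustering <- as.logical(panel$use_clustering)
  panel$use_reduction <- as.logical(panel$use_reduction)
  samples <- df_restore(h5r("sample_meta"))
  cell_sample <- as.character(h5r("cell_sample"))
  cell_meta <- if ("cell_meta" %in% top) df_restore(h5r("cell_meta")) else
    data.frame(row.names = seq_len(nrow(raw)))
  colnames(raw) <- panel$channel_id
  colnames(transformed) <- panel$channel_id

  exp <- new("Experiment", raw = raw, transformed = transformed,
             cell_sample = cell_sample, panel = panel, samples = samples,
             cell_meta = cell_meta, reductions = list(),
             clusterings = list(), cell_labels = list(), provenance = list())

  group_children <- function(g) ls0$name[ls0$group == paste0("/", g)]
  if ("reductions" %in% top) {
    for (nm in group_children("reductions")) {
      m <- h5r(paste0("reductions/", nm))
      colnames(m) <- paste0(toupper(nm), 1:2)
      exp@reductions[[nm]] <- m
    }
  }
  if ("cell_labels" %in% top) {
    for (nm in group_children("cell_labels")) {
      exp@cell_labels[[nm]] <- as.character(h5r(paste0("cell_labels/", nm)))
    }
  }
  if ("clusterings" %in% top) {
    for (nm in group_children("clusterings")) {
      g <- paste0("clusterings/", nm)
      kids <- group_children(g)
      ks <- as.integer(h5r(paste0(g, "/k_values")))
      labmat <- h5r(paste0(g, "/labels"))
      labels_by_k <- setNames(
        lapply(seq_along(ks), function(i) as.integer(labmat[, i])),
        as.character(ks))
      model <- list()
      if ("codes" %in% kids) {
        model$som <- list(codes = h5r(paste0(g, "/codes")))
      }
      if ("area" %in% kids) {
        area <- as.numeric(h5r(paste0(g, "/area")))
        delta <- as.numeric(h5r(paste0(g, "/delta")))
        names(area) <- names(delta) <- as.character(ks)
        cons <- list()
        for (kk in group_children(paste0(g, "/consensus"))) {
          cons[[sub("^K", "", kk)]] <- h5r(paste0(g, "/consensus/", kk))
        }
        model$consensus_result <- structure(
          list(labels_by_k = NULL, consensus = cons, area = area,
               delta = delta, never_cosampled = NA, params = list()),
          class = "ConsensusResult")
      }
      exp@clusterings[[nm]] <- structure(list(
        algorithm = as.character(h5r(paste0(g, "/algorithm"))),
        params = jsonlite::fromJSON(as.character(h5r(paste0(g, "/params"))),
                                    simplifyVector = TRUE),
        labels_by_k = labels_by_k,
        node_of_cell = if ("node_of_cell" %in% kids) {
          as.integer(h5r(paste0(g, "/node_of_cell")))
        },
        model = model
      ), class = "ClusterAssignments")
    }
  }
  if ("provenance" %in% top) {
    exp@provenance <- jsonlite::fromJSON(as.character(h5r("provenance")),
                                         simplifyVector = FALSE)
  }
  validObject(exp)
  exp
}

# HDF5 compound datasets round-trip characters/doubles/ints cleanly but not
# logicals/factors/NA strings; normalise before writing
df_sanitize <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cn in names(df)) {
    v <- df[[cn]]
    if (is.logical(v)) v <- as.integer(v)
    if (is.factor(v)) v <- as.character(v)
    if (is.character(v)) v[is.na(v)] <- ""
    df[[cn]] <- v
  }
  df
}

df_restore <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cn in names(df)) {
    v <- df[[cn]]
    if (is.factor(v)) v <- as.character(v)
    df[[cn]] <- as.vector(v)  # strip 1-d array dims added by the HDF5 reader
  }
  df
}
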