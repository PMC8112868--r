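#' UMAP embedding of an Experiment
#'
#' 2-D uniform manifold approximation and projection on the
#' reduction-flagged markers, with optional embedding-stage downsampling
#' (e.g. a 500k total cap for multi-million-cell runs). Cells excluded by
#' downsampling carry `NA` coordinates; cluster labels are computed on all
#' cells independently, so plots simply show the embedded subset. Marker
#' columns are put in a canonical order internally, making the coordinates
#' invariant to panel column permutations. Runs single-threaded with exact
#' nearest neighbors so a fixed seed reproduces coordinates exactly.
#'
#' @param exp an [Experiment].
#' @param ds a [downsample_config()] applied before embedding.
#' @param seed integer seed.
#' @param n_neighbors,min_dist UMAP hyperparameters (defaults 15 / 0.1, the
#'   upstream algorithm defaults; recorded in provenance).
#' @param name reduction layer name.
#' @return the [Experiment] with `reductions[[name]]` filled.
#' @export
run_umap <- function(exp, ds = downsample_config("none"), seed = 42,
                     n_neighbors = 15, min_dist = 0.1, name = "umap") {
  prep <- embed_input(exp, ds)
  if (nrow(prep$m) < n_neighbors + 1) {
    cs_stop(sprintf(
      "too few cells (%d) after downsampling for n_neighbors = %d",
      nrow(prep$m), n_neighbors), "value_error")
  }
  coords_sub <- with_seed(derive_seed(seed, "umap"), {
    uwot::umap(prep$m, n_neighbors = n_neighbors, min_dist = min_dist,
               n_components = 2, nn_method = "fnn", n_threads = 1,
               n_sgd_threads = 0, batch = FALSE, verbose = FALSE)
  })
  exp <- store_reduction(exp, name, coords_sub, prep$kept)
  add_provenance(exp, "run_umap",
                 list(n_neighbors = n_neighbors, min_dist = min_dist,
                      downsample = ds$mode), seed = seed)
}

#' tSNE embedding of an Experiment
#'
#' t-distributed stochastic neighbor embedding with the same downsampling,
#' determinism and column-canonicalisation contract as [run_umap()].
#'
#' @inheritParams run_umap
#' @param perplexity tSNE perplexity; must satisfy
#'   `perplexity < (n_cells - 1) / 3`.
#' @return the [Experiment] with `reductions[[name]]` filled.
#' @export
run_tsne <- function(exp, ds = downsample_config("none"), seed = 42,
                     perplexity = 30, name = "tsne") {
  prep <- embed_input(exp, ds)
  n <- nrow(prep$m)
  if (perplexity >= (n - 1) / 3) {
    cs_stop(sprintf(
      "perplexity (%g) must be below (n_cells - 1) / 3 = %g", perplexity,
      (n - 1) / 3), "value_error")
  }
  coords_sub <- with_seed(derive_seed(seed, "tsne"), {
    Rtsne::Rtsne(prep$m, dims = 2, perplexity = perplexity,
                 check_duplicates = FALSE, pca = FALSE, num_threads = 1,
                 verbose = FALSE)$Y
  })
  exp <- store_reduction(exp, name, coords_sub, prep$kept)
  add_provenance(exp, "run_tsne",
                 list(perplexity = perplexity, downsample = ds$mode),
                 seed = seed)
}

# shared embedding input: reduction markers in canonical column order plus
# kept-cell indices from embedding-stage downsampling
embed_input <- function(exp, ds) {
  m <- marker_matrix(exp, "reduction")
  m <- m[, order(colnames(m)), drop = FALSE]
  kept <- downsample(exp, ds)$kept
  list(m = m[kept, , drop = FALSE], kept = kept)
}

store_reduction <- function(exp, name, coords_sub, kept) {
  coords <- matrix(NA_real_, n_cells(exp), 2,
                   dimnames = list(NULL, paste0(toupper(name), 1:2)))
  coords[kept, ] <- as.matrix(coords_sub)
  exp@reductions[[name]] <- coords
  exp
}

#' Principal component embedding (2-D)
#'
#' Simple PCA reduction stored alongside UMAP/tSNE layers.
#'
#' @param exp an [Experiment].
#' @param name reduction layer name.
#' @return the [Experiment] with `reductions[[name]]` filled.
#' @export
run_pca <- function(exp, name = "pca") {
  m <- marker_matrix(exp, "reduction")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  exp <- store_reduction(exp, name, pc$x[, 1:2, drop = FALSE],
                         seq_len(n_cells(exp)))
  add_provenance(exp, "run_pca", list())
}

#' Per-cell density on a 2-D embedding
#'
#' Gaussian product-kernel density estimate evaluated at every embedded
#' cell, with per-axis bandwidths from Scott's rule
#' (`sd * n^(-1/(d+4))`, d = 2). Highlights the density of cell islands in a
#' UMAP/tSNE plot.
#'
#' @param coords numeric n x 2 coordinate matrix (rows with NA are dropped
#'   from the computation and get NA density).
#' @return numeric vector of densities (positive, finite), aligned to rows.
#' @export
embedding_density <- function(coords) {
  coords <- as.matrix(coords)
  ok <- stats::complete.cases(coords)
  x <- coords[ok, , drop = FALSE]
  n <- nrow(x)
  if (n < 2) {
    cs_stop("embedding_density requires at least 2 points", "value_error")
  }
  h <- apply(x, 2, sd) * n^(-1 / 6)
  if (any(h == 0)) {
    cs_stop(paste0("degenerate embedding (zero spread on an axis); ",
                   "jitter the coordinates before computing densities"),
            "value_error")
  }
  z1 <- outer(x[, 1], x[, 1], "-") / h[1]
  z2 <- outer(x[, 2], x[, 2], "-") / h[2]
  kern <- exp(-0.5 * (z1^2 + z2^2))
  dens <- rowMeans(kern) / (2 * pi * h[1] * h[2])
  out <- rep(NA_real_, nrow(coords))
  out[ok] <- dens
  out
}
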