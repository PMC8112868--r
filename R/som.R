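#' Train a self-organizing map
#'
#' Online (default) or batch SOM on a rectangular grid. Codes are initialised
#' from a seeded random sample of cells; training presents the data for
#' `rlen` shuffled passes with the learning rate decaying linearly over
#' `alpha` and a Gaussian neighborhood whose radius shrinks linearly from
#' `ceiling(2/3 * grid diagonal)` to 0. Every cell is finally mapped to its
#' nearest code (Euclidean).
#'
#' With a zero radius the batch update is exactly Lloyd's k-means step, so a
#' `1 x K` grid in batch mode with `radius = c(0, 0)` reproduces k-means from
#' the same initialisation.
#'
#' @param m numeric cells x markers matrix (finite).
#' @param x_dim,y_dim grid dimensions (default 10 x 10, 100 nodes).
#' @param rlen training passes (online) or batch iterations.
#' @param alpha learning-rate range (online mode), default `c(0.05, 0.01)`.
#' @param radius neighborhood radius range; default
#'   `c(ceiling(2/3 * sqrt(x_dim^2 + y_dim^2)), 0)`.
#' @param mode `"online"` or `"batch"`.
#' @param seed integer seed (initialisation and presentation order).
#' @return a `SomModel`: list with `codes` (nodes x markers), `grid`,
#'   `node_of_cell`, `quantization_error` and training `params`.
#' @export
train_som <- function(m, x_dim = 10, y_dim = 10, rlen = 10,
                      alpha = c(0.05, 0.01), radius = NULL,
                      mode = c("online", "batch"), seed = 42) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) {
    cs_stop("train_som requires finite input values", "value_error")
  }
  n <- nrow(m)
  n_nodes <- as.integer(x_dim * y_dim)
  if (n < n_nodes) {
    cs_warn(sprintf("fewer cells (%d) than SOM nodes (%d); grid may be underused",
                    n, n_nodes))
  }
  if (is.null(radius)) {
    radius <- c(ceiling(2 / 3 * sqrt(x_dim^2 + y_dim^2)), 0)
  }
  grid <- as.matrix(expand.grid(gx = seq_len(x_dim), gy = seq_len(y_dim)))
  grid_d2 <- as.matrix(dist(grid))^2

  codes0 <- with_seed(derive_seed(seed, "som_init"), {
    m[sample.int(n, n_nodes, replace = n < n_nodes), , drop = FALSE]
  })
  codes <- if (mode == "online") {
    ord <- with_seed(derive_seed(seed, "som_order"), {
      unlist(lapply(seq_len(rlen), function(i) sample.int(n)))
    })
    .som_online(m, codes0, grid_d2, as.integer(ord - 1L),
                alpha[1], alpha[2], radius[1], radius[2])
  } else {
    .som_batch(m, codes0, grid_d2, as.integer(rlen), radius[1], radius[2])
  }
  mp <- .map_to_codes(m, codes)
  colnames(codes) <- colnames(m)
  structure(list(
    codes = codes, grid = c(x_dim = x_dim, y_dim = y_dim),
    node_of_cell = mp$node, quantization_error = mp$quantization_error,
    params = list(rlen = rlen, alpha = alpha, radius = radius,
                  mode = mode, seed = seed)
  ), class = "SomModel")
}
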