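#' SOM + consensus-metaclustering ensemble clustering
#'
#' The FlowSOM-style ensemble: train a SOM on the clustering markers, then
#' consensus-metacluster the SOM codes for every K in `2..maxK`. Cells
#' inherit the metacluster of their SOM node, so labels for every K are
#' stored and can be explored after the fact; over-clustering (maxK above the
#' expected number of populations, e.g. 56 in a whole-immune panel) is the
#' recommended usage, refined later by table-driven merging.
#'
#' @param exp an [Experiment] with clustering-flagged panel channels.
#' @param x_dim,y_dim SOM grid (default 10 x 10).
#' @param maxK largest number of metaclusters to store.
#' @param rlen SOM training passes.
#' @param reps,p_item consensus subsampling parameters.
#' @param seed integer seed.
#' @param name clustering layer name.
#' @return the [Experiment] with `clusterings[[name]]` filled
#'   (algorithm `som_consensus`; labels for every K, node map, SOM model and
#'   consensus result).
#' @export
flowsom_cluster <- function(exp, x_dim = 10, y_dim = 10, maxK = 20,
                            rlen = 10, reps = 100, p_item = 0.9, seed = 42,
                            name = "flowsom") {
  m <- marker_matrix(exp, "clustering")
  som <- train_som(m, x_dim = x_dim, y_dim = y_dim, rlen = rlen,
                   seed = derive_seed(seed, "som"))
  cr <- consensus_metacluster(som$codes, maxK = maxK, reps = reps,
                              p_item = p_item,
                              seed = derive_seed(seed, "consensus"))
  labels_by_k <- lapply(cr$labels_by_k, function(node_lab) {
    cell_lab <- node_lab[som$node_of_cell]
    # relabel by decreasing cell count; cells sharing a node keep sharing
    relabel_by_size(cell_lab)
  })
  ca <- cluster_assignments(
    algorithm = "som_consensus",
    params = list(x_dim = x_dim, y_dim = y_dim, maxK = maxK, rlen = rlen,
                  reps = reps, p_item = p_item, seed = seed),
    labels_by_k = labels_by_k,
    node_of_cell = som$node_of_cell,
    model = list(som = som, consensus_result = cr)
  )
  exp@clusterings[[name]] <- ca
  add_provenance(exp, "flowsom_cluster", ca$params, seed = seed)
}

#' kNN-graph community detection (PhenoGraph-style)
#'
#' Exact k-nearest neighbors (Euclidean) on the clustering markers, edges
#' weighted by the Jaccard overlap of the two endpoints' neighbor sets on
#' the union graph, then Louvain modularity maximisation. Labels are
#' relabeled `1..K` by decreasing community size.
#'
#' @param exp an [Experiment].
#' @param k number of nearest neighbors (must be `< n_cells`).
#' @param seed integer seed (community detection order).
#' @param name clustering layer name.
#' @return the [Experiment] with `clusterings[[name]]` filled (algorithm
#'   `graph_community`; one K = number of communities found; modularity in
#'   the model).
#' @export
graph_cluster <- function(exp, k = 30, seed = 42, name = "phenograph") {
  m <- marker_matrix(exp, "clustering")
  n <- nrow(m)
  if (k >= n) {
    cs_stop(sprintf("k (%d) must be smaller than the number of cells (%d)",
                    k, n), "value_error")
  }
  nn <- FNN::get.knn(m, k = k)$nn.index
  edges <- .jaccard_edges(nn)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  comm <- with_seed(derive_seed(seed, "louvain"), {
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  })
  labels <- relabel_by_size(as.integer(igraph::membership(comm)))
  kk <- max(labels)
  ca <- cluster_assignments(
    algorithm = "graph_community",
    params = list(k = k, seed = seed),
    labels_by_k = setNames(list(labels), as.character(kk)),
    model = list(modularity = igraph::modularity(comm),
                 n_edges = nrow(edges))
  )
  exp@clusterings[[name]] <- ca
  add_provenance(exp, "graph_cluster", ca$params, seed = seed)
}

#' k-means clustering of an Experiment
#'
#' Lloyd iterations from k-means++ seeding, best of `n_starts` restarts by
#' total within-cluster sum of squares.
#'
#' @param exp an [Experiment].
#' @param k number of clusters (`<= n_cells`).
#' @param seed integer seed.
#' @param n_starts number of k-means++ restarts.
#' @param name clustering layer name.
#' @return the [Experiment] with `clusterings[[name]]` filled (algorithm
#'   `kmeans`; centroids and WSS in the model).
#' @export
kmeans_cluster <- function(exp, k, seed = 42, n_starts = 10,
                           name = "kmeans") {
  m <- marker_matrix(exp, "clustering")
  fit <- kmeans_fit(m, k, seed = seed, n_starts = n_starts)
  labels <- relabel_by_size(fit$labels)
  ca <- cluster_assignments(
    algorithm = "kmeans",
    params = list(k = k, seed = seed, n_starts = n_starts),
    labels_by_k = setNames(list(labels), as.character(k)),
    model = list(centroids = fit$centroids,
                 tot_withinss = fit$tot_withinss,
                 wss_trace = fit$wss_trace)
  )
  exp@clusterings[[name]] <- ca
  add_provenance(exp, "kmeans_cluster", ca$params, seed = seed)
}

#' Fit k-means on a matrix (k-means++ / Lloyd)
#'
#' @param m numeric matrix (rows = observations).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param n_starts restarts; the fit with minimal total within-cluster sum of
#'   squares wins.
#' @param iter_max Lloyd iteration cap per start.
#' @return list with `labels`, `centroids`, `tot_withinss` and `wss_trace`
#'   (WSS after each Lloyd iteration of the winning start; non-increasing).
#' @export
kmeans_fit <- function(m, k, seed = 42, n_starts = 10, iter_max = 100) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  n <- nrow(m)
  if (k > n) {
    cs_stop(sprintf("k (%d) must not exceed the number of observations (%d)",
                    k, n), "value_error")
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- with_seed(derive_seed(seed, paste0("kmeans_start", s)), {
      centers <- kmeanspp_init(m, k)
      lloyd(m, centers, iter_max)
    })
    if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
  }
  best
}

# k-means++ seeding: first center uniform, then D^2-weighted draws
kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  centers <- matrix(0, k, ncol(m))
  centers[1, ] <- m[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums(sweep(m, 2, centers[1, ])^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- m[sample.int(n, 1, prob = probs), ]
      d2 <- pmin(d2, rowSums(sweep(m, 2, centers[j, ])^2))
    }
  }
  centers
}

lloyd <- function(m, centers, iter_max) {
  n <- nrow(m)
  k <- nrow(centers)
  rs_m <- rowSums(m^2)
  assign_prev <- rep(0L, n)
  wss_trace <- numeric(0)
  for (it in seq_len(iter_max)) {
    d2 <- outer(rs_m, rowSums(centers^2), "+") - 2 * (m %*% t(centers))
    labels <- max.col(-d2, ties.method = "first")
    for (j in which(tabulate(labels, k) == 0L)) {
      # empty cluster: steal the point farthest from its current center
      far <- which.max(d2[cbind(seq_len(n), labels)])
      labels[far] <- j
      d2[far, ] <- Inf  # don't steal the same point twice in this pass
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(m[labels == j, , drop = FALSE])
    }
    wss <- sum((m - centers[labels, , drop = FALSE])^2)
    wss_trace <- c(wss_trace, wss)
    if (identical(labels, assign_prev)) break
    assign_prev <- labels
  }
  list(labels = labels, centroids = centers, tot_withinss = wss,
       wss_trace = wss_trace)
}

#' Adjusted Rand index between two partitions
#'
#' Label-permutation-invariant agreement score used for all clustering
#' recovery checks (1 = identical partitions, ~0 = chance).
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    cs_stop("partitions must have equal length", "value_error")
  }
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
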