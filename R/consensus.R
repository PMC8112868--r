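#' Consensus metaclustering of SOM codes
#'
#' Tests the stability of candidate metaclusterings by repeated subsampling:
#' for each of `reps` repetitions a fraction `p_item` of the nodes is drawn,
#' hierarchically clustered (Euclidean, average linkage) and cut at every K
#' in `2..maxK`. The consensus matrix entry (i, j) is the number of times i
#' and j co-clustered divided by the number of times they were co-sampled
#' (0, flagged, for never-co-sampled pairs). The final partition for each K
#' is average-linkage hierarchical clustering of `1 - consensus`, cut at K.
#'
#' @param codes numeric nodes x markers matrix (typically SOM codes).
#' @param maxK largest number of metaclusters (must be `< nrow(codes)`).
#' @param reps number of subsampling repetitions.
#' @param p_item fraction of nodes drawn per repetition.
#' @param seed integer seed.
#' @return a `ConsensusResult`: list with `labels_by_k` (node labels per K,
#'   relabeled by decreasing node count), `consensus` (matrix per K), `area`
#'   (A(K), area under the consensus CDF), `delta` (relative area increase
#'   used for the elbow plot), `never_cosampled` (pair count) and `params`.
#' @export
consensus_metacluster <- function(codes, maxK, reps = 100, p_item = 0.9,
                                  seed = 42) {
  codes <- as.matrix(codes)
  n <- nrow(codes)
  if (maxK >= n) {
    cs_stop(sprintf("maxK (%d) must be smaller than the number of items (%d)",
                    maxK, n), "value_error")
  }
  if (maxK < 2) cs_stop("maxK must be at least 2", "value_error")
  ks <- 2:maxK
  n_draw <- ceiling(p_item * n)
  co_sample <- matrix(0, n, n)
  co_cluster <- lapply(ks, function(k) matrix(0, n, n))
  names(co_cluster) <- as.character(ks)

  for (r in seq_len(reps)) {
    idx <- with_seed(derive_seed(seed, paste0("consensus_rep", r)),
                     sort(sample.int(n, n_draw)))
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    hc <- hclust(dist(codes[idx, , drop = FALSE]), method = "average")
    for (k in ks) {
      lab <- cutree(hc, k = min(k, length(idx)))
      same <- outer(lab, lab, "==") * 1
      key <- as.character(k)
      co_cluster[[key]][idx, idx] <- co_cluster[[key]][idx, idx] + same
    }
  }

  never <- sum(co_sample[upper.tri(co_sample)] == 0)
  if (never > 0) {
    cs_warn(sprintf(
      "%d node pair(s) never co-sampled (p_item too small?); consensus set to 0",
      never))
  }
  consensus <- lapply(co_cluster, function(cc) {
    cm <- cc / pmax(co_sample, 1)
    cm[co_sample == 0] <- 0
    diag(cm) <- 1
    cm
  })

  labels_by_k <- list()
  for (k in ks) {
    cm <- consensus[[as.character(k)]]
    hc <- hclust(as.dist(1 - cm), method = "average")
    labels_by_k[[as.character(k)]] <- relabel_by_size(cutree(hc, k = k))
  }

  area <- vapply(ks, function(k) {
    consensus_cdf_area(consensus[[as.character(k)]])
  }, 0)
  names(area) <- as.character(ks)
  delta <- numeric(length(ks))
  delta[1] <- area[1]
  if (length(ks) > 1) {
    delta[-1] <- diff(area) / area[-length(area)]
  }
  names(delta) <- as.character(ks)

  structure(list(labels_by_k = labels_by_k, consensus = consensus,
                 area = area, delta = delta, never_cosampled = never,
                 params = list(maxK = maxK, reps = reps, p_item = p_item,
                               seed = seed)),
            class = "ConsensusResult")
}

# area under the empirical CDF of off-diagonal consensus values:
# sum over sorted values of (v[i+1] - v[i]) * CDF(v[i])
consensus_cdf_area <- function(cm) {
  v <- sort(cm[upper.tri(cm)])
  if (length(v) < 2) return(0)
  cdf <- seq_along(v) / length(v)
  sum(diff(v) * cdf[-length(v)])
}

#' Elbow-plot table from a consensus result
#'
#' A(K) is the area under the consensus-value CDF for each K; the relative
#' increase Delta(K) flattens once K exceeds the true number of clusters,
#' which is the elbow criterion for choosing K.
#'
#' @param cr a `ConsensusResult` (or a clustering layer carrying one).
#' @return data.frame with columns `K`, `area`, `delta`.
#' @export
elbow_data <- function(cr) {
  if (inherits(cr, "ClusterAssignments")) cr <- cr$model$consensus_result
  if (!inherits(cr, "ConsensusResult")) {
    cs_stop("elbow_data needs a ConsensusResult", "value_error")
  }
  if (length(cr$area) < 1) {
    cs_stop("consensus result covers no K values", "value_error")
  }
  data.frame(K = as.integer(names(cr$area)), area = unname(cr$area),
             delta = unname(cr$delta))
}
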