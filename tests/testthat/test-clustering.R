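test_that("train_som fixed point, determinism and quantization", {
  set.seed(2)
  m <- matrix(rnorm(16 * 3), 16, 3)
  # grid size == n: seeded init is a permutation of the data, and with a
  # zero radius every update pulls a code toward its own point -> QE 0
  som <- train_som(m, x_dim = 4, y_dim = 4, rlen = 3, radius = c(0, 0),
                   seed = 7)
  expect_equal(som$quantization_error, 0, tolerance = 1e-12)
  som2 <- train_som(m, x_dim = 4, y_dim = 4, rlen = 3, radius = c(0, 0),
                    seed = 7)
  expect_identical(som$codes, som2$codes)
  expect_warning(train_som(m, x_dim = 10, y_dim = 10, seed = 1),
                 "fewer cells")
  expect_error(train_som(matrix(c(1, NA), 2, 1)), class = "value_error")
})

test_that("batch SOM with zero neighborhood equals Lloyd from same init", {
  set.seed(31)
  for (case in 1:3) {
    m <- matrix(rnorm(40 * 2, mean = rep(c(0, 8, 16, 24), each = 10)),
                40, 2)
    k <- 4
    seed <- 100 + case
    som <- train_som(m, x_dim = k, y_dim = 1, rlen = 50, radius = c(0, 0),
                     mode = "batch", seed = seed)
    init <- cytosuite:::with_seed(derive_seed(seed, "som_init"),
                                  m[sample.int(nrow(m), k), , drop = FALSE])
    oracle <- lloyd_oracle(m, init, iters = 50)
    expect_equal(unname(som$codes), unname(oracle), tolerance = 1e-9)
  }
})

test_that("consensus metaclustering recovers separated structure", {
  set.seed(17)
  codes <- rbind(matrix(rnorm(10, sd = 0.05), 5, 2),
                 matrix(rnorm(10, mean = 10, sd = 0.05), 5, 2),
                 matrix(rnorm(10, mean = rep(c(0, 20), each = 5), sd = 0.05), 5, 2))
  truth <- rep(1:3, each = 5)
  cr <- consensus_metacluster(codes, maxK = 5, reps = 20, seed = 12)
  expect_equal(adjusted_rand_index(cr$labels_by_k[["3"]], truth), 1)
  # within-block consensus exactly 1 at the true K
  cm <- cr$consensus[["3"]]
  for (g in 1:3) {
    blk <- cm[truth == g, truth == g]
    expect_equal(unname(blk), matrix(1, 5, 5))
  }
  # consensus matrix invariants
  expect_true(all(cm >= 0 & cm <= 1))
  expect_equal(diag(cm), rep(1, 15))
  expect_identical(cm, t(cm))
  # labels stored for every K in 2..maxK
  expect_equal(names(cr$labels_by_k), as.character(2:5))
  expect_error(consensus_metacluster(codes, maxK = 15), class = "value_error")
})

test_that("never-co-sampled pairs are flagged and zeroed", {
  set.seed(3)
  codes <- matrix(rnorm(40), 20, 2)
  expect_warning(
    cr <- consensus_metacluster(codes, maxK = 2, reps = 3, p_item = 0.25,
                                seed = 5),
    "never co-sampled")
  expect_gt(cr$never_cosampled, 0)
})

test_that("elbow table: hand-computed area, monotone A(K), flat past true K", {
  # toy 2-value consensus matrix: sorted upper triangle {0.2, 0.2, 1}
  cm <- matrix(c(1, 0.2, 0.2, 0.2, 1, 1, 0.2, 1, 1), 3, 3)
  expect_equal(cytosuite:::consensus_cdf_area(cm),
               (1 - 0.2) * 2 / 3, tolerance = 1e-12)
  set.seed(17)
  codes <- rbind(matrix(rnorm(10, sd = 0.05), 5, 2),
                 matrix(rnorm(10, mean = 10, sd = 0.05), 5, 2),
                 matrix(rnorm(10, mean = rep(c(0, 20), each = 5), sd = 0.05), 5, 2))
  cr <- consensus_metacluster(codes, maxK = 5, reps = 20, seed = 12)
  tab <- elbow_data(cr)
  expect_equal(tab$K, 2:5)
  expect_true(all(diff(tab$area) >= -1e-12))    # A(K) non-decreasing
  # combinatorial oracle: binary consensus -> A(K) = 1 - sum C(n_c,2)/C(n,2);
  # the stable 3-group structure gives A(3) = 1 - 3*10/105 exactly
  expect_equal(tab$area[tab$K == 3], 1 - 30 / 105, tolerance = 1e-12)
  # past the true K the relative area gain flattens: the elbow
  expect_true(all(abs(tab$delta[tab$K > 3]) < 0.1))
  expect_gt(tab$delta[tab$K == 3], 4 * max(tab$delta[tab$K > 3]))
})

test_that("flowsom_cluster recovers simulated populations", {
  sim <- simulate_experiment(simulation_spec(cells_per_sample = 200,
                                             n_samples_per_group = c(A = 2, B = 2),
                                             seed = 42))
  exp <- sim$experiment
  exp <- flowsom_cluster(exp, maxK = 10, reps = 30, seed = 5)
  ca <- exp@clusterings$flowsom
  expect_equal(names(ca$labels_by_k), as.character(2:10))
  lab <- cluster_labels(exp, "flowsom", 8)
  expect_gte(adjusted_rand_index(lab, exp@cell_labels$truth), 0.9)
  # cells sharing a SOM node always share a metacluster
  for (k in c(3, 8)) {
    labk <- cluster_labels(exp, "flowsom", k)
    expect_true(all(tapply(labk, ca$node_of_cell,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("flowsom_cluster degenerates gracefully on constant data", {
  panel <- create_panel(c("a", "b"))
  samples <- create_sample_table("S1")
  exp <- build_experiment(matrix(1, 30, 2), rep("S1", 30), panel, samples)
  suppressWarnings(exp <- flowsom_cluster(exp, x_dim = 3, y_dim = 3,
                                          maxK = 4, reps = 10, seed = 1))
  for (k in 2:4) {
    expect_equal(length(unique(cluster_labels(exp, "flowsom", k))), 1)
  }
})

test_that("graph_cluster recovers two blobs and reports modularity", {
  # high-dimensional blobs: kNN graphs of low-dimensional geometric clouds
  # are modularity-splittable (sub-blob communities beat the 2-block
  # partition), whereas high-d neighbourhood graphs are expander-like and
  # stay whole; see the methods vignette
  exp <- blob_experiment(rbind(rep(0, 100), rep(6, 100)), n_per_blob = 50,
                         sd = 1, seed = 3)
  exp <- graph_cluster(exp, k = 10, seed = 9)
  ca <- exp@clusterings$phenograph
  kk <- names(ca$labels_by_k)[1]
  lab <- ca$labels_by_k[[kk]]
  expect_equal(as.integer(kk), 2)
  expect_equal(adjusted_rand_index(lab, exp@cell_labels$truth), 1)
  # modularity of the single-community partition is 0 by definition
  expect_gte(ca$model$modularity, 0)
  expect_error(graph_cluster(exp, k = 200), class = "value_error")
})

test_that("Jaccard edge weights: identical neighbor sets weigh 1", {
  nn <- rbind(c(2, 3, 4), c(1, 3, 5), c(1, 2, 4), c(1, 3, 5), c(2, 3, 4))
  edges <- cytosuite:::.jaccard_edges(nn)
  w12 <- edges$weight[(edges$from == 1 & edges$to == 2)]
  # self-inclusive sets: Ñ(1) = {1,2,3,4}, Ñ(2) = {1,2,3,5}: |I|=3, |U|=5
  expect_equal(w12, 0.6)
  # mutual neighbours sharing all other neighbours -> weight 1
  nn2 <- rbind(c(2, 3, 4), c(1, 3, 4), c(4, 1, 2), c(3, 1, 2))
  e2 <- cytosuite:::.jaccard_edges(nn2)
  expect_equal(e2$weight[e2$from == 1 & e2$to == 2], 1)
})

test_that("kmeans: toy optimum, k=1, monotone WSS, exhaustive oracle", {
  m <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  fit <- kmeans_fit(m, 2, seed = 1, n_starts = 10)
  expect_equal(sort(fit$centroids[, 1]), c(0.05, 10.05))
  expect_equal(fit$labels[1], fit$labels[2])
  expect_equal(fit$labels[3], fit$labels[4])

  fit1 <- kmeans_fit(m, 1, seed = 1)
  expect_equal(fit1$centroids[1, 1], mean(m))
  expect_true(all(diff(fit$wss_trace) <= 1e-12))
  expect_error(kmeans_fit(m, 5, seed = 1), class = "value_error")

  set.seed(77)
  for (case in 1:5) {
    n <- sample(4:8, 1)
    k <- sample(2:3, 1)
    mm <- matrix(rnorm(2 * n), n, 2)
    fit <- kmeans_fit(mm, k, seed = case, n_starts = 20)
    expect_equal(fit$tot_withinss, kmeans_oracle_wss(mm, k),
                 tolerance = 1e-9)
  }
})

test_that("kmeans_cluster stores relabeled assignments on the experiment", {
  exp <- blob_experiment(rbind(c(0, 0), c(8, 8), c(0, 8)), n_per_blob = 20,
                         seed = 5)
  exp <- kmeans_cluster(exp, k = 3, seed = 2)
  lab <- cluster_labels(exp, "kmeans", 3)
  expect_equal(sort(unique(lab)), 1:3)
  expect_equal(adjusted_rand_index(lab, exp@cell_labels$truth), 1)
  # label 1 is the largest cluster by convention (all equal here), and the
  # same seed reproduces the same labels
  exp2 <- kmeans_cluster(exp, k = 3, seed = 2, name = "km2")
  expect_identical(lab, cluster_labels(exp2, "km2", 3))
})
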