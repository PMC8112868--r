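annotated_experiment <- function() {
  exp <- blob_experiment(rbind(c(0, 0), c(6, 0), c(0, 6)), n_per_blob = 20,
                         seed = 13)
  kmeans_cluster(exp, k = 3, seed = 2)
}

test_that("cluster_medians summarises per cluster with optional scaling", {
  panel <- create_panel("c1")
  samples <- create_sample_table("S1")
  exp <- build_experiment(matrix(c(1, 2, 9, 5, 7), 5, 1), rep("S1", 5),
                          panel, samples)
  exp@cell_labels[["lab"]] <- c("x", "x", "x", "y", "y")
  med <- cluster_medians(exp, labels = "lab")
  expect_equal(med["x", "c1"], 2)
  expect_equal(med["y", "c1"], 6)
  sc <- cluster_medians(exp, labels = "lab", scale = "zero_one")
  expect_equal(unname(sc[, "c1"]), c(0, 1))
  # single cluster equals the global medians
  exp@cell_labels[["one"]] <- rep("all", 5)
  expect_equal(unname(cluster_medians(exp, labels = "one")[1, 1]), median(exp@raw))
  # empty cluster at a declared K gives an NA row with warning
  exp2 <- annotated_experiment()
  lab <- cluster_labels(exp2, "kmeans", 3)
  exp2@clusterings$kmeans$labels_by_k[["4"]] <- lab  # K=4, cluster 4 empty
  expect_warning(m4 <- cluster_medians(exp2, "kmeans", 4), "empty")
  expect_true(all(is.na(m4["4", ])))
})

test_that("imc_rank ranks clusters per marker with mid-rank ties", {
  med <- matrix(c(0.1, 0.5, 0.3), 3, 1,
                dimnames = list(1:3, "m"))
  expect_equal(unname(imc_rank(med)[, 1]), c(1, 3, 2))
  tied <- matrix(c(0.2, 0.2, 0.7), 3, 1)
  expect_equal(unname(imc_rank(tied)[, 1]), c(1.5, 1.5, 3))
  eight <- matrix(seq(0.1, 0.8, by = 0.1), 8, 1)
  expect_equal(max(imc_rank(eight)), 8)
  expect_error(imc_rank(med[1, , drop = FALSE]), class = "value_error")
  # invariance under strictly monotone per-marker transforms
  set.seed(4)
  m <- matrix(rexp(40), 8, 5)
  expect_equal(imc_rank(m), imc_rank(asinh(m * 10)))
  expect_equal(imc_rank(m), imc_rank(m^3))
})

test_that("merge_clusters is table-driven, complete and reversible", {
  exp <- annotated_experiment()
  lab <- cluster_labels(exp, "kmeans", 3)
  # identity table -> isomorphic labels
  ident <- data.frame(cluster = 1:3, cell_type = paste0("C", 1:3))
  exp2 <- merge_clusters(exp, "kmeans", 3, ident)
  expect_equal(exp2@cell_labels$cell_type, paste0("C", lab))
  # original integer labels retained untouched
  expect_identical(cluster_labels(exp2, "kmeans", 3), lab)
  # merge two clusters into one name, then un-merge via provenance
  mt <- data.frame(cluster = 1:3, cell_type = c("T", "T", "B"))
  exp3 <- merge_clusters(exp, "kmeans", 3, mt, name = "lvl1")
  expect_equal(sort(unique(exp3@cell_labels$lvl1)), c("B", "T"))
  expect_identical(unmerge_clusters(exp3, "lvl1"), lab)
  # incomplete table -> completeness error naming the missing cluster
  expect_error(merge_clusters(exp, "kmeans", 3,
                              data.frame(cluster = 1:2,
                                         cell_type = c("a", "b"))),
               "3", class = "completeness_error")
  expect_error(merge_clusters(exp, "kmeans", 3,
                              data.frame(cluster = c(1, 1, 2, 3),
                                         cell_type = c("a", "b", "c", "d"))),
               class = "value_error")
  expect_error(merge_clusters(exp, "kmeans", 3,
                              data.frame(cluster = 1:3,
                                         cell_type = c("a", "", "c"))),
               class = "value_error")
})

test_that("biaxial_data returns subset points with nested contours", {
  exp <- annotated_experiment()
  exp <- merge_clusters(exp, "kmeans", 3,
                        data.frame(cluster = 1:3,
                                   cell_type = c("a", "b", "c")))
  bd <- biaxial_data(exp, "M1", "M2", labels = "a", label_layer = "cell_type")
  expect_equal(nrow(bd$points), sum(exp@cell_labels$cell_type == "a"))
  # x == y marker puts points on the diagonal
  bd2 <- biaxial_data(exp, "M1", "M1")
  expect_equal(bd2$points$x, bd2$points$y)
  expect_error(biaxial_data(exp, "M1", "nope"), class = "panel_error")
  # contour nesting on a single blob: higher-level contours sit inside
  set.seed(6)
  panel <- create_panel(c("a", "b"))
  blob <- build_experiment(matrix(rnorm(600), 300, 2), rep("S1", 300),
                           panel, create_sample_table("S1"))
  bd3 <- biaxial_data(blob, "a", "b", levels = c(0.3, 0.9))
  lv <- vapply(bd3$contours, function(d) d$level[1], 0)
  lo <- do.call(rbind, bd3$contours[lv == min(lv)])
  hi <- do.call(rbind, bd3$contours[lv == max(lv)])
  expect_true(min(hi$x) >= min(lo$x) && max(hi$x) <= max(lo$x))
  expect_true(min(hi$y) >= min(lo$y) && max(hi$y) <= max(lo$y))
})

test_that("feature_overlay aligns values to embedded cells", {
  exp <- annotated_experiment()
  exp <- run_umap(exp, ds = downsample_config("equal_per_sample", 20,
                                              seed = 3), seed = 3)
  ov <- feature_overlay(exp, "umap", "M1")
  expect_equal(nrow(ov), sum(complete.cases(exp@reductions$umap)))
  # constant marker -> uniform values
  exp@transformed[, 1] <- 1
  ov2 <- feature_overlay(exp, "umap", "M1")
  expect_true(all(ov2$value == 1))
  # cluster labels as overlay (annotation-style coloring)
  exp <- merge_clusters(exp, "kmeans", 3,
                        data.frame(cluster = 1:3,
                                   cell_type = c("a", "b", "c")))
  ov3 <- feature_overlay(exp, "umap", "cell_type")
  expect_true(all(ov3$value %in% c("a", "b", "c")))
  # metadata columns resolve through the sample table
  ov4 <- feature_overlay(exp, "umap", "group")
  expect_true(all(ov4$value %in% c("A", "B")))
  expect_error(feature_overlay(exp, "nope", "M1"), class = "state_error")
  expect_error(feature_overlay(exp, "umap", "unknown_col"),
               class = "value_error")
})
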