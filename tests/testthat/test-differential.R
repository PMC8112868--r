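make_abundance <- function(props, groups) {
  samples <- sprintf("S%d", seq_len(nrow(props)))
  rownames(props) <- samples
  ab <- structure(list(counts = round(props * 1000), proportions = props),
                  class = "AbundanceTable")
  st <- data.frame(sample_id = samples, group = groups,
                   stringsAsFactors = FALSE)
  list(ab = ab, samples = st)
}

test_that("cluster_abundances counts and normalises per sample", {
  panel <- create_panel("c1")
  samples <- create_sample_table(c("S1", "S2"))
  exp <- build_experiment(matrix(0, 12, 1),
                          c(rep("S1", 10), rep("S2", 2)), panel, samples)
  exp@cell_labels[["lab"]] <- c(rep("a", 1), rep("b", 3), rep("c", 6),
                                rep("a", 2))
  ab <- cluster_abundances(exp, labels = "lab")
  expect_equal(unname(ab$proportions["S1", ]), c(0.1, 0.3, 0.6))
  # population absent from a sample -> 0, not NA
  expect_equal(unname(ab$proportions["S2", ]), c(1, 0, 0))
  expect_equal(unname(rowSums(ab$proportions)), c(1, 1), tolerance = 1e-9)
})

test_that("wilcoxon_rank_sum: exact enumeration values and edge cases", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 6)
  expect_equal(res$p, 0.1)      # 2/20 by enumeration over C(6,3) splits
  expect_true(res$exact)
  # identical multisets: p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(wilcoxon_rank_sum(1, c(1, 2)), class = "value_error")
  # exact path agrees with the enumeration oracle across random cases
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(sample(2:6, 1))
    y <- rnorm(sample(2:6, 1))
    expect_equal(wilcoxon_rank_sum(x, y)$p, wilcox_p_enum(x, y),
                 tolerance = 1e-12)
  }
  # normal approximation (forced by n > 20) close to the enumeration
  set.seed(11)
  x <- rnorm(10); y <- rnorm(11)
  expect_false(wilcoxon_rank_sum(x, y)$exact)
  expect_lt(abs(wilcoxon_rank_sum(x, y)$p - wilcox_p_enum(x, y)), 0.02)
})

test_that("welch_t matches the hand-computed toy and its limits", {
  res <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.2878641, tolerance = 1e-6)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # equal variances, equal n: Welch df hits the Student limit 2n - 2
  set.seed(2)
  x <- rnorm(6)
  y <- x + 1   # same variance exactly
  expect_equal(welch_t(x, y)$df, 10)
  expect_error(welch_t(c(1, 1), c(2, 2)), class = "degenerate_data_error")
})

test_that("bh_fdr equals the brute-force step-up", {
  expect_equal(bh_fdr(c(0.04, 0.01, 0.03)), c(0.04, 0.03, 0.04))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 1.2)), class = "value_error")
  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(1:15, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  # NA p-values pass through without disturbing the family
  p <- c(0.01, NA, 0.04)
  q <- bh_fdr(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_fdr(c(0.01, 0.04)))
})

test_that("stat_test_clust: enumeration oracle, symmetry, identical groups", {
  props <- cbind(p1 = c(0.2, 0.22, 0.21, 0.1, 0.11, 0.12))
  props <- cbind(props, p2 = 1 - props[, 1])
  ma <- make_abundance(props, rep(c("A", "B"), each = 3))
  dr <- stat_test_clust(ma$ab, ma$samples, "group", c("A", "B"))
  expect_equal(dr$log2fc[1], log2(0.21 / 0.11), tolerance = 1e-9)
  expect_gt(dr$log2fc[1], 0.9)
  expect_lt(abs(dr$log2fc[1] - 1), 0.1)
  expect_equal(dr$p[1], 0.1)   # exact Wilcoxon, all A above all B
  # symmetry: swapping the contrast negates log2FC, keeps p and FDR
  dr2 <- stat_test_clust(ma$ab, ma$samples, "group", c("B", "A"))
  expect_equal(dr2$log2fc, -dr$log2fc, tolerance = 1e-12)
  expect_equal(dr2$p, dr$p)
  expect_equal(dr2$fdr, dr$fdr)
  # identical groups: all p = 1, log2FC = 0
  same <- matrix(rep(c(0.3, 0.7), each = 6), 6, 2)
  ms <- make_abundance(same, rep(c("A", "B"), each = 3))
  dr3 <- stat_test_clust(ms$ab, ms$samples, "group", c("A", "B"))
  expect_true(all(dr3$p == 1))
  expect_true(all(dr3$log2fc == 0))
  # design errors
  expect_error(stat_test_clust(ma$ab, ma$samples, "nope", c("A", "B")),
               class = "design_error")
  expect_error(stat_test_clust(ma$ab, ma$samples, "group", c("A", "Z")),
               class = "design_error")
  # t-test mode runs and agrees in direction
  drt <- stat_test_clust(ma$ab, ma$samples, "group", c("A", "B"),
                         test = "ttest")
  expect_equal(sign(drt$statistic[1]), 1)
})

test_that("stat_test_expression localises a marker shift", {
  spec <- simulation_spec(
    cells_per_sample = 300,
    n_samples_per_group = c(A = 4, B = 4),
    effects = list(list(population = "P2", group = "A", marker = 9,
                        shift = 1)),
    seed = 33)
  sim <- simulate_experiment(spec)
  exp <- sim$experiment
  dr <- stat_test_expression(exp, labels = "truth", group_col = "group",
                             contrast = c("A", "B"))
  spiked <- dr[dr$population == "P2" & dr$marker == "M9", ]
  # the spiked pair attains the minimum p (ties possible: exact-test floor)
  expect_equal(spiked$p, min(dr$p, na.rm = TRUE))
  expect_gt(spiked$log2fc, 0.5)
  # joint BH family across all pairs
  expect_equal(dr$fdr[!is.na(dr$p)], bh_fdr(dr$p[!is.na(dr$p)]))
})

test_that("stat_test_expression: single pair gives q = p, absences noted", {
  panel <- create_panel("c1")
  samples <- create_sample_table(sprintf("S%d", 1:4),
                                 group = c("A", "A", "B", "B"))
  set.seed(9)
  exp <- build_experiment(matrix(rnorm(40), 40, 1),
                          rep(sprintf("S%d", 1:4), each = 10),
                          panel, samples)
  exp@cell_labels[["lab"]] <- rep("only", 40)
  dr <- stat_test_expression(exp, labels = "lab", group_col = "group",
                             contrast = c("A", "B"))
  expect_equal(nrow(dr), 1)
  expect_equal(dr$fdr, dr$p)
  # a population present in fewer than 2 samples per group -> NA + note
  exp@cell_labels[["lab"]][1:30] <- "rare_host"
  exp@cell_labels[["lab"]][31:40] <- "only"   # 'only' present in S4 alone
  dr2 <- stat_test_expression(exp, labels = "lab", group_col = "group",
                              contrast = c("A", "B"))
  row <- dr2[dr2$population == "only", ]
  expect_true(is.na(row$p))
  expect_match(row$note, "fewer than 2")
})

test_that("volcano_data applies the strict FDR threshold", {
  dr <- data.frame(population = c("a", "b", "c"),
                   log2fc = c(1, -1, 0),
                   p = c(0.001, 0.02, 0.9),
                   fdr = c(0.049, 0.05, 1))
  vd <- volcano_data(dr)
  expect_equal(vd$significant, c(TRUE, FALSE, FALSE))
  expect_equal(vd$neg_log10_fdr[3], 0)
  expect_error(volcano_data(dr[0, ]), class = "value_error")
})
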