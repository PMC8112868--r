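test_that("recover_imc_intensity applies the 16-bit scale factor", {
  expect_equal(recover_imc_intensity(matrix(1)), matrix(65535))
  expect_equal(recover_imc_intensity(matrix(0)), matrix(0))
  expect_equal(recover_imc_intensity(matrix(0.5)), matrix(32767.5))
  expect_warning(recover_imc_intensity(matrix(2)), "outside")
})

test_that("arcsinh_transform matches the closed form and its inverse", {
  expect_equal(arcsinh_transform(matrix(0), cofactor = 3), matrix(0))
  expect_equal(arcsinh_transform(matrix(0.8), cofactor = 0.8),
               matrix(log(1 + sqrt(2))), tolerance = 1e-9)
  set.seed(5)
  x <- matrix(rexp(200, rate = 0.01), 40, 5)
  y <- arcsinh_transform(x, cofactor = 5)
  expect_lt(max(abs(5 * sinh(y) - x)), 1e-9)
  # strict monotonicity: per-column ranks preserved
  for (j in seq_len(ncol(x))) {
    expect_equal(cor(rank(x[, j]), rank(y[, j])), 1)
  }
  expect_error(arcsinh_transform(x, cofactor = 0), class = "value_error")
  # on an Experiment the raw assay stays untouched
  exp <- toy_experiment()
  exp2 <- arcsinh_transform(exp, cofactor = 5)
  expect_identical(exp2@raw, exp@raw)
  expect_equal(exp2@transformed, asinh(exp@raw / 5))
})

make_sized_experiment <- function(counts) {
  sids <- names(counts)
  n <- sum(counts)
  panel <- create_panel(c("c1", "c2"))
  samples <- create_sample_table(sids, group = rep("A", length(sids)))
  set.seed(3)
  build_experiment(matrix(rnorm(2 * n), n, 2),
                   rep(sids, counts), panel, samples)
}

test_that("equal_per_sample downsampling draws min(target, n) per sample", {
  exp <- make_sized_experiment(c(S1 = 100, S2 = 200, S3 = 50))
  cfg <- downsample_config("equal_per_sample", target = 50, seed = 9)
  res <- downsample(exp, cfg)
  counts <- table(res$experiment@cell_sample)
  expect_equal(as.integer(counts[c("S1", "S2", "S3")]), c(50, 50, 50))
  # bit-reproducible under the same seed
  res2 <- downsample(exp, cfg)
  expect_identical(res$kept, res2$kept)
  # smaller samples keep everything, with a warning
  cfg80 <- downsample_config("equal_per_sample", target = 80, seed = 9)
  expect_warning(res3 <- downsample(exp, cfg80), "S3")
  expect_equal(as.integer(table(res3$experiment@cell_sample)[c("S1", "S2", "S3")]),
               c(80, 80, 50))
  expect_error(downsample_config("equal_per_sample", target = 0),
               class = "value_error")
})

test_that("total_cap downsampling splits the budget, remainder to largest", {
  exp <- make_sized_experiment(c(S1 = 100, S2 = 200, S3 = 50))
  res <- downsample(exp, downsample_config("total_cap", target = 120,
                                           seed = 1))
  expect_equal(as.integer(table(res$experiment@cell_sample)[c("S1", "S2", "S3")]),
               c(40, 40, 40))
  res2 <- downsample(exp, downsample_config("total_cap", target = 122,
                                            seed = 1))
  counts <- table(res2$experiment@cell_sample)
  expect_equal(as.integer(counts[c("S1", "S2", "S3")]), c(41, 41, 40))
  # mode none is the identity
  res3 <- downsample(exp, downsample_config("none"))
  expect_identical(res3$kept, seq_len(n_cells(exp)))
  expect_identical(res3$experiment@raw, exp@raw)
})

test_that("import_dataset concatenates, reorders channels and transforms", {
  dir <- tempfile()
  dir.create(dir)
  panel <- create_panel(c("chA", "chB"))
  samples <- data.frame(sample_id = c("S1", "S2"),
                        group = c("g1", "g2"), stringsAsFactors = FALSE)
  d1 <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2,
               dimnames = list(NULL, c("chA", "chB")))
  d2 <- matrix(c(40, 50, 4, 5), 2, 2,
               dimnames = list(NULL, c("chB", "chA")))  # shuffled order
  f1 <- file.path(dir, "s1.fcs"); f2 <- file.path(dir, "s2.fcs")
  write_fcs(d1, path = f1)
  write_fcs(d2, path = f2)

  exp <- import_dataset(c(S1 = f1, S2 = f2), panel, samples,
                        transform = transform_config("none"))
  expect_equal(n_cells(exp), 5)
  # channel order normalised to panel order despite shuffled file 2
  expect_equal(unname(exp@raw[4:5, ]),
               matrix(c(4, 5, 40, 50), 2, 2), tolerance = 1e-6)
  # permutation of the file list: same (sample, original_row) set
  exp_rev <- import_dataset(c(S2 = f2, S1 = f1), panel, samples,
                            transform = transform_config("none"))
  key <- function(e) sort(paste(e@cell_sample, e@cell_meta$original_row))
  expect_identical(key(exp), key(exp_rev))

  # missing channel reported per file
  panel3 <- create_panel(c("chA", "chB", "chC"))
  expect_error(import_dataset(c(S1 = f1, S2 = f2), panel3, samples),
               "chC", class = "import_error")
  expect_error(
    import_dataset(c(S1 = f1, S2 = f2), panel,
                   data.frame(sample_id = c("S1", "S1"))),
    class = "metadata_error")
})

test_that("IMC CSV import reproduces the recover + arcsinh chain", {
  dir <- tempfile()
  dir.create(dir)
  vals <- c(0, 0.25, 0.5, 1)
  f <- file.path(dir, "imc.csv")
  writeLines(c("CD20,CD3",
               paste(vals, rev(vals), sep = ",")), f)
  panel <- create_panel(c("CD20", "CD3"))
  samples <- data.frame(sample_id = "R1", stringsAsFactors = FALSE)
  exp <- import_dataset(c(R1 = f), panel, samples,
                        transform = transform_config("arcsinh", 0.8,
                                                     imc_recover = TRUE))
  expect_equal(unname(exp@transformed[, 1]), asinh(vals * 65535 / 0.8),
               tolerance = 1e-12)
  expect_equal(unname(exp@raw[, 1]), vals * 65535)
})
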