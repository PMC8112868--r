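# in-code fixtures: no binary files, everything generated at test time

# minimal 2-sample experiment: S1 has 3 cells, S2 has 2, two channels
toy_experiment <- function(raw = NULL) {
  if (is.null(raw)) {
    raw <- matrix(c(1, 2, 3, 4, 5,
                    10, 20, 30, 40, 50), ncol = 2,
                  dimnames = list(NULL, c("ch1", "ch2")))
  }
  panel <- create_panel(c("ch1", "ch2"), marker_name = c("CD3", "CD19"),
                        role = c("lineage", "lineage"))
  samples <- create_sample_table(c("S1", "S2"), condition = c("a", "b"))
  build_experiment(raw, c("S1", "S1", "S1", "S2", "S2"), panel, samples)
}

# well-separated Gaussian blobs as an Experiment (transformed == raw)
blob_experiment <- function(centers, n_per_blob = 50, sd = 0.3, seed = 11,
                            n_samples = 2) {
  set.seed(seed)
  p <- ncol(centers)
  k <- nrow(centers)
  m <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(rnorm(n_per_blob * p, mean = rep(centers[i, ], each = n_per_blob),
                 sd = sd), n_per_blob, p)
  }))
  n <- nrow(m)
  ids <- sprintf("M%d", seq_len(p))
  panel <- create_panel(ids, role = "lineage")
  sids <- sprintf("S%d", seq_len(n_samples))
  samples <- create_sample_table(sids, group = rep(c("A", "B"),
                                                   length.out = n_samples))
  cell_sample <- rep(sids, length.out = n)[order(rep(seq_len(n_samples),
                                                     length.out = n))]
  exp <- build_experiment(m, sort(rep(sids, length.out = n)), panel, samples)
  exp@cell_labels[["truth"]] <- as.character(rep(seq_len(k),
                                                 each = n_per_blob))
  exp
}

# independent low-level FCS writer used as an oracle for reader tests:
# parametrises endianness and integer datatypes, unlike write_fcs
write_fcs_custom <- function(data, path, byteord = "1,2,3,4",
                             datatype = "F", pnb = NULL, mode = "L",
                             nextdata = "0") {
  p <- ncol(data)
  if (is.null(pnb)) {
    pnb <- rep(if (datatype == "D") 64L else 32L, p)
  }
  kw <- c("$BYTEORD" = byteord, "$DATATYPE" = datatype, "$MODE" = mode,
          "$NEXTDATA" = nextdata, "$PAR" = as.character(p),
          "$TOT" = as.character(nrow(data)),
          "$BEGINDATA" = sprintf("%010d", 0),
          "$ENDDATA" = sprintf("%010d", 0))
  for (i in seq_len(p)) {
    kw[sprintf("$P%dN", i)] <- sprintf("chan%d", i)
    kw[sprintf("$P%dB", i)] <- as.character(pnb[i])
  }
  render <- function(kw) paste0("/", paste0(names(kw), "/", kw, "/",
                                            collapse = ""))
  text <- render(kw)
  text_start <- 58L
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_end + 1L
  bytes <- sum(pnb / 8) * nrow(data)
  kw["$BEGINDATA"] <- sprintf("%010d", data_start)
  kw["$ENDDATA"] <- sprintf("%010d", data_start + bytes - 1)
  text <- render(kw)
  header <- paste0("FCS3.1    ", sprintf("%8d", text_start),
                   sprintf("%8d", text_end), sprintf("%8d", data_start),
                   sprintf("%8d", data_start + bytes - 1),
                   sprintf("%8d", 0L), sprintf("%8d", 0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  endian <- if (grepl("^1", byteord)) "little" else "big"
  vals <- as.vector(t(data))
  if (datatype == "I") {
    writeBin(as.integer(vals), con, size = pnb[1] / 8, endian = endian)
  } else {
    writeBin(vals, con, size = pnb[1] / 8, endian = endian)
  }
  invisible(path)
}

# enumeration oracle for the two-sided Wilcoxon rank-sum p-value
wilcox_p_enum <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  subsets <- utils::combn(n, nx)
  u_all <- colSums(matrix(r[subsets], nrow = nx)) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# literal step-up definition of BH as an oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(m * p[o[i:m]] / seq(i, m)))
  }
  # note: p[o[i:m]]/seq(i,m) pairs sorted p with its own rank
  q
}

# exhaustive-partition k-means optimum: min WSS over all k^n assignments
kmeans_oracle_wss <- function(m, k) {
  n <- nrow(m)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- grid[r, ]
    wss <- 0
    for (j in unique(lab)) {
      pts <- m[lab == j, , drop = FALSE]
      ctr <- colMeans(pts)
      wss <- wss + sum(sweep(pts, 2, ctr)^2)
    }
    if (wss < best) best <- wss
  }
  best
}

# Lloyd oracle matching the batch-SOM "empty node keeps its code" convention
lloyd_oracle <- function(m, centers, iters = 50) {
  for (it in seq_len(iters)) {
    d2 <- outer(rowSums(m^2), rowSums(centers^2), "+") - 2 * m %*% t(centers)
    lab <- max.col(-d2, ties.method = "first")
    for (j in seq_len(nrow(centers))) {
      if (any(lab == j)) centers[j, ] <- colMeans(m[lab == j, , drop = FALSE])
    }
  }
  centers
}
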