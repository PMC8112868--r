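#' Per-sample cluster abundance table
#'
#' Counts of cells per (sample, population) and the corresponding per-sample
#' proportions (each row sums to 1). Populations absent from a sample get
#' proportion 0, not NA.
#'
#' @param exp an [Experiment].
#' @param labels a `cell_labels` layer name, a per-cell label vector, or via
#'   `clustering`/`k`.
#' @param clustering,k alternative label source (see [cluster_labels()]).
#' @return an `AbundanceTable`: list with `counts` and `proportions`
#'   (samples x populations matrices).
#' @export
cluster_abundances <- function(exp, labels = NULL, clustering = NULL,
                               k = NULL) {
  lab <- resolve_labels(exp, clustering, k, labels)
  sample_ids <- exp@samples$sample_id
  have <- sample_ids %in% unique(exp@cell_sample)
  if (any(!have)) {
    cs_warn(sprintf("samples with zero cells excluded: %s",
                    paste(sample_ids[!have], collapse = ", ")))
    sample_ids <- sample_ids[have]
  }
  pops <- if (is.numeric(lab)) as.character(sort(unique(lab))) else
    sort(unique(as.character(lab)))
  counts <- matrix(0L, length(sample_ids), length(pops),
                   dimnames = list(sample_ids, pops))
  tab <- table(exp@cell_sample, as.character(lab))
  counts[rownames(tab), colnames(tab)] <- tab
  props <- counts / rowSums(counts)
  structure(list(counts = counts, proportions = props),
            class = "AbundanceTable")
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact null distribution when `n_x + n_y <= 20` and the pooled data are
#' tie-free; otherwise the normal approximation with tie and continuity
#' corrections. The statistic reported is the rank sum of `x`.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return list with `statistic` (rank sum W of x), `u` (Mann-Whitney U),
#'   `p` (two-sided) and `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    cs_stop("each group needs at least 2 values", "value_error")
  }
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  u <- w - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (nx + ny <= 20 && !ties) {
    p <- min(1, 2 * min(pwilcox(u, nx, ny), 1 - pwilcox(u - 1, nx, ny)))
    return(list(statistic = w, u = u, p = p, exact = TRUE))
  }
  n <- nx + ny
  tie_tab <- table(r)
  sigma2 <- (nx * ny / 12) * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                                (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = w, u = u, p = 1, exact = FALSE))
  }
  z <- u - nx * ny / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = w, u = u, p = p, exact = FALSE)
}

#' Welch's unequal-variance t-test (two-sided)
#'
#' @param x,y numeric vectors (each of length >= 2); at least one group must
#'   have nonzero variance.
#' @return list with `statistic` (t), `df` (Welch-Satterthwaite) and `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    cs_stop("each group needs at least 2 values", "value_error")
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(list(statistic = 0, df = NA_real_, p = 1))
    cs_stop("degenerate data: both groups have zero variance", "degenerate_data_error")
  }
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: `q(i) = min over j >= i of m * p(j) / j` on the
#' sorted p-values, mapped back to input order and clipped to 1.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA passed through).
#' @return vector of q-values in input order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    cs_stop("p-values must lie in [0, 1]", "value_error")
  }
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(q)
  o <- order(pv)
  ranked <- pv[o] * m / seq_len(m)
  ranked <- rev(cummin(rev(ranked)))
  qq <- numeric(m)
  qq[o] <- pmin(ranked, 1)
  q[ok] <- qq
  q
}

#' Differential cluster abundance between two groups
#'
#' Per population: a two-group test (Wilcoxon rank-sum by default, Welch's
#' t optionally) on the per-sample proportions, log2 fold change of group
#' means with the first contrast level positive, and BH-FDR across
#' populations. When a group mean is 0 a half-minimum pseudo-count keeps the
#' fold change finite (flagged in the output).
#'
#' @param ab an `AbundanceTable` from [cluster_abundances()].
#' @param samples sample table (or an [Experiment]).
#' @param group_col grouping column in the sample table.
#' @param contrast length-2 character: (group A, group B); log2FC > 0 means
#'   higher in A.
#' @param test `"wilcox"` or `"ttest"`.
#' @return a `DiffResult` data.frame: `population`, `mean_A`, `mean_B`,
#'   `log2fc`, `statistic`, `p`, `fdr`, `pseudo_used`, `test`.
#' @export
stat_test_clust <- function(ab, samples, group_col, contrast,
                            test = c("wilcox", "ttest")) {
  test <- match.arg(test)
  if (is(samples, "Experiment")) samples <- samples@samples
  if (!group_col %in% names(samples)) {
    cs_stop(sprintf("design error: no grouping column '%s'", group_col),
            "design_error")
  }
  props <- ab$proportions
  grp <- samples[[group_col]][match(rownames(props), samples$sample_id)]
  ia <- which(grp == contrast[1]); ib <- which(grp == contrast[2])
  if (length(ia) < 2 || length(ib) < 2) {
    cs_stop(sprintf(
      "design error: each contrast level needs >= 2 samples (got %d '%s', %d '%s')",
      length(ia), contrast[1], length(ib), contrast[2]), "design_error")
  }
  pseudo <- min(props[props > 0]) / 2
  rows <- lapply(colnames(props), function(pop) {
    xa <- props[ia, pop]; xb <- props[ib, pop]
    res <- if (test == "wilcox") wilcoxon_rank_sum(xa, xb) else welch_t(xa, xb)
    ma <- mean(xa); mb <- mean(xb)
    pseudo_used <- ma == 0 || mb == 0
    l2fc <- if (ma == 0 && mb == 0) 0 else
      log2(max(ma, if (pseudo_used) pseudo else 0) /
             max(mb, if (pseudo_used) pseudo else 0))
    data.frame(population = pop, mean_A = ma, mean_B = mb, log2fc = l2fc,
               statistic = res$statistic, p = res$p,
               pseudo_used = pseudo_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$test <- test
  attr(out, "contrast") <- contrast
  class(out) <- c("DiffResult", "data.frame")
  out
}

#' Differential marker expression within populations
#'
#' For every (population, marker) pair: the per-sample median of the
#' transformed marker within the population (samples lacking the population
#' are omitted for that population), a two-group test across samples, and
#' BH-FDR computed jointly across all pairs (the conservative family
#' choice). Pairs with fewer than 2 usable samples in either group get NA
#' with a note.
#'
#' @param exp an [Experiment].
#' @param labels,clustering,k label source (see [cluster_abundances()]).
#' @param group_col,contrast,test as in [stat_test_clust()].
#' @param which marker set passed to [marker_matrix()].
#' @return a `DiffResult` data.frame with one row per (population, marker).
#' @export
stat_test_expression <- function(exp, labels = NULL, clustering = NULL,
                                 k = NULL, group_col, contrast,
                                 test = c("wilcox", "ttest"), which = "all") {
  test <- match.arg(test)
  lab <- resolve_labels(exp, clustering, k, labels)
  m <- marker_matrix(exp, which)
  samples <- exp@samples
  if (!group_col %in% names(samples)) {
    cs_stop(sprintf("design error: no grouping column '%s'", group_col),
            "design_error")
  }
  grp <- setNames(samples[[group_col]], samples$sample_id)
  sa <- names(grp)[grp == contrast[1]]
  sb <- names(grp)[grp == contrast[2]]
  if (length(sa) < 2 || length(sb) < 2) {
    cs_stop("design error: each contrast level needs >= 2 samples",
            "design_error")
  }
  pops <- if (is.numeric(lab)) as.character(sort(unique(lab))) else
    sort(unique(as.character(lab)))
  rows <- list()
  for (pop in pops) {
    in_pop <- as.character(lab) == pop
    med_by_sample <- function(sids, j) {
      v <- vapply(sids, function(s) {
        sel <- in_pop & exp@cell_sample == s
        if (!any(sel)) return(NA_real_)
        median(m[sel, j])
      }, 0)
      v[!is.na(v)]
    }
    for (j in seq_len(ncol(m))) {
      xa <- med_by_sample(sa, j); xb <- med_by_sample(sb, j)
      if (length(xa) < 2 || length(xb) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          population = pop, marker = colnames(m)[j],
          mean_A = NA_real_, mean_B = NA_real_, log2fc = NA_real_,
          statistic = NA_real_, p = NA_real_,
          note = "fewer than 2 samples with this population in a group",
          stringsAsFactors = FALSE)
        next
      }
      res <- if (test == "wilcox") wilcoxon_rank_sum(xa, xb) else
        welch_t(xa, xb)
      rows[[length(rows) + 1]] <- data.frame(
        population = pop, marker = colnames(m)[j],
        mean_A = mean(xa), mean_B = mean(xb),
        log2fc = mean(xa) - mean(xb),  # difference in asinh units
        statistic = res$statistic, p = res$p, note = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$test <- test
  attr(out, "contrast") <- contrast
  class(out) <- c("DiffResult", "data.frame")
  out
}

#' Volcano-plot table from a differential result
#'
#' @param dr a `DiffResult`.
#' @param fdr_threshold significance cut (strict `fdr < threshold`).
#' @return data.frame with `log2fc`, `neg_log10_fdr` and `significant`.
#' @export
volcano_data <- function(dr, fdr_threshold = 0.05) {
  if (!nrow(dr)) cs_stop("empty differential result", "value_error")
  out <- as.data.frame(dr)
  out$neg_log10_fdr <- -log10(out$fdr)
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_threshold
  out
}
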