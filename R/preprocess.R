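#' Transformation configuration
#'
#' @param kind `"arcsinh"` or `"none"`.
#' @param cofactor positive divisor c in `asinh(x / c)`. Modality defaults:
#'   5 (mass cytometry), 150 (fluorescence flow), 0.8 (IMC); only the IMC
#'   value is prescribed by the IMC intensity-recovery protocol, the others
#'   follow field convention.
#' @param imc_recover multiply intensities by 65,535 before transforming
#'   (recovers 16-bit image intensities from mean-normalised IMC exports).
#' @return a `TransformConfig` list.
#' @export
transform_config <- function(kind = c("arcsinh", "none"), cofactor = 5,
                             imc_recover = FALSE) {
  kind <- match.arg(kind)
  if (!is.numeric(cofactor) || cofactor <= 0) {
    cs_stop("cofactor must be a positive real", "value_error")
  }
  structure(list(kind = kind, cofactor = cofactor,
                 imc_recover = isTRUE(imc_recover)),
            class = "TransformConfig")
}

#' Downsampling configuration
#'
#' Two interpretations of adaptive downsampling are provided:
#' `equal_per_sample` draws the same number of cells from every sample
#' (rectifying unequal cell recovery across samples), `total_cap` enforces a
#' total cell budget split into per-sample quotas.
#'
#' @param mode `"equal_per_sample"`, `"total_cap"` or `"none"`.
#' @param target cells per sample (equal_per_sample) or total cap (total_cap).
#' @param seed integer RNG seed; per-sample draws are seeded by
#'   (seed, sample index) so adding a sample never perturbs other samples.
#' @return a `DownsampleConfig` list.
#' @export
downsample_config <- function(mode = c("none", "equal_per_sample", "total_cap"),
                              target = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (mode != "none") {
    if (is.null(target) || !is.numeric(target) || target < 1) {
      cs_stop("downsample target must be a positive integer", "value_error")
    }
    target <- as.integer(target)
  }
  structure(list(mode = mode, target = target, seed = as.integer(seed)),
            class = "DownsampleConfig")
}

#' Recover 16-bit IMC image intensities
#'
#' Mean per-cell IMC intensities are commonly exported normalised to
#' `[0, 1]`; multiplying by 65,535 recovers the instrument's 16-bit dynamic
#' range before arcsinh transformation.
#'
#' @param m numeric matrix of normalised intensities.
#' @return `m * 65535`. Values outside `[0, 1]` trigger a warning only.
#' @export
recover_imc_intensity <- function(m) {
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    cs_warn("recover_imc_intensity: values outside [0, 1]; input may already be on the intensity scale")
  }
  m * 65535
}

#' Arcsinh-transform an Experiment or matrix
#'
#' Applies the variance-stabilising transform `asinh(x / cofactor)`
#' entrywise. On an [Experiment] the result is stored in the `transformed`
#' assay; the `raw` assay is never modified.
#'
#' @param x an [Experiment] or numeric matrix.
#' @param cofactor positive cofactor.
#' @return transformed object of the same type as `x`.
#' @export
arcsinh_transform <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0) {
    cs_stop("cofactor must be a single positive real", "value_error")
  }
  if (is(x, "Experiment")) {
    x@transformed <- asinh(x@raw / cofactor)
    x <- add_provenance(x, "arcsinh_transform", list(cofactor = cofactor))
    return(x)
  }
  asinh(x / cofactor)
}

#' Downsample an Experiment
#'
#' `equal_per_sample`: each sample contributes `min(target, n_sample)` cells
#' drawn without replacement (samples smaller than the target keep all cells,
#' with a warning). `total_cap`: per-sample quota `floor(cap / n_samples)`
#' with the remainder given to the largest samples. Deterministic given the
#' config seed.
#'
#' @param exp an [Experiment].
#' @param cfg a [downsample_config()].
#' @return list with `experiment` (the downsampled [Experiment]) and `kept`
#'   (integer indices into the input cells, for provenance).
#' @export
downsample <- function(exp, cfg) {
  stopifnot(inherits(cfg, "DownsampleConfig"))
  n <- n_cells(exp)
  if (cfg$mode == "none") {
    return(list(experiment = exp, kept = seq_len(n)))
  }
  sample_ids <- exp@samples$sample_id
  counts <- vapply(sample_ids, function(s) sum(exp@cell_sample == s), 1L)
  quota <- if (cfg$mode == "equal_per_sample") {
    setNames(rep(cfg$target, length(sample_ids)), sample_ids)
  } else {
    ns <- length(sample_ids)
    base <- cfg$target %/% ns
    rem <- cfg$target - base * ns
    q <- setNames(rep(base, ns), sample_ids)
    if (rem > 0) {
      big <- names(sort(counts, decreasing = TRUE))[seq_len(rem)]
      q[big] <- q[big] + 1L
    }
    q
  }
  short <- sample_ids[counts < quota[sample_ids] & counts > 0]
  if (cfg$mode == "equal_per_sample" && length(short)) {
    cs_warn(sprintf("samples smaller than target keep all cells: %s",
                    paste(short, collapse = ", ")))
  }
  kept <- integer(0)
  for (i in seq_along(sample_ids)) {
    s <- sample_ids[i]
    idx <- which(exp@cell_sample == s)
    take <- min(quota[[s]], length(idx))
    if (take == 0L) next
    picked <- with_seed(derive_seed(cfg$seed, paste0("downsample_", i)), {
      if (take == length(idx)) idx else sort(sample(idx, take))
    })
    kept <- c(kept, picked)
  }
  kept <- sort(kept)
  out <- subset_experiment(exp, cells = kept)
  out <- add_provenance(out, "downsample",
                        list(mode = cfg$mode, target = cfg$target),
                        seed = cfg$seed)
  list(experiment = out, kept = kept)
}

#' Import a multi-sample dataset into an Experiment
#'
#' Reads one FCS file or IMC cell table per sample, checks that every file
#' carries all panel channels, reorders channels to panel order, concatenates
#' events, applies the configured transform (optionally with 16-bit IMC
#' intensity recovery) and optional downsampling. Per-cell provenance
#' (sample, source file, original row) is kept in `cell_meta`.
#'
#' @param paths character vector of FCS/CSV paths, one per sample, aligned to
#'   rows of `samples` (or named by sample_id).
#' @param panel panel from [create_panel()] or a panel CSV path with the same
#'   columns.
#' @param samples sample table from [create_sample_table()] or a CSV path
#'   with a `sample_id` column.
#' @param transform a [transform_config()].
#' @param ds a [downsample_config()].
#' @return an [Experiment].
#' @export
import_dataset <- function(paths, panel, samples,
                           transform = transform_config("arcsinh", 5),
                           ds = downsample_config("none")) {
  if (is.character(panel)) panel <- read_panel_csv(panel)
  if (is.character(samples)) samples <- read_sample_csv(samples)
  if (anyDuplicated(samples$sample_id)) {
    cs_stop("metadata error: duplicate sample_id in sample table",
            "metadata_error")
  }
  if (is.null(names(paths))) {
    if (length(paths) != nrow(samples)) {
      cs_stop(sprintf(
        "import error: %d files but %d samples; name paths by sample_id or supply one per sample",
        length(paths), nrow(samples)), "import_error")
    }
    names(paths) <- samples$sample_id
  }
  missing_s <- setdiff(names(paths), samples$sample_id)
  if (length(missing_s)) {
    cs_stop(sprintf("metadata error: file sample ids not in sample table: %s",
                    paste(missing_s, collapse = ", ")), "metadata_error")
  }

  mats <- list(); metas <- list(); cell_samples <- list()
  for (s in names(paths)) {
    pth <- paths[[s]]
    rs <- if (grepl("\\.csv$", pth, ignore.case = TRUE)) {
      read_cell_table(pth)
    } else {
      read_fcs(pth)
    }
    miss <- setdiff(panel$channel_id, rs$channel_ids)
    if (length(miss)) {
      cs_stop(sprintf("import error: file %s is missing panel channel(s): %s",
                      pth, paste(miss, collapse = ", ")), "import_error")
    }
    m <- rs$data[, panel$channel_id, drop = FALSE]  # normalise channel order
    meta <- data.frame(source_file = rep(basename(pth), nrow(m)),
                       original_row = seq_len(nrow(m)),
                       stringsAsFactors = FALSE)
    if (!is.null(rs$cell_meta) && nrow(rs$cell_meta) == nrow(m) &&
        ncol(rs$cell_meta) > 0) {
      meta <- cbind(meta, rs$cell_meta)
    }
    mats[[s]] <- m
    metas[[s]] <- meta
    cell_samples[[s]] <- rep(s, nrow(m))
  }
  raw <- do.call(rbind, mats)
  rownames(raw) <- NULL
  cell_meta <- do.call(rbind, lapply(metas, function(d) {
    d[setdiff(unique(unlist(lapply(metas, names))), names(d))] <- NA
    d[, unique(unlist(lapply(metas, names))), drop = FALSE]
  }))
  rownames(cell_meta) <- NULL
  if (isTRUE(transform$imc_recover)) raw <- recover_imc_intensity(raw)

  exp <- build_experiment(raw, unlist(cell_samples, use.names = FALSE),
                          panel, samples, cell_meta = cell_meta)
  exp <- add_provenance(exp, "import_dataset",
                        list(files = unname(vapply(paths, basename, "")),
                             transform = unclass(transform)))
  if (transform$kind == "arcsinh") {
    exp <- arcsinh_transform(exp, transform$cofactor)
  }
  if (ds$mode != "none") {
    exp <- downsample(exp, ds)$experiment
  }
  exp
}

#' Read / write panel and sample metadata CSVs
#'
#' Header contracts: the panel CSV needs columns `channel_id`, `marker_name`,
#' `role`, `use_clustering`, `use_reduction`; the sample CSV needs
#' `sample_id` plus arbitrary covariate columns.
#'
#' @param path CSV path.
#' @return a panel or sample `data.frame`.
#' @export
read_panel_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel_id", "marker_name", "role", "use_clustering",
            "use_reduction")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    cs_stop(sprintf("panel CSV missing column(s): %s",
                    paste(miss, collapse = ", ")), "metadata_error")
  }
  create_panel(df$channel_id, df$marker_name, df$role,
               as.logical(df$use_clustering), as.logical(df$use_reduction))
}

#' @rdname read_panel_csv
#' @export
read_sample_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    cs_stop("sample CSV missing 'sample_id' column", "metadata_error")
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    cs_stop("metadata error: duplicate sample_id in sample CSV",
            "metadata_error")
  }
  df
}
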