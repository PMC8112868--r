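#' Specification for a synthetic cytometry dataset
#'
#' Describes a multi-sample, multi-group experiment with known population
#' structure: Gaussian populations in transformed (arcsinh) space, per-sample
#' abundances drawn from a Dirichlet around group-adjusted base abundances,
#' and optional group effects (abundance multipliers, marker shifts). The
#' default emulates a whole-immune panel at desk scale: 8 populations
#' including one rare 1% population, 2 groups x 8 samples, 5,000 cells per
#' sample, 10 markers (8 lineage one-hot archetypes + 2 functional), and one
#' 2x abundance spike on a 10% population in group A.
#'
#' @param populations list of `list(name, mean, sd)` entries; `mean` is a
#'   length-`n_markers` vector in transformed units, `sd` a positive scalar.
#' @param base_abundance probability vector (sums to 1), one per population.
#' @param n_samples_per_group named integer vector, e.g. `c(A = 8, B = 8)`.
#' @param cells_per_sample cells drawn per sample (multinomial).
#' @param effects list of `list(population, group, abundance_multiplier)` or
#'   `list(population, group, marker, shift)` entries.
#' @param concentration Dirichlet concentration: per-sample abundances are
#'   `Dirichlet(concentration * adjusted base)`; 100 gives a realistic
#'   ~30% CV for a 10% population.
#' @param cofactor arcsinh cofactor used to back-compute the raw assay via
#'   `raw = cofactor * sinh(transformed)`.
#' @param seed integer seed.
#' @return a validated `SimulationSpec` list.
#' @export
simulation_spec <- function(populations = NULL, base_abundance = NULL,
                            n_samples_per_group = c(A = 8, B = 8),
                            cells_per_sample = 5000, effects = NULL,
                            concentration = 100, cofactor = 5, seed = 1) {
  if (is.null(populations)) {
    n_markers <- 10
    populations <- lapply(seq_len(8), function(i) {
      mu <- rep(0.5, n_markers)
      mu[i] <- 3            # one-hot lineage archetype
      mu[9:10] <- 1         # functional markers, shared baseline
      list(name = paste0("P", i), mean = mu, sd = 0.35)
    })
  }
  if (is.null(base_abundance)) {
    base_abundance <- c(0.24, 0.20, 0.15, 0.12, 0.10, 0.10, 0.08, 0.01)
  }
  if (is.null(effects)) {
    effects <- list(list(population = "P5", group = "A",
                         abundance_multiplier = 2))
  }
  if (length(base_abundance) != length(populations)) {
    cs_stop("invalid spec: base_abundance length must match populations",
            "value_error")
  }
  if (abs(sum(base_abundance) - 1) > 1e-9) {
    cs_stop("invalid spec: base_abundance must sum to 1", "value_error")
  }
  p <- length(populations[[1]]$mean)
  for (pop in populations) {
    if (length(pop$mean) != p) {
      cs_stop("invalid spec: populations: mean vectors must share length",
              "value_error")
    }
    if (is.null(pop$sd) || pop$sd <= 0) {
      cs_stop("invalid spec: populations: sd (covariance scale) must be > 0",
              "value_error")
    }
  }
  pop_names <- vapply(populations, `[[`, "", "name")
  for (ef in effects) {
    if (!ef$population %in% pop_names) {
      cs_stop(sprintf("invalid spec: effects: unknown population '%s'",
                      ef$population), "value_error")
    }
    if (!ef$group %in% names(n_samples_per_group)) {
      cs_stop(sprintf("invalid spec: effects: unknown group '%s'", ef$group),
              "value_error")
    }
    if (!is.null(ef$abundance_multiplier) && ef$abundance_multiplier <= 0) {
      cs_stop("invalid spec: effects: abundance_multiplier must be > 0",
              "value_error")
    }
  }
  if (concentration <= 0) {
    cs_stop("invalid spec: concentration must be > 0", "value_error")
  }
  structure(list(populations = populations, base_abundance = base_abundance,
                 n_samples_per_group = n_samples_per_group,
                 cells_per_sample = as.integer(cells_per_sample),
                 effects = effects, concentration = concentration,
                 cofactor = cofactor, seed = as.integer(seed),
                 n_markers = p),
            class = "SimulationSpec")
}

#' Simulate a multi-sample cytometry Experiment with known ground truth
#'
#' Per sample: abundances are drawn `Dirichlet(concentration x
#' group-adjusted base)`, realized cell counts are multinomial, and cells
#' are drawn from the Gaussian populations in transformed space (with any
#' marker-shift effects applied). The raw assay is back-computed via
#' `cofactor * sinh(.)` so the FCS import path can be exercised end to end.
#' Fully seeded: the same spec gives bit-identical output.
#'
#' @param spec a [simulation_spec()].
#' @return a `Simulation`: list with `experiment` (an [Experiment] whose
#'   `cell_labels$truth` holds the ground-truth population per cell),
#'   `true_proportions` (samples x populations Dirichlet draws) and `spec`.
#' @export
simulate_experiment <- function(spec) {
  if (!inherits(spec, "SimulationSpec")) spec <- do.call(simulation_spec, spec)
  pops <- spec$populations
  pop_names <- vapply(pops, `[[`, "", "name")
  n_pop <- length(pops)
  groups <- names(spec$n_samples_per_group)
  sample_ids <- unlist(lapply(groups, function(g) {
    sprintf("%s_s%d", g, seq_len(spec$n_samples_per_group[[g]]))
  }))
  sample_group <- rep(groups, times = spec$n_samples_per_group)

  adj_base <- function(g) {
    b <- spec$base_abundance
    for (ef in spec$effects) {
      if (!is.null(ef$abundance_multiplier) && ef$group == g) {
        b[match(ef$population, pop_names)] <-
          b[match(ef$population, pop_names)] * ef$abundance_multiplier
      }
    }
    b / sum(b)
  }
  shift_for <- function(g, pop_i) {
    mu <- pops[[pop_i]]$mean
    for (ef in spec$effects) {
      if (!is.null(ef$shift) && ef$group == g &&
          ef$population == pop_names[pop_i]) {
        mu[ef$marker] <- mu[ef$marker] + ef$shift
      }
    }
    mu
  }

  true_props <- matrix(0, length(sample_ids), n_pop,
                       dimnames = list(sample_ids, pop_names))
  mats <- list(); labels <- list()
  for (si in seq_along(sample_ids)) {
    g <- sample_group[si]
    base <- adj_base(g)
    drawn <- with_seed(derive_seed(spec$seed, paste0("sample_", si)), {
      alpha <- spec$concentration * base
      gm <- rgamma(n_pop, shape = alpha, rate = 1)
      props <- gm / sum(gm)
      counts <- as.integer(rmultinom(1, spec$cells_per_sample, props))
      cells <- matrix(0, spec$cells_per_sample, spec$n_markers)
      lab <- rep(pop_names, counts)
      row0 <- 0
      for (pi in seq_len(n_pop)) {
        if (counts[pi] == 0) next
        mu <- shift_for(g, pi)
        block <- matrix(rnorm(counts[pi] * spec$n_markers,
                              mean = rep(mu, each = counts[pi]),
                              sd = pops[[pi]]$sd),
                        counts[pi], spec$n_markers)
        cells[row0 + seq_len(counts[pi]), ] <- block
        row0 <- row0 + counts[pi]
      }
      ord <- sample.int(spec$cells_per_sample)  # shuffle cell order
      list(props = props, cells = cells[ord, , drop = FALSE],
           lab = lab[ord])
    })
    true_props[si, ] <- drawn$props
    mats[[si]] <- drawn$cells
    labels[[si]] <- drawn$lab
  }
  transformed <- do.call(rbind, mats)
  colnames(transformed) <- sprintf("M%d", seq_len(spec$n_markers))
  raw <- spec$cofactor * sinh(transformed)

  role <- ifelse(seq_len(spec$n_markers) <= n_pop, "lineage", "functional")
  panel <- create_panel(sprintf("M%d", seq_len(spec$n_markers)),
                        role = role,
                        use_clustering = role == "lineage",
                        use_reduction = role == "lineage")
  samples <- create_sample_table(sample_ids, group = sample_group)
  exp <- build_experiment(raw, rep(sample_ids, each = spec$cells_per_sample),
                          panel, samples)
  exp@transformed <- transformed
  exp@cell_labels[["truth"]] <- unlist(labels, use.names = FALSE)
  exp <- add_provenance(exp, "simulate_experiment",
                        list(n_pop = n_pop, cells = spec$cells_per_sample,
                             concentration = spec$concentration),
                        seed = spec$seed)
  structure(list(experiment = exp, true_proportions = true_props,
                 spec = spec),
            class = "Simulation")
}

#' Write a simulated Experiment as an importable FCS dataset
#'
#' One FCS 3.1 file per sample (raw intensities), a panel CSV, a sample
#' metadata CSV and a JSON truth manifest (spec summary, true proportions,
#' per-cell ground-truth labels per file). Re-importing with
#' [import_dataset()] and the spec's cofactor reproduces the transformed
#' matrix to float32 precision. Deterministic: same simulation, same bytes.
#'
#' @param sim a `Simulation` from [simulate_experiment()].
#' @param out_dir output directory (created if needed).
#' @return list of written paths (`fcs`, `panel`, `samples`, `manifest`).
#' @export
write_simulation_fcs <- function(sim, out_dir) {
  stopifnot(inherits(sim, "Simulation"))
  exp <- sim$experiment
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    cs_stop(sprintf("cannot create output directory %s", out_dir), "io_error")
  }
  sample_ids <- exp@samples$sample_id
  fcs_paths <- character(0)
  truth_cells <- list()
  for (s in sample_ids) {
    sel <- exp@cell_sample == s
    path <- file.path(out_dir, paste0(s, ".fcs"))
    write_fcs(exp@raw[sel, , drop = FALSE],
              channel_ids = exp@panel$channel_id,
              channel_labels = exp@panel$marker_name, path = path)
    fcs_paths[s] <- path
    truth_cells[[s]] <- exp@cell_labels$truth[sel]
  }
  panel_path <- file.path(out_dir, "panel.csv")
  write.csv(exp@panel, panel_path, row.names = FALSE)
  samples_path <- file.path(out_dir, "samples.csv")
  write.csv(exp@samples, samples_path, row.names = FALSE)
  manifest_path <- file.path(out_dir, "truth_manifest.json")
  manifest <- list(
    seed = sim$spec$seed,
    cofactor = sim$spec$cofactor,
    cells_per_sample = sim$spec$cells_per_sample,
    concentration = sim$spec$concentration,
    base_abundance = sim$spec$base_abundance,
    populations = vapply(sim$spec$populations, `[[`, "", "name"),
    true_proportions = as.data.frame(sim$true_proportions),
    cell_population = truth_cells
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = FALSE)
  list(fcs = fcs_paths, panel = panel_path, samples = samples_path,
       manifest = manifest_path)
}
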