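#' Simulation configuration for an arrayed two-temperature screen
#'
#' Describes one synthetic query screen against an arrayed deletion library:
#' grid geometry, replicate structure, the two growth-condition labels
#' (reference first, cold second), and the noise model. Colony sizes are
#' log-normal: growth is multiplicative and sizes are positive, so all noise
#' terms act additively on the natural-log scale. Each physical plate (one
#' per temperature x replicate x library-plate) gets its own multiplicative
#' plate effect, which the downstream plate-median normalization is designed
#' to remove.
#'
#' @param n_genes Number of library genes (default 2000).
#' @param grid_rows,grid_cols Plate grid (default 32 x 48, the 1536 format).
#' @param n_replicates Technical replicates per temperature (default 3).
#' @param temperatures Ordered pair of condition labels, reference first
#'   (default `c("30C", "19C")`).
#' @param baseline_log_size_mean Mean log colony size, natural-log scale of
#'   arbitrary area units (default `log(500)`).
#' @param baseline_log_size_sd SD of a per-gene intrinsic growth offset,
#'   shared across temperatures and replicates (default 0.25). It models
#'   gene-to-gene baseline fitness variation and cancels in the NGR ratio.
#' @param plate_effect_sd SD of the per-physical-plate multiplicative effect,
#'   log scale (default 0.2).
#' @param colony_noise_sd Per-colony log-scale measurement/growth noise
#'   (default 0.35, i.e. ~0.5 on the log2 scale).
#' @param dropout_prob Probability a colony is missing (absent row), default
#'   0.02.
#' @param edge_penalty Multiplicative size factor applied to first/last rows
#'   (edge effect), default 1 = off.
#' @param planted_effects Tibble from [planted_effects()], or `NULL`.
#' @param gene_ids Optional character vector of library gene identifiers
#'   (length `n_genes`, unique); default ids are generated (`g0001`, ...).
#' @param allow_multiplate If `FALSE`, refuse configurations whose gene count
#'   exceeds one plate's capacity instead of spilling onto numbered plates.
#' @param seed Master seed for the pseudo-random stream.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       grid_rows = 32, grid_cols = 48,
                       n_replicates = 3,
                       temperatures = c("30C", "19C"),
                       baseline_log_size_mean = log(500),
                       baseline_log_size_sd = 0.25,
                       plate_effect_sd = 0.2,
                       colony_noise_sd = 0.35,
                       dropout_prob = 0.02,
                       edge_penalty = 1,
                       planted_effects = NULL,
                       gene_ids = NULL,
                       allow_multiplate = TRUE,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), grid_rows = as.integer(grid_rows),
    grid_cols = as.integer(grid_cols), n_replicates = as.integer(n_replicates),
    temperatures = as.character(temperatures),
    baseline_log_size_mean = baseline_log_size_mean,
    baseline_log_size_sd = baseline_log_size_sd,
    plate_effect_sd = plate_effect_sd,
    colony_noise_sd = colony_noise_sd,
    dropout_prob = dropout_prob,
    edge_penalty = edge_penalty,
    planted_effects = planted_effects,
    gene_ids = if (!is.null(gene_ids)) as.character(gene_ids),
    allow_multiplate = isTRUE(allow_multiplate),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1) stop_io("n_genes must be positive")
  if (cfg$grid_rows < 1 || cfg$grid_cols < 1) stop_io("grid must be positive")
  if (cfg$n_replicates < 1) stop_io("n_replicates must be positive")
  if (length(cfg$temperatures) != 2 || anyDuplicated(cfg$temperatures)) {
    stop_io("temperatures must be an ordered pair of distinct labels")
  }
  sds <- c(cfg$baseline_log_size_sd, cfg$plate_effect_sd, cfg$colony_noise_sd)
  if (any(sds < 0)) stop_io("all SD fields must be >= 0")
  if (cfg$dropout_prob < 0 || cfg$dropout_prob > 1) {
    stop_io("dropout_prob must be in [0, 1]")
  }
  if (cfg$edge_penalty <= 0) stop_io("edge_penalty must be > 0")
  capacity <- cfg$grid_rows * cfg$grid_cols
  if (!cfg$allow_multiplate && cfg$n_genes > capacity) {
    stop_io("configuration error: ", cfg$n_genes, " genes exceed single-plate",
            " capacity ", capacity, " and multi-plate mode is disabled")
  }
  if (!is.null(cfg$gene_ids)) {
    if (length(cfg$gene_ids) != cfg$n_genes ||
        anyDuplicated(cfg$gene_ids) > 0 || any(!nzchar(cfg$gene_ids))) {
      stop_io("gene_ids must be ", cfg$n_genes,
              " unique nonempty identifiers")
    }
  }
  if (!is.null(cfg$planted_effects)) {
    validate_planted_effects(cfg$planted_effects, sim_gene_ids(cfg))
  }
  cfg
}

sim_gene_ids <- function(cfg) {
  cfg$gene_ids %||%
    sprintf("g%0*d", nchar(as.character(cfg$n_genes)), seq_len(cfg$n_genes))
}

#' Declare planted fitness interactions for the simulator
#'
#' Each planted gene multiplies its expected colony size by
#' `factor_30` at the reference temperature and `factor_19` at the cold
#' temperature. Labels name the phenotype class the effect encodes:
#' `cs_suppressor` (cold-specific rescue, `factor_19 > factor_30`),
#' `cs_enhancer` / `reverter` (cold-specific sickness), `synthetic_sick`
#' (sick at both or at reference), `neutral` (both factors 1).
#'
#' @param gene_id Character vector of planted genes.
#' @param factor_30,factor_19 Positive fitness factors (recycled).
#' @param label Phenotype class label per gene (recycled); one of
#'   `synthetic_sick`, `cs_suppressor`, `cs_enhancer`, `reverter`, `neutral`.
#' @return A tibble with one row per planted gene.
#' @export
planted_effects <- function(gene_id, factor_30 = 1, factor_19 = 1,
                            label = "neutral") {
  tb <- tibble::tibble(gene_id = as.character(gene_id),
                       factor_30 = as.numeric(factor_30),
                       factor_19 = as.numeric(factor_19),
                       label = as.character(label))
  validate_planted_effects(tb)
  tb
}

planted_labels <- c("synthetic_sick", "cs_suppressor", "cs_enhancer",
                    "reverter", "neutral")

validate_planted_effects <- function(pe, universe = NULL) {
  if (any(pe$factor_30 <= 0) || any(pe$factor_19 <= 0)) {
    stop_io("fitness factors must be > 0")
  }
  if (!all(pe$label %in% planted_labels)) {
    stop_io("unknown planted-effect label(s): ",
            paste(setdiff(pe$label, planted_labels), collapse = ", "))
  }
  neutral <- pe$factor_30 == 1 & pe$factor_19 == 1
  if (any(neutral != (pe$label == "neutral"))) {
    stop_io("label 'neutral' must coincide exactly with factor_30 ==",
            " factor_19 == 1")
  }
  if (anyDuplicated(pe$gene_id) > 0) stop_io("duplicated planted gene_id")
  if (!is.null(universe) && !all(pe$gene_id %in% universe)) {
    stop_io("configuration error: planted gene(s) not in library: ",
            paste(setdiff(pe$gene_id, universe), collapse = ", "))
  }
  invisible(pe)
}

# Deterministic child seed for one (query, temperature, replicate) stream:
# a 31-based string hash folded into the master seed, mod a large prime.
# Adding a query therefore never perturbs another query's draws.
child_seed <- function(master, ...) {
  h <- as.numeric(master) %% 2147483563
  for (code in utf8ToInt(paste(..., sep = "|"))) {
    h <- (h * 31 + code) %% 2147483563
  }
  as.integer(h)
}

#' Simulate one arrayed two-temperature query screen
#'
#' Expected colony size for gene *g* on physical plate *p* at temperature
#' *t* is `exp(baseline_log_size_mean + gene_offset_g) * plate_effect_p *
#' fitness_factor(g, t)`, with independent log-normal colony noise on top,
#' and each colony dropped (absent row) with probability `dropout_prob`.
#' Identical seeds give bit-identical output.
#'
#' @param config A [sim_config()].
#' @param query_label Query-genotype label stamped into plate ids (default
#'   `"query"`).
#' @return A list with elements `colonies` (colony tibble, see
#'   [read_colony_table()]), `layout` (layout tibble), and `truth` (ground
#'   truth tibble: `gene_id`, `factor_30`, `factor_19`, `label`, covering
#'   exactly the planted genes; unplanted genes are implicitly neutral).
#' @export
simulate_screen <- function(config, query_label = "query") {
  config <- validate_sim_config(config)
  genes <- sim_gene_ids(config)
  capacity <- config$grid_rows * config$grid_cols
  n_plates <- ceiling(config$n_genes / capacity)

  idx <- seq_len(config$n_genes) - 1L
  lib_plate <- idx %/% capacity + 1L
  within <- idx %% capacity
  g_row <- within %/% config$grid_cols + 1L
  g_col <- within %% config$grid_cols + 1L

  f30 <- rep(1, config$n_genes)
  f19 <- rep(1, config$n_genes)
  pe <- config$planted_effects
  if (!is.null(pe) && nrow(pe) > 0) {
    m <- match(pe$gene_id, genes)
    f30[m] <- pe$factor_30
    f19[m] <- pe$factor_19
  }

  # per-gene intrinsic offset: shared across temperatures and replicates.
  # Standard normals are always drawn and scaled afterwards (rnorm with
  # sd = 0 consumes nothing), so changing one noise parameter never shifts
  # another parameter's random stream.
  set.seed(child_seed(config$seed, query_label, "gene_offsets"))
  gene_offset <- stats::rnorm(config$n_genes) * config$baseline_log_size_sd

  edge <- g_row == 1L | g_row == config$grid_rows
  pieces <- vector("list", 2L * config$n_replicates)
  k <- 0L
  for (temp_i in 1:2) {
    temp <- config$temperatures[temp_i]
    fac <- if (temp_i == 1L) f30 else f19
    for (rep_i in seq_len(config$n_replicates)) {
      set.seed(child_seed(config$seed, query_label, temp, rep_i))
      plate_eff <- stats::rnorm(n_plates) * config$plate_effect_sd
      noise <- stats::rnorm(config$n_genes) * config$colony_noise_sd
      log_size <- config$baseline_log_size_mean + gene_offset +
        plate_eff[lib_plate] + log(fac) + noise
      if (config$edge_penalty != 1) {
        log_size[edge] <- log_size[edge] + log(config$edge_penalty)
      }
      keep <- stats::runif(config$n_genes) >= config$dropout_prob
      k <- k + 1L
      pieces[[k]] <- tibble::tibble(
        plate_id = sprintf("%s_%s_r%d_p%d", query_label, temp, rep_i,
                           lib_plate)[keep],
        temperature = temp,
        replicate = rep_i,
        row = g_row[keep],
        col = g_col[keep],
        gene_id = genes[keep],
        size = exp(log_size)[keep]
      )
    }
  }
  colonies <- dplyr::bind_rows(pieces)

  layout <- tidyr::expand_grid(
    temperature = config$temperatures,
    replicate = seq_len(config$n_replicates),
    gi = seq_len(config$n_genes)
  )
  layout <- tibble::tibble(
    plate_id = sprintf("%s_%s_r%d_p%d", query_label, layout$temperature,
                       layout$replicate, lib_plate[layout$gi]),
    row = g_row[layout$gi],
    col = g_col[layout$gi],
    gene_id = genes[layout$gi]
  )
  attr(layout, "grid_rows") <- config$grid_rows
  attr(layout, "grid_cols") <- config$grid_cols

  truth <- if (is.null(pe)) {
    tibble::tibble(gene_id = character(), factor_30 = numeric(),
                   factor_19 = numeric(), label = character())
  } else {
    pe
  }
  list(colonies = colonies, layout = layout, truth = truth,
       query_label = query_label, config = config)
}

#' Simulate parallel query screens over a shared library
#'
#' Runs [simulate_screen()] once per query genotype (e.g. the five screens
#' taz1, rif1, S-rif1, taz1 rif1, taz1 S-rif1), sharing the gene universe and
#' layout geometry. Per-(query, temperature, replicate) random streams are
#' derived deterministically from the base seed, so adding or removing a
#' query never changes the others' data. A gene may be planted with
#' different effects in different screens — this is how reverter scenarios
#' (deleterious in the double/triple-query screens only) are constructed.
#'
#' @param base A [sim_config()]; its `planted_effects` are ignored in favour
#'   of `query_specs`.
#' @param query_specs Named list: query label -> [planted_effects()] tibble
#'   (or `NULL` for a screen with no planted effects). Must be non-empty with
#'   distinct labels.
#' @return Named list of [simulate_screen()] results, one per query.
#' @export
simulate_parallel_screens <- function(base, query_specs) {
  base <- validate_sim_config(base)
  if (length(query_specs) == 0) {
    stop_io("query_specs is empty: at least one query screen is required")
  }
  labels <- names(query_specs)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels) > 0) {
    stop_io("query_specs must be a named list with distinct, nonempty labels")
  }
  genes <- sim_gene_ids(base)
  out <- vector("list", length(labels))
  names(out) <- labels
  for (q in labels) {
    pe <- query_specs[[q]]
    if (!is.null(pe)) validate_planted_effects(pe, universe = genes)
    cfg <- base
    cfg$planted_effects <- pe
    out[[q]] <- simulate_screen(cfg, query_label = q)
  }
  out
}

#' Planted five-screen study design
#'
#' Builds the per-query planted-effect specification for the canonical
#' five-screen layout ([run_config()] roles): `n_per_class` cold-specific
#' suppressors (log2 NGR effect `+log2_effect` in the cold-sensitive query
#' screen), the same number of permissive-temperature synthetic-sick genes
#' (log2 NG30 effect `-log2_effect`), true reverters (log2 NGR
#' `-log2_effect` in the double and triple screens, neutral in the singles),
#' and "fake reverters" that are equally sick in the single-mutant screens —
#' the negative control the single-mutant filter must reject.
#'
#' @param n_genes Library size (default 2000).
#' @param n_per_class Planted genes per class (default 20).
#' @param log2_effect Planted effect magnitude on the log2 scale (default 3,
#'   i.e. fitness factors 8 and 1/8).
#' @return A list with `query_specs` (for [simulate_parallel_screens()] /
#'   [run_config()]) and `truth` (named list of planted gene-id vectors:
#'   `suppressors`, `synthetic_sick`, `reverters`, `fake_reverters`).
#' @export
planted_study_design <- function(n_genes = 2000, n_per_class = 20,
                                 log2_effect = 3) {
  if (4 * n_per_class > n_genes) stop_io("too many planted genes")
  genes <- sprintf("g%0*d", nchar(as.character(n_genes)), seq_len(n_genes))
  take <- function(i) genes[seq((i - 1) * n_per_class + 1, i * n_per_class)]
  sup <- take(1); sick <- take(2); rev_ <- take(3); fake <- take(4)
  up <- 2^log2_effect
  dn <- 2^(-log2_effect)
  specs <- list(
    cs_query = planted_effects(
      c(sup, sick),
      factor_30 = c(rep(1, n_per_class), rep(dn, n_per_class)),
      factor_19 = c(rep(up, n_per_class), rep(dn, n_per_class)),
      label = c(rep("cs_suppressor", n_per_class),
                rep("synthetic_sick", n_per_class))),
    suppressor_single = planted_effects(fake, 1, dn, "cs_enhancer"),
    sof_single = planted_effects(fake, 1, dn, "cs_enhancer"),
    double = planted_effects(c(rev_, fake), 1, dn, "reverter"),
    triple = planted_effects(c(rev_, fake), 1, dn, "reverter"))
  list(query_specs = specs,
       truth = list(suppressors = sup, synthetic_sick = sick,
                    reverters = rev_, fake_reverters = fake))
}

#' Write one simulated screen's outputs to a directory
#'
#' Emits `colonies.tsv`, `layout.tsv`, `truth.tsv` and a `manifest.yaml`
#' under `dir`, in the [plate-formats] dialects.
#'
#' @param screen A [simulate_screen()] result.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_screen <- function(screen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  colony_path <- file.path(dir, "colonies.tsv")
  write_colony_table(screen$colonies, colony_path)
  write_layout(screen$layout, file.path(dir, "layout.tsv"))
  write_tsv_commented(screen$truth, file.path(dir, "truth.tsv"))
  manifest <- list(
    query_label = screen$query_label,
    reference_temperature = screen$config$temperatures[1],
    cold_temperature = screen$config$temperatures[2],
    colony_tables = "colonies.tsv",
    layout = "layout.tsv"
  )
  write_manifest(manifest, file.path(dir, "manifest.yaml"))
}
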