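#' Build a validated pipeline run configuration
#'
#' The configuration is the single source of truth for a run: the input
#' screens (a simulation config plus per-query planted effects, or manifest
#' paths to on-disk colony tables), the hit-calling method, and every
#' threshold the classification depends on. Screens are threshold-sensitive,
#' so the effective configuration is always echoed into the run report.
#'
#' The five query roles mirror the screen design: `cs_query` (the
#' cold-sensitive query, e.g. taz1), `suppressor_single` (its suppressor,
#' e.g. rif1), `sof_single` (separation-of-function allele, e.g. S-rif1),
#' `double` and `triple` (the suppressed double/triple mutants).
#'
#' @param sim_config A [sim_config()] for simulated input, or `NULL` when
#'   reading manifests.
#' @param query_specs Named list role -> [planted_effects()] (simulated
#'   input only). Roles default to the five canonical labels.
#' @param manifests Named list role -> manifest path (file input only).
#' @param hit_method `"two_sd"` or `"percentile25"` (default `"two_sd"`).
#' @param suppressor_method Method for suppressor calling (default
#'   `"percentile25"`, the top-quartile rule).
#' @param similarity_fraction See [filter_query_specific()]; in (0, 1].
#' @param single_mutant_tolerance See [classify_reverters()]; > 0, SD units
#'   (default 2).
#' @param min_replicates See [aggregate_replicates()].
#' @param min_term_size See [enrich()].
#' @param annotation Optional annotation tibble for enrichment.
#' @param seed Master seed (overrides `sim_config$seed` when given).
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param ... Unknown keys are rejected by name (fail-fast validation).
#' @return A validated `run_config` list.
#' @export
run_config <- function(sim_config = NULL, query_specs = NULL,
                       manifests = NULL,
                       hit_method = "two_sd",
                       suppressor_method = "percentile25",
                       similarity_fraction = 0.5,
                       single_mutant_tolerance = 2,
                       min_replicates = 2,
                       min_term_size = 3,
                       annotation = NULL,
                       seed = NULL,
                       out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop_io("unknown configuration key(s): ",
            paste(names(extra), collapse = ", "))
  }
  if (is.null(sim_config) && is.null(manifests)) {
    stop_io("supply either sim_config (simulated run) or manifests")
  }
  if (!hit_method %in% c("two_sd", "percentile25")) {
    stop_io("hit_method must be two_sd or percentile25")
  }
  if (!suppressor_method %in% c("two_sd", "percentile25")) {
    stop_io("suppressor_method must be two_sd or percentile25")
  }
  if (similarity_fraction <= 0 || similarity_fraction > 1) {
    stop_io("similarity_fraction must be in (0, 1]")
  }
  if (single_mutant_tolerance <= 0) {
    stop_io("single_mutant_tolerance must be > 0")
  }
  if (min_replicates < 1) stop_io("min_replicates must be >= 1")
  if (min_term_size < 1) stop_io("min_term_size must be >= 1")
  if (!is.null(sim_config)) {
    if (!is.null(seed)) sim_config$seed <- as.integer(seed)
    sim_config <- validate_sim_config(sim_config)
  }
  roles <- c("cs_query", "suppressor_single", "sof_single", "double",
             "triple")
  if (is.null(query_specs) && !is.null(sim_config)) {
    query_specs <- stats::setNames(vector("list", 5), roles)
  }
  if (!is.null(query_specs) && !all(names(query_specs) %in% roles)) {
    stop_io("query_specs roles must be among: ", paste(roles, collapse = ", "))
  }
  if (!is.null(manifests)) {
    missing_roles <- setdiff(roles, names(manifests))
    if (length(missing_roles) > 0) {
      stop_io("manifests must name every query role; missing: ",
              paste(missing_roles, collapse = ", "))
    }
    absent <- manifests[!vapply(unlist(manifests), file.exists, logical(1))]
    if (length(absent) > 0) {
      stop_io("manifest file(s) not found: ",
              paste(unlist(absent), collapse = ", "))
    }
  }
  structure(list(
    sim_config = sim_config, query_specs = query_specs,
    manifests = manifests, hit_method = hit_method,
    suppressor_method = suppressor_method,
    similarity_fraction = similarity_fraction,
    single_mutant_tolerance = single_mutant_tolerance,
    min_replicates = min_replicates, min_term_size = min_term_size,
    annotation = annotation, out_dir = out_dir
  ), class = "run_config")
}

load_screen_from_manifest <- function(path) {
  m <- read_manifest(path)
  base <- dirname(path)
  layout <- if (!is.null(m$layout)) read_layout(file.path(base, m$layout))
  tabs <- lapply(file.path(base, m$colony_tables), read_colony_table,
                 layout = layout)
  list(colonies = dplyr::bind_rows(tabs), query_label = m$query_label,
       reference_temperature = m$reference_temperature,
       cold_temperature = m$cold_temperature)
}

write_stage_tsv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  write_tsv_commented(df, file.path(out_dir, name))
}

#' Run the full screen-analysis pipeline
#'
#' Orchestrates simulate (or load) -> score -> call hits -> classify ->
#' enrich as one deterministic run, producing every stage's table plus a run
#' report with row counts, QC exclusion tallies, per-screen distribution
#' summaries, the echoed configuration, and wall-clock per stage. At every
#' stage, genes in = genes out + genes excluded.
#'
#' Stage outputs (and `report.yaml`) are written to `config$out_dir` as TSVs
#' when an output directory is configured.
#'
#' @param config A [run_config()].
#' @return A list: `scores` (per-role gene-score tibbles), `suppressors`,
#'   `specific_negative_30` (query-specific negative hit tibble),
#'   `reverters` (classification tibble), `venn` (double vs triple negative
#'   hit partition), `enrichment` (per analysis, if annotation given), and
#'   `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  # ---- acquire screens -----------------------------------------------------
  if (!is.null(config$sim_config)) {
    screens <- simulate_parallel_screens(config$sim_config,
                                         config$query_specs)
    screens <- lapply(screens, function(s) {
      list(colonies = s$colonies, query_label = s$query_label,
           reference_temperature = s$config$temperatures[1],
           cold_temperature = s$config$temperatures[2], truth = s$truth)
    })
  } else {
    screens <- lapply(config$manifests, load_screen_from_manifest)
  }
  tick("acquire")

  # ---- score ---------------------------------------------------------------
  scores <- lapply(names(screens), function(role) {
    s <- screens[[role]]
    sc <- score_screen(s$colonies,
                       reference_temperature = s$reference_temperature,
                       cold_temperature = s$cold_temperature,
                       min_replicates = config$min_replicates,
                       query_label = role)
    write_stage_tsv(sc, config$out_dir, paste0("scores_", role, ".tsv"))
    sc
  })
  names(scores) <- names(screens)
  dist_summaries <- dplyr::bind_rows(lapply(names(scores), function(role) {
    dplyr::mutate(
      summarize_distribution(scores[[role]]$log2_ngr, "log2_ngr"),
      query = role, .before = 1)
  }))
  tick("score")

  # ---- suppressors of the cold-sensitive query -----------------------------
  suppressors <- classify_suppressors(scores$cs_query,
                                      method = config$suppressor_method)
  write_stage_tsv(attr(suppressors, "hits"), config$out_dir,
                  "hits_suppressors.tsv")

  # ---- query-specific negative interactions at 30C -------------------------
  neg30 <- call_hits(scores$cs_query, method = config$hit_method,
                     statistic_name = "log2_ng_30", direction = "negative")
  neg30_other <- call_hits(scores$suppressor_single,
                           method = config$hit_method,
                           statistic_name = "log2_ng_30",
                           direction = "negative")
  specific_neg30 <- filter_query_specific(
    neg30, scores$suppressor_single, hits_other = neg30_other,
    similarity_fraction = config$similarity_fraction)
  write_stage_tsv(specific_neg30, config$out_dir,
                  "hits_specific_negative_30.tsv")
  tick("call_hits")

  # ---- reverters and the double/triple Venn --------------------------------
  reverters <- classify_reverters(
    scores$double, scores$triple, scores$suppressor_single,
    scores$sof_single, method = config$hit_method,
    single_mutant_tolerance = config$single_mutant_tolerance)
  write_stage_tsv(reverters, config$out_dir, "classification_reverters.tsv")
  venn <- venn_partition(list(
    double = call_hits(scores$double, method = config$hit_method,
                       statistic_name = "log2_ngr",
                       direction = "negative")$gene_id,
    triple = call_hits(scores$triple, method = config$hit_method,
                       statistic_name = "log2_ngr",
                       direction = "negative")$gene_id))
  venn_tbl <- tibble::tibble(
    region = rep(names(venn), lengths(venn)),
    gene_id = unlist(venn, use.names = FALSE))
  write_stage_tsv(venn_tbl, config$out_dir, "venn_double_triple.tsv")
  tick("classify")

  # ---- enrichment ----------------------------------------------------------
  enrichment <- NULL
  if (!is.null(config$annotation)) {
    universe_of <- function(sc, stat) {
      sc$gene_id[is.finite(sc[[stat]])]
    }
    enrichment <- list(
      suppressors = enrich(as.character(suppressors), config$annotation,
                           universe_of(scores$cs_query, "log2_ngr"),
                           min_term_size = config$min_term_size),
      specific_negative_30 = enrich(
        specific_neg30$gene_id, config$annotation,
        universe_of(scores$cs_query, "log2_ng_30"),
        min_term_size = config$min_term_size),
      reverters = enrich(attr(reverters, "reverters"), config$annotation,
                         universe_of(scores$double, "log2_ngr"),
                         min_term_size = config$min_term_size)
    )
    for (nm in names(enrichment)) {
      write_stage_tsv(enrichment[[nm]], config$out_dir,
                      paste0("enrichment_", nm, ".tsv"))
    }
  }
  tick("enrich")

  # ---- report --------------------------------------------------------------
  qc_tally <- dplyr::bind_rows(lapply(names(scores), function(role) {
    sc <- scores[[role]]
    tibble::tibble(
      query = role,
      n_genes = nrow(sc),
      n_clean = sum(!nzchar(sc$qc_flags)),
      n_missing_ref = sum(grepl("MISSING_REF", sc$qc_flags)),
      n_missing_cold = sum(grepl("MISSING_COLD", sc$qc_flags)),
      n_zero_size = sum(grepl("ZERO_SIZE", sc$qc_flags)),
      n_low_replicates = sum(grepl("LOW_REPLICATES", sc$qc_flags)),
      n_finite_log2_ngr = sum(is.finite(sc$log2_ngr))
    )
  }))
  report <- list(
    package_version = as.character(utils::packageVersion("coldscreen")),
    config = list(
      hit_method = config$hit_method,
      suppressor_method = config$suppressor_method,
      similarity_fraction = config$similarity_fraction,
      single_mutant_tolerance = config$single_mutant_tolerance,
      min_replicates = config$min_replicates,
      min_term_size = config$min_term_size,
      seed = if (!is.null(config$sim_config)) config$sim_config$seed
    ),
    stage_counts = list(
      colonies_in = vapply(screens, function(s) nrow(s$colonies),
                           integer(1)),
      genes_scored = vapply(scores, nrow, integer(1)),
      suppressors = length(suppressors),
      negative_30_hits = nrow(neg30),
      negative_30_specific = nrow(specific_neg30),
      negative_30_filtered_out = nrow(attr(specific_neg30, "excluded")),
      reverter_candidates = nrow(reverters),
      reverters = length(attr(reverters, "reverters"))
    ),
    qc = qc_tally,
    distribution_summaries = dist_summaries,
    seconds_per_stage = timings
  )
  if (!is.null(config$out_dir)) {
    rep_out <- report
    rep_out$qc <- lapply(split(qc_tally, seq_len(nrow(qc_tally))), as.list)
    rep_out$distribution_summaries <-
      lapply(split(dist_summaries, seq_len(nrow(dist_summaries))), as.list)
    yaml::write_yaml(rep_out, file.path(config$out_dir, "report.yaml"))
  }
  list(scores = scores, suppressors = suppressors,
       specific_negative_30 = specific_neg30, reverters = reverters,
       venn = venn, enrichment = enrichment, report = report)
}
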