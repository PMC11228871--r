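#' Per-plate median normalization of colony sizes (NG)
#'
#' Normalized growth (NG) is a colony's size divided by the median size of
#' all non-missing colonies on the same physical plate. This removes the
#' multiplicative plate effect (incubator position, media batch, pinning
#' pressure) common to every colony on a plate; by construction the median
#' NG on each plate is 1. The plate median is computed over *all* measured
#' library colonies, including planted/hit genes: on a ~1536-colony plate a
#' handful of true interactors cannot move the median materially.
#'
#' Plates whose colonies are all missing, or whose median size is 0, cannot
#' be normalized; they are excluded with a warning.
#'
#' @param colonies Colony tibble (see [read_colony_table()]); may span many
#'   plates.
#' @return The input with an added `ng` column, restricted to non-missing
#'   colonies on normalizable plates.
#' @export
normalize_plates <- function(colonies) {
  measured <- colonies[!is.na(colonies$size), , drop = FALSE]
  if (nrow(measured) == 0) stop_io("no measured colonies to normalize")
  out <- measured |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::mutate(plate_median = stats::median(.data$size)) |>
    dplyr::ungroup()
  bad <- unique(out$plate_id[out$plate_median == 0])
  if (length(bad) > 0) {
    warning("excluding plate(s) with zero median size: ",
            paste(bad, collapse = ", "), call. = FALSE)
    out <- out[!(out$plate_id %in% bad), , drop = FALSE]
  }
  if (nrow(out) == 0) stop_io("all plates excluded (zero median)")
  out$ng <- out$size / out$plate_median
  dplyr::select(out, -"plate_median")
}

#' @rdname normalize_plates
#' @details `normalize_plate()` is the single-plate form: it takes the
#'   colonies of exactly one plate and returns their NG values in input
#'   order (`NA` for missing colonies).
#' @param plate_colonies Colony tibble of a single plate.
#' @export
normalize_plate <- function(plate_colonies) {
  if (length(unique(plate_colonies$plate_id)) > 1) {
    stop_io("normalize_plate expects colonies of a single plate")
  }
  sizes <- plate_colonies$size
  if (all(is.na(sizes))) stop_io("all colonies missing on plate")
  med <- stats::median(sizes, na.rm = TRUE)
  if (med == 0) stop_io("plate median size is 0; plate cannot be normalized")
  sizes / med
}

#' Aggregate replicate NG values per gene and temperature
#'
#' The replicate aggregate is the median across available replicate NG
#' values — robust to a single failed pinning. Genes observed in fewer than
#' `min_replicates` replicates at a temperature are aggregated anyway but
#' flagged `LOW_REPLICATES`.
#'
#' @param ng_tbl Output of [normalize_plates()] (needs `gene_id`,
#'   `temperature`, `replicate`, `ng`).
#' @param min_replicates Minimum replicates before the `LOW_REPLICATES` QC
#'   flag is raised (default 2).
#' @return Tibble: `gene_id`, `temperature`, `ng` (replicate median),
#'   `n_rep`, `low_replicates` (logical).
#' @export
aggregate_replicates <- function(ng_tbl, min_replicates = 2) {
  if (nrow(ng_tbl) == 0) stop_io("no NG values to aggregate")
  ng_tbl |>
    dplyr::group_by(.data$gene_id, .data$temperature) |>
    dplyr::summarise(n_rep = dplyr::n(),
                     ng = stats::median(.data$ng), .groups = "drop") |>
    dplyr::mutate(low_replicates = .data$n_rep < min_replicates)
}

#' Fill NGR and log2 fields of a gene-score table
#'
#' NGR = NG(cold) / NG(reference); NGR > 1 means relatively better growth in
#' the cold (candidate suppressor direction), NGR < 1 cold-specific
#' sickness. A gene with missing or zero reference NG has no NGR (flagged
#' `MISSING_REF` / `ZERO_SIZE`) but keeps its 30C-only interaction measure.
#'
#' @param scores Tibble with at least `ng_30` and `ng_19` columns.
#' @return The input with `ngr`, `log2_ng_30`, `log2_ng_19`, `log2_ngr`
#'   columns (re)computed.
#' @export
compute_ngr <- function(scores) {
  ok_ref <- !is.na(scores$ng_30) & scores$ng_30 > 0
  scores$ngr <- ifelse(ok_ref & !is.na(scores$ng_19),
                       scores$ng_19 / scores$ng_30, NA_real_)
  scores$log2_ng_30 <- ifelse(ok_ref, log2(scores$ng_30), NA_real_)
  scores$log2_ng_19 <- ifelse(!is.na(scores$ng_19), log2(scores$ng_19),
                              NA_real_)
  scores$log2_ngr <- ifelse(!is.na(scores$ngr), log2(scores$ngr), NA_real_)
  scores
}

qc_flag_string <- function(missing_ref, missing_cold, zero_size, low_rep) {
  flags <- cbind(MISSING_REF = missing_ref, MISSING_COLD = missing_cold,
                 ZERO_SIZE = zero_size, LOW_REPLICATES = low_rep)
  apply(flags, 1, function(r) paste(colnames(flags)[r], collapse = ";"))
}

#' Score one query screen: NG, NGR and log2 statistics per gene
#'
#' Runs the full scoring chain: per-plate median normalization
#' ([normalize_plates()]), replicate aggregation per gene and temperature
#' ([aggregate_replicates()]), then the cold-specificity ratio
#' ([compute_ngr()]). The order is fixed: NG is computed per colony, then
#' aggregated per genotype, then the ratio is taken (aggregate-then-ratio).
#'
#' @param colonies Colony tibble with `gene_id` resolved.
#' @param reference_temperature,cold_temperature Condition labels (defaults
#'   `"30C"`, `"19C"`).
#' @param min_replicates See [aggregate_replicates()].
#' @param query_label Label stamped into the output (default `"query"`).
#' @return A gene-score tibble: `gene_id`, `query_label`, `ng_30`, `ng_19`,
#'   `ngr`, `log2_ng_30`, `log2_ng_19`, `log2_ngr`, `n_rep_30`, `n_rep_19`,
#'   `qc_flags` (semicolon-joined subset of `MISSING_REF`, `MISSING_COLD`,
#'   `ZERO_SIZE`, `LOW_REPLICATES`; empty string if clean).
#' @export
score_screen <- function(colonies,
                         reference_temperature = "30C",
                         cold_temperature = "19C",
                         min_replicates = 2,
                         query_label = "query") {
  temps <- c(reference_temperature, cold_temperature)
  if (!all(temps %in% colonies$temperature)) {
    stop_io("colony table lacks temperature(s): ",
            paste(setdiff(temps, colonies$temperature), collapse = ", "))
  }
  if (all(is.na(colonies$gene_id))) {
    stop_io("gene_id unresolved: supply a layout to read_colony_table()")
  }
  ng <- normalize_plates(colonies[colonies$temperature %in% temps, ,
                                  drop = FALSE])
  agg <- aggregate_replicates(ng, min_replicates = min_replicates)

  ref <- agg[agg$temperature == reference_temperature, , drop = FALSE]
  cold <- agg[agg$temperature == cold_temperature, , drop = FALSE]
  genes <- sort(unique(agg$gene_id))
  i_ref <- match(genes, ref$gene_id)
  i_cold <- match(genes, cold$gene_id)

  scores <- tibble::tibble(
    gene_id = genes,
    query_label = query_label,
    ng_30 = ref$ng[i_ref],
    ng_19 = cold$ng[i_cold],
    n_rep_30 = ifelse(is.na(i_ref), 0L, ref$n_rep[i_ref]),
    n_rep_19 = ifelse(is.na(i_cold), 0L, cold$n_rep[i_cold])
  )
  scores <- compute_ngr(scores)
  low_rep <- (!is.na(i_ref) & ref$low_replicates[i_ref]) |
    (!is.na(i_cold) & cold$low_replicates[i_cold])
  scores$qc_flags <- qc_flag_string(
    missing_ref = is.na(scores$ng_30),
    missing_cold = is.na(scores$ng_19),
    zero_size = !is.na(scores$ng_30) & scores$ng_30 == 0,
    low_rep = low_rep
  )
  scores[, c("gene_id", "query_label", "ng_30", "ng_19", "ngr",
             "log2_ng_30", "log2_ng_19", "log2_ngr",
             "n_rep_30", "n_rep_19", "qc_flags")]
}

#' Summarize a log2 statistic's distribution
#'
#' Median and sample SD (n - 1 denominator) of the finite values of one
#' screen statistic — the quantities the outlier thresholds are built from.
#' The SD is mean-centered by default; `center = "median"` computes the
#' spread about the median instead (both are defensible readings of
#' "median and SDs"; the choice is recorded in the output).
#'
#' @param values Numeric vector (non-finite entries are excluded, counted).
#' @param statistic_name Name of the statistic summarized (e.g.
#'   `"log2_ngr"`).
#' @param center `"mean"` (default) or `"median"`: the centering used for
#'   the SD.
#' @return One-row tibble: `statistic_name`, `median`, `sd`, `n`,
#'   `n_nonfinite`, `sd_center`.
#' @export
summarize_distribution <- function(values, statistic_name = "log2_ngr",
                                   center = c("mean", "median")) {
  center <- match.arg(center)
  finite <- values[is.finite(values)]
  n <- length(finite)
  if (n < 2) stop_io("need >= 2 finite values to summarize a distribution")
  med <- stats::median(finite)
  s <- if (center == "mean") {
    stats::sd(finite)
  } else {
    sqrt(sum((finite - med)^2) / (n - 1))
  }
  tibble::tibble(statistic_name = statistic_name, median = med, sd = s,
                 n = n, n_nonfinite = length(values) - n, sd_center = center)
}
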