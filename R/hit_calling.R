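#' Choose the interaction statistic for an analysis goal
#'
#' Pure routing: the permissive-temperature interaction measure is log2 NG
#' at 30C (how a deletion changes the query's growth where the query is
#' healthy), while cold-specific effects are read from log2 NGR (the ratio
#' cancels any temperature-independent interaction).
#'
#' @param query_label Query-genotype label (recorded, not interpreted).
#' @param analysis_goal `"permissive_interaction"` or `"cold_specific"`.
#' @return `"log2_ng_30"` or `"log2_ngr"`.
#' @export
select_statistic <- function(query_label,
                             analysis_goal = c("cold_specific",
                                               "permissive_interaction")) {
  analysis_goal <- match.arg(analysis_goal)
  switch(analysis_goal,
         permissive_interaction = "log2_ng_30",
         cold_specific = "log2_ngr")
}

finite_statistic <- function(scores, statistic_name) {
  if (!statistic_name %in% names(scores)) {
    stop_io("unknown statistic: ", statistic_name)
  }
  v <- scores[[statistic_name]]
  ok <- is.finite(v)
  excluded <- tibble::tibble(
    gene_id = scores$gene_id[!ok],
    reason = paste0("non-finite ", statistic_name,
                    ifelse(nzchar(scores$qc_flags[!ok] %||% ""),
                           paste0(" (qc: ", scores$qc_flags[!ok], ")"), ""))
  )
  list(gene_id = scores$gene_id[ok], value = v[ok], excluded = excluded)
}

hit_tibble <- function(gene_id, value, query_label, statistic_name,
                       direction, method, threshold_used) {
  tibble::tibble(gene_id = gene_id, query_label = query_label,
                 statistic_name = statistic_name, value = value,
                 direction = direction, method = method,
                 threshold_used = threshold_used)
}

#' Call outlier hits by the 2-SD method
#'
#' A gene is a hit when its log2 statistic lies at least `n_sd` sample
#' standard deviations beyond the distribution center (the median of the
#' finite values; the SD's centering follows `sd_center`). Genes whose
#' statistic is undefined (QC-voided) are excluded before calling and
#' reported in the `excluded` attribute.
#'
#' @param scores Gene-score tibble from [score_screen()].
#' @param statistic_name One of `log2_ngr`, `log2_ng_30`, `log2_ng_19`.
#' @param direction `"positive"` (upper tail) or `"negative"` (lower tail).
#' @param n_sd Threshold in SD units (default 2).
#' @param sd_center Passed to [summarize_distribution()].
#' @param min_genes Minimum number of finite scores required (default 10).
#' @return Hit tibble (`gene_id`, `query_label`, `statistic_name`, `value`,
#'   `direction`, `method`, `threshold_used`), sorted by decreasing
#'   |deviation|; attributes `distribution_summary` and `excluded`.
#' @export
call_hits_two_sd <- function(scores, statistic_name = "log2_ngr",
                             direction = c("positive", "negative"),
                             n_sd = 2, sd_center = c("mean", "median"),
                             min_genes = 10) {
  direction <- match.arg(direction)
  fs <- finite_statistic(scores, statistic_name)
  if (length(fs$value) < min_genes) {
    stop_io("need >= ", min_genes, " finite scores; got ", length(fs$value))
  }
  summ <- summarize_distribution(fs$value, statistic_name,
                                 center = match.arg(sd_center))
  if (summ$sd == 0) {
    stop_io("degenerate distribution: sd = 0, outliers undefined")
  }
  thr <- if (direction == "positive") summ$median + n_sd * summ$sd
         else summ$median - n_sd * summ$sd
  sel <- if (direction == "positive") fs$value >= thr else fs$value <= thr
  ord <- order(-abs(fs$value[sel] - summ$median), fs$gene_id[sel])
  out <- hit_tibble(fs$gene_id[sel][ord], fs$value[sel][ord],
                    unique(scores$query_label)[1], statistic_name,
                    direction, "two_sd", thr)
  attr(out, "distribution_summary") <- summ
  attr(out, "excluded") <- fs$excluded
  out
}

#' Call hits by the top-25th-percentile method
#'
#' Takes the `k = ceiling(fraction * n)` most extreme genes in the requested
#' tail, rank-based (sort-and-slice, no quantile interpolation). Ties at the
#' k-th value are all included when that enlarges the list by at most
#' `ceiling(tie_slack_frac * n)` genes; otherwise ties are broken by
#' ascending `gene_id` — a deterministic, portable rule.
#'
#' @inheritParams call_hits_two_sd
#' @param fraction Tail fraction to select (default 0.25).
#' @param tie_slack_frac Maximum tie-driven enlargement as a fraction of n
#'   (default 0.01).
#' @param min_genes Minimum number of finite scores (default 4).
#' @return Hit tibble as in [call_hits_two_sd()]; `threshold_used` is the
#'   k-th (boundary) value.
#' @export
call_hits_percentile <- function(scores, statistic_name = "log2_ngr",
                                 direction = c("positive", "negative"),
                                 fraction = 0.25, tie_slack_frac = 0.01,
                                 min_genes = 4) {
  direction <- match.arg(direction)
  stopifnot(fraction > 0, fraction < 1)
  fs <- finite_statistic(scores, statistic_name)
  n <- length(fs$value)
  if (n < min_genes) {
    stop_io("need >= ", min_genes, " finite scores; got ", n)
  }
  k <- ceiling(fraction * n)
  sgn <- if (direction == "positive") -1 else 1
  ord <- order(sgn * fs$value, fs$gene_id)
  boundary <- fs$value[ord[k]]
  strictly_in <- if (direction == "positive") fs$value > boundary
                 else fs$value < boundary
  tied <- fs$value == boundary
  with_ties <- sum(strictly_in) + sum(tied)
  sel_idx <- if (with_ties <= k + ceiling(tie_slack_frac * n)) {
    which(strictly_in | tied)
  } else {
    ord[seq_len(k)]
  }
  o <- order(sgn * fs$value[sel_idx], fs$gene_id[sel_idx])
  sel_idx <- sel_idx[o]
  out <- hit_tibble(fs$gene_id[sel_idx], fs$value[sel_idx],
                    unique(scores$query_label)[1], statistic_name,
                    direction, "percentile25", boundary)
  attr(out, "excluded") <- fs$excluded
  out
}

#' Call hits by either method
#'
#' Thin dispatcher over [call_hits_two_sd()] and [call_hits_percentile()].
#'
#' @inheritParams call_hits_two_sd
#' @param method `"two_sd"` or `"percentile25"`.
#' @param ... Passed to the selected caller.
#' @export
call_hits <- function(scores, method = c("two_sd", "percentile25"),
                      statistic_name = "log2_ngr",
                      direction = c("positive", "negative"), ...) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  switch(method,
         two_sd = call_hits_two_sd(scores, statistic_name, direction, ...),
         percentile25 = call_hits_percentile(scores, statistic_name,
                                             direction, ...))
}
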