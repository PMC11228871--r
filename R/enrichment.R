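#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) when drawing `n_hits` genes without replacement from a universe
#' of `N` genes of which `K` carry the annotation. This is the one-sided
#' Fisher / over-representation p-value; it is computed through the stable
#' tail routine of [stats::phyper()].
#'
#' @param k Annotated genes among the hits.
#' @param n_hits Number of hit genes drawn.
#' @param K Annotated genes in the universe.
#' @param N Universe size.
#' @return P(X >= k), in (0, 1].
#' @export
hypergeometric_pvalue <- function(k, n_hits, K, N) {
  if (any(k < 0) || any(k > pmin(n_hits, K)) || any(n_hits > N) ||
      any(K > N) || any(N < 1)) {
    stop_io("hypergeometric bounds violated: need 0 <= k <= min(n_hits, K)",
            " and n_hits, K <= N")
  }
  stats::phyper(k - 1, K, N - K, n_hits, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate adjustment with monotonicity
#' enforcement; adjusted values are >= the raw values and preserve their
#' order. Thin validated wrapper over [stats::p.adjust()].
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop_io("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Ontology-term over-representation in a hit set
#'
#' For every annotation term with at least `min_term_size` annotated genes
#' in the universe, tests whether the hit set contains more term members
#' than expected by chance (upper-tail hypergeometric), then applies
#' Benjamini-Hochberg correction across the tested terms. The universe
#' should be the set of genes actually scored (post-QC) in the screen the
#' hits came from — conditioning on testability — and genes without any
#' annotation stay in it (they inform `N`). No ontology-graph propagation is
#' done: the annotation is treated as a flat, pre-slimmed term set.
#'
#' @param hit_set Character vector of hit gene ids; must be a subset of
#'   `universe`.
#' @param annotation Annotation tibble ([read_annotation()]).
#' @param universe Character vector of all testable gene ids.
#' @param min_term_size Smallest universe term size tested (default 3).
#' @return Tibble sorted by `p_value` then `term_id`: `term_id`,
#'   `term_name`, `k` (hits in term), `n_hits`, `K` (universe genes in
#'   term), `N`, `fold_enrichment`, `p_value`, `adjusted_p`.
#' @export
enrich <- function(hit_set, annotation, universe, min_term_size = 3) {
  hit_set <- unique(hit_set)
  universe <- unique(universe)
  stray <- setdiff(hit_set, universe)
  if (length(stray) > 0) {
    stop_io("hit gene(s) outside the universe: ",
            paste(stray, collapse = ", "))
  }
  if (nrow(annotation) == 0) stop_io("annotation is empty")
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  N <- length(universe)
  n_hits <- length(hit_set)

  terms <- ann |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(K = dplyr::n_distinct(.data$gene_id),
                     k = sum(unique(.data$gene_id) %in% hit_set),
                     .groups = "drop") |>
    dplyr::filter(.data$K >= min_term_size)
  if (nrow(terms) == 0) {
    return(tibble::tibble(term_id = character(), term_name = character(),
                          k = integer(), n_hits = integer(), K = integer(),
                          N = integer(), fold_enrichment = numeric(),
                          p_value = numeric(), adjusted_p = numeric()))
  }
  terms$n_hits <- n_hits
  terms$N <- N
  terms$p_value <- hypergeometric_pvalue(terms$k, n_hits, terms$K, N)
  terms$adjusted_p <- bh_adjust(terms$p_value)
  terms$fold_enrichment <- if (n_hits > 0) {
    (terms$k / n_hits) / (terms$K / N)
  } else {
    NA_real_
  }
  terms <- terms[order(terms$p_value, terms$term_id), , drop = FALSE]
  terms[, c("term_id", "term_name", "k", "n_hits", "K", "N",
            "fold_enrichment", "p_value", "adjusted_p")]
}
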