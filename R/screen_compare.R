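#' Filter a hit list down to query-specific interactions
#'
#' Removes from query A's hit list every gene that interacts "similarly"
#' with query B: same direction and at least `similarity_fraction` of A's
#' effect magnitude in B's screen, or an outright same-direction hit in B.
#' This is the screen-comparison step that separates, e.g., interactions
#' specific to the telomere-entanglement query from those shared with its
#' suppressor query. Genes unscored in B cannot be assessed and are
#' retained, with a note in the `excluded` attribute's companion
#' `unassessed` attribute.
#'
#' @param hits_primary Hit tibble for query A ([call_hits()] output).
#' @param scores_other Gene-score tibble for query B; must contain the
#'   statistic A's hits were called on.
#' @param hits_other Optional hit tibble for query B on the same statistic
#'   (any direction); same-direction hits in B are always "similar".
#' @param similarity_fraction Fraction of A's effect magnitude that makes
#'   B's effect "similar" (default 0.5). Recorded in the output attributes.
#' @return Filtered hit tibble; attributes `excluded` (gene_id, reason) and
#'   `similarity_fraction`.
#' @export
filter_query_specific <- function(hits_primary, scores_other,
                                  hits_other = NULL,
                                  similarity_fraction = 0.5) {
  stat <- unique(hits_primary$statistic_name)
  if (length(stat) != 1) stop_io("hits_primary mixes statistics")
  if (!stat %in% names(scores_other)) {
    stop_io("statistic mismatch: ", stat, " absent from the other screen")
  }
  if (!is.null(hits_other) && !all(hits_other$statistic_name == stat)) {
    stop_io("statistic mismatch between hit lists")
  }
  v_other <- scores_other[[stat]][match(hits_primary$gene_id,
                                        scores_other$gene_id)]
  same_dir <- sign(v_other) == sign(hits_primary$value)
  similar <- !is.na(v_other) & same_dir &
    abs(v_other) >= similarity_fraction * abs(hits_primary$value)
  if (!is.null(hits_other)) {
    dir_other <- hits_other$direction[match(hits_primary$gene_id,
                                            hits_other$gene_id)]
    similar <- similar |
      (!is.na(dir_other) & dir_other == hits_primary$direction)
  }
  unassessed <- is.na(v_other)
  out <- hits_primary[!similar, , drop = FALSE]
  attr(out, "excluded") <- tibble::tibble(
    gene_id = hits_primary$gene_id[similar],
    reason = sprintf("similar interaction in other screen (%s = %.4g)",
                     stat, v_other[similar])
  )
  attr(out, "unassessed") <- hits_primary$gene_id[unassessed]
  attr(out, "similarity_fraction") <- similarity_fraction
  out
}

#' Classify cold-sensitivity suppressors in a query screen
#'
#' Suppressors are genes whose deletion rescues the query's cold-specific
#' growth defect: positive-direction outliers on log2 NGR by the configured
#' calling method.
#'
#' @param scores Gene-score tibble for the cold-sensitive query screen.
#' @param method,... Passed to [call_hits()].
#' @return Character vector of suppressor gene ids, with the underlying hit
#'   tibble in attribute `hits`.
#' @export
classify_suppressors <- function(scores, method = "percentile25", ...) {
  hits <- call_hits(scores, method = method, statistic_name = "log2_ngr",
                    direction = "positive", ...)
  out <- hits$gene_id
  attr(out, "hits") <- hits
  out
}

#' Classify mitotic-function reverters across four screens
#'
#' A reverter abolishes the suppression of the query's cold sensitivity
#' without harming the corresponding single mutants. Operationally, a gene
#' is a reverter iff it is (i) a negative-direction log2 NGR hit in the
#' double-query screen AND (ii) in the triple-query (separation-of-function)
#' screen — the intersection of the two hit lists — AND is quiet in both
#' single-mutant screens: (iii)/(iv) not a hit in either direction there and
#' |log2 NGR| within `single_mutant_tolerance` SDs of that screen's
#' distribution. Genes lacking a score in any required screen are reported
#' `unclassifiable`, never silently dropped.
#'
#' @param double_scores,triple_scores Gene-score tibbles for the two
#'   suppressed-query screens (e.g. taz1 rif1 and taz1 S-rif1).
#' @param single1_scores,single2_scores Gene-score tibbles for the matching
#'   single-mutant screens (e.g. rif1 and S-rif1).
#' @param method,... Hit-calling method and options ([call_hits()]).
#' @param single_mutant_tolerance Quiet-in-singles band, in SD units of each
#'   single screen's log2 NGR distribution (default 2, aligning "does not
#'   affect the single mutant" with the 2-SD outlier definition; a 1-SD band
#'   would reject ~32 percent of genuinely null genes per screen under
#'   Gaussian replicate noise, whatever the noise magnitude).
#' @return Tibble over all candidate genes (negative hits in either
#'   suppressed screen): `gene_id`, `class` (`reverter`, `none`, or
#'   `unclassifiable`), `evidence`, `exclusion_reasons`. The reverter gene
#'   set is in attribute `reverters`.
#' @export
classify_reverters <- function(double_scores, triple_scores,
                               single1_scores, single2_scores,
                               method = "two_sd",
                               single_mutant_tolerance = 2, ...) {
  screens <- list(double = double_scores, triple = triple_scores,
                  single1 = single1_scores, single2 = single2_scores)
  for (nm in names(screens)) {
    if (is.null(screens[[nm]]) || !"log2_ngr" %in% names(screens[[nm]])) {
      stop_io("missing or unscored screen: ", nm)
    }
  }
  hits_dbl <- call_hits(double_scores, method = method,
                        statistic_name = "log2_ngr",
                        direction = "negative", ...)
  hits_tpl <- call_hits(triple_scores, method = method,
                        statistic_name = "log2_ngr",
                        direction = "negative", ...)
  # a single-mutant screen with zero spread has, by definition, no outliers
  hits_or_none <- function(s, dir) {
    tryCatch(call_hits(s, method = method, statistic_name = "log2_ngr",
                       direction = dir, ...)$gene_id,
             error = function(e) {
               if (grepl("degenerate", conditionMessage(e))) character()
               else stop(e)
             })
  }
  single_hit_sets <- lapply(list(single1_scores, single2_scores), function(s) {
    unique(c(hits_or_none(s, "negative"), hits_or_none(s, "positive")))
  })
  single_sd <- vapply(list(single1_scores, single2_scores), function(s) {
    summarize_distribution(s$log2_ngr, "log2_ngr")$sd
  }, numeric(1))

  candidates <- sort(union(hits_dbl$gene_id, hits_tpl$gene_id))
  res <- lapply(candidates, function(g) {
    reasons <- character()
    evid <- character()
    in_dbl <- g %in% hits_dbl$gene_id
    in_tpl <- g %in% hits_tpl$gene_id
    if (in_dbl) evid <- c(evid, "negative log2_ngr hit in double screen")
    if (!in_dbl) reasons <- c(reasons, "not a hit in double screen")
    if (in_tpl) evid <- c(evid, "negative log2_ngr hit in triple screen")
    if (!in_tpl) reasons <- c(reasons, "not a hit in triple screen")

    unclass <- FALSE
    for (i in 1:2) {
      s <- list(single1_scores, single2_scores)[[i]]
      v <- s$log2_ngr[match(g, s$gene_id)]
      if (length(v) == 0 || !is.finite(v)) {
        unclass <- TRUE
        reasons <- c(reasons, sprintf("no finite log2_ngr in single screen %d",
                                      i))
      } else {
        if (g %in% single_hit_sets[[i]]) {
          reasons <- c(reasons,
                       sprintf("affects single mutant %d (outlier)", i))
        } else if (abs(v) > single_mutant_tolerance * single_sd[i]) {
          reasons <- c(reasons,
                       sprintf("affects single mutant %d (|log2_ngr| = %.3g > %.3g)",
                               i, abs(v), single_mutant_tolerance * single_sd[i]))
        } else {
          evid <- c(evid, sprintf("quiet in single screen %d (log2_ngr = %.3g)",
                                  i, v))
        }
      }
    }
    cls <- if (unclass && in_dbl && in_tpl) "unclassifiable"
           else if (length(reasons) == 0) "reverter" else "none"
    tibble::tibble(gene_id = g, class = cls,
                   evidence = paste(evid, collapse = "; "),
                   exclusion_reasons = paste(reasons, collapse = "; "))
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(gene_id = character(), class = character(),
                          evidence = character(),
                          exclusion_reasons = character())
  }
  attr(out, "reverters") <- out$gene_id[out$class == "reverter"]
  attr(out, "single_mutant_tolerance") <- single_mutant_tolerance
  out
}

#' Exact disjoint Venn partition of named gene sets
#'
#' Decomposes >= 2 named sets into their nonempty exclusive regions. Region
#' names join the member set labels with `&` (e.g. `"A&B"` is the genes in
#' exactly A and B).
#'
#' @param named_sets Named list of character vectors.
#' @return Named list: region label -> sorted gene character vector. The
#'   regions are disjoint and their union is the union of the inputs.
#' @export
venn_partition <- function(named_sets) {
  if (length(named_sets) < 2) stop_io("need >= 2 sets")
  labels <- names(named_sets)
  if (is.null(labels) || any(!nzchar(labels))) stop_io("sets must be named")
  universe <- sort(unique(unlist(named_sets)))
  if (length(universe) == 0) return(list())
  membership <- vapply(named_sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, labels))
  region <- apply(membership, 1, function(r) {
    paste(labels[r], collapse = "&")
  })
  split(universe, region)
}
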