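#!/usr/bin/env Rscript
# Stage 4 — comparative classification across the five screens:
#   * cold-sensitivity suppressors of the query (positive log2 NGR tail);
#   * query-specific synthetic-sick interactors at 30C (negative log2 NG30
#     hits, minus genes interacting similarly with the suppressor single
#     mutant);
#   * reverters: genes whose deletion abolishes the suppression in BOTH the
#     double and triple screens while leaving the single mutants untouched;
#   * the Venn partition of the double/triple negative hit lists.
# Planted ground truth from stage 1 is used only to report recovery.

suppressPackageStartupMessages(library(coldscreen))

sc <- lapply(c(cs_query = "cs_query", suppressor_single = "suppressor_single",
               sof_single = "sof_single", double = "double",
               triple = "triple"),
             function(r) read_gene_scores(
               file.path("results", paste0("scores_", r, ".tsv"))))
truth <- utils::read.delim("results/planted_truth.tsv", comment.char = "#")

sup <- classify_suppressors(sc$cs_query, method = "two_sd")
write_tsv_commented(attr(sup, "hits"), "results/class_suppressors.tsv")

neg30 <- call_hits_two_sd(sc$cs_query, "log2_ng_30", "negative")
neg30_other <- call_hits_two_sd(sc$suppressor_single, "log2_ng_30",
                                "negative")
specific <- filter_query_specific(neg30, sc$suppressor_single,
                                  hits_other = neg30_other)
write_tsv_commented(specific, "results/class_specific_negative_30.tsv")

rev_cl <- classify_reverters(sc$double, sc$triple, sc$suppressor_single,
                             sc$sof_single, method = "two_sd")
write_tsv_commented(rev_cl, "results/class_reverters.tsv")

venn <- venn_partition(list(
  double = call_hits_two_sd(sc$double, "log2_ngr", "negative")$gene_id,
  triple = call_hits_two_sd(sc$triple, "log2_ngr", "negative")$gene_id))
write_tsv_commented(
  tibble::tibble(region = rep(names(venn), lengths(venn)),
                 gene_id = unlist(venn, use.names = FALSE)),
  "results/venn_double_triple.tsv")

tr <- function(cls) truth$gene_id[truth$class == cls]
revs <- attr(rev_cl, "reverters")
cat(sprintf("suppressors called:       %3d (planted recovery %.0f%%)\n",
            length(sup), 100 * mean(tr("suppressors") %in% sup)))
cat(sprintf("specific negative @30C:   %3d (planted recovery %.0f%%, %d filtered as shared)\n",
            nrow(specific),
            100 * mean(tr("synthetic_sick") %in% specific$gene_id),
            nrow(attr(specific, "excluded"))))
cat(sprintf("reverters:                %3d (planted recovery %.0f%%; fake reverters let through: %d)\n",
            length(revs), 100 * mean(tr("reverters") %in% revs),
            sum(tr("fake_reverters") %in% revs)))
cat(sprintf("venn regions (double/triple negatives): %s\n",
            paste(sprintf("%s=%d", names(venn), lengths(venn)),
                  collapse = ", ")))
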