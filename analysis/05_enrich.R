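#!/usr/bin/env Rscript
# Stage 5 — ontology over-representation in the classified gene sets.
#
# Real screens would use a curated GO-slim association table; here a
# SYNTHETIC annotation is generated alongside the simulation so the stage is
# runnable end to end: planted suppressors are concentrated in a "DNA
# replication/repair"-style term, planted reverters in a "lipid
# metabolism"-style term, and the remaining genes are spread over background
# terms. One-sided hypergeometric test per term, BH-adjusted.

suppressPackageStartupMessages(library(coldscreen))

set.seed(20260923)
truth <- utils::read.delim("results/planted_truth.tsv", comment.char = "#")
sup_sc <- read_gene_scores("results/scores_cs_query.tsv")
dbl_sc <- read_gene_scores("results/scores_double.tsv")
universe_ngr <- sup_sc$gene_id[is.finite(sup_sc$log2_ngr)]

tr <- function(cls) truth$gene_id[truth$class == cls]
background <- setdiff(sup_sc$gene_id, truth$gene_id)
mk_term <- function(term_id, term_name, genes) {
  tibble::tibble(gene_id = genes, term_id = term_id, term_name = term_name)
}
annotation <- dplyr::bind_rows(
  mk_term("SYN:0001", "DNA replication and repair (synthetic)",
          c(tr("suppressors"), sample(background, 40))),
  mk_term("SYN:0002", "lipid metabolic process (synthetic)",
          c(tr("reverters"), sample(background, 40))),
  mk_term("SYN:0003", "transcription regulation (synthetic)",
          c(tr("synthetic_sick"), sample(background, 60))),
  mk_term("SYN:0004", "cytoskeleton organization (synthetic)",
          sample(background, 80)),
  mk_term("SYN:0005", "vesicle transport (synthetic)",
          sample(background, 80)))
write_annotation(annotation, "results/annotation_synthetic.tsv")

hits <- list(
  suppressors = utils::read.delim("results/class_suppressors.tsv",
                                  comment.char = "#")$gene_id,
  reverters = {
    cl <- utils::read.delim("results/class_reverters.tsv",
                            comment.char = "#")
    cl$gene_id[cl$class == "reverter"]
  })

for (nm in names(hits)) {
  res <- enrich(intersect(hits[[nm]], universe_ngr), annotation,
                universe_ngr)
  write_tsv_commented(res, file.path("results",
                                     paste0("enrichment_", nm, ".tsv")))
  top <- res[1, ]
  cat(sprintf(
    "%-12s n=%3d | top term %s '%s': k=%d/K=%d, p=%.3g (adj %.3g)\n",
    nm, length(hits[[nm]]), top$term_id, top$term_name, top$k, top$K,
    top$p_value, top$adjusted_p))
}
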