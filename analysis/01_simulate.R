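#!/usr/bin/env Rscript
# Stage 1 — generate the five parallel query screens.
#
# Emulates the screen design: a 2,000-gene arrayed deletion library crossed
# into five query genotypes (the cold-sensitive query, its suppressor, the
# separation-of-function allele, and the suppressed double/triple mutants),
# grown at 30C and 19C in technical triplicate on 32 x 48 plates, with
# multiplicative plate effects, log-normal colony noise (0.5 on the log2
# scale) and 2% colony dropout. Known interactions are planted: 20
# cold-specific suppressors, 20 permissive-temperature synthetic-sick genes,
# 20 true reverters and 20 "fake" reverters that are also sick in the
# single-mutant screens.

suppressPackageStartupMessages(library(coldscreen))

seed <- 20260923
out_root <- "results/screens"

design <- planted_study_design(n_genes = 2000, n_per_class = 20,
                               log2_effect = 3)
base <- sim_config(n_genes = 2000, colony_noise_sd = 0.5 * log(2),
                   seed = seed)
screens <- simulate_parallel_screens(base, design$query_specs)

for (role in names(screens)) {
  write_screen(screens[[role]], file.path(out_root, role))
  cat(sprintf("%-18s %6d colonies, %d planted effects\n", role,
              nrow(screens[[role]]$colonies), nrow(screens[[role]]$truth)))
}

truth_tbl <- tibble::tibble(
  gene_id = unlist(design$truth, use.names = FALSE),
  class = rep(names(design$truth), lengths(design$truth)))
write_tsv_commented(truth_tbl, "results/planted_truth.tsv")
cat("planted ground truth ->", "results/planted_truth.tsv", "\n")
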