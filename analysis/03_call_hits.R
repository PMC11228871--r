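#!/usr/bin/env Rscript
# Stage 3 — call outlier genes in each screen by both methods.
#
# Cold-specific interactions are read from log2 NGR; interactions at the
# permissive temperature from log2 NG(30C). The top-25th-percentile caller
# compiles each tail's top quartile; the 2-SD caller takes genes beyond two
# standard deviations from the distribution median.

suppressPackageStartupMessages(library(coldscreen))

roles <- c("cs_query", "suppressor_single", "sof_single", "double", "triple")
summaries <- list()

for (role in roles) {
  sc <- read_gene_scores(file.path("results",
                                   paste0("scores_", role, ".tsv")))
  for (goal in c("cold_specific", "permissive_interaction")) {
    stat <- select_statistic(role, goal)
    for (dir in c("positive", "negative")) {
      h2 <- call_hits_two_sd(sc, stat, dir)
      hp <- call_hits_percentile(sc, stat, dir)
      write_tsv_commented(
        h2, file.path("results",
                      sprintf("hits_%s_%s_%s_two_sd.tsv", role, stat, dir)))
      write_tsv_commented(
        hp, file.path("results",
                      sprintf("hits_%s_%s_%s_pct25.tsv", role, stat, dir)))
      summaries[[length(summaries) + 1]] <-
        dplyr::mutate(attr(h2, "distribution_summary"), query = role,
                      direction = dir, n_two_sd = nrow(h2),
                      n_pct25 = nrow(hp), .before = 1)
    }
  }
  cat(sprintf("%-18s: hit tables written for both statistics/methods\n",
              role))
}

write_tsv_commented(dplyr::bind_rows(summaries),
                    "results/distribution_summaries.tsv")
cat("2-SD thresholds derive from the medians/SDs in",
    "results/distribution_summaries.tsv\n")
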