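#!/usr/bin/env Rscript
# Stage 2 — score every screen: per-plate median NG, replicate-aggregated
# per-gene NG at each temperature, then NGR = NG(19C)/NG(30C) and the log2
# statistics the outlier calling operates on. Reads the stage-1 manifests.

suppressPackageStartupMessages(library(coldscreen))

roles <- c("cs_query", "suppressor_single", "sof_single", "double", "triple")

for (role in roles) {
  m <- read_manifest(file.path("results/screens", role, "manifest.yaml"))
  base <- file.path("results/screens", role)
  layout <- read_layout(file.path(base, m$layout))
  colonies <- dplyr::bind_rows(
    lapply(file.path(base, m$colony_tables), read_colony_table,
           layout = layout))
  sc <- score_screen(colonies,
                     reference_temperature = m$reference_temperature,
                     cold_temperature = m$cold_temperature,
                     query_label = m$query_label)
  write_tsv_commented(sc, file.path("results",
                                    paste0("scores_", role, ".tsv")))
  ds <- summarize_distribution(sc$log2_ngr, "log2_ngr")
  cat(sprintf(
    "%-18s %4d genes | log2 NGR median %+.3f, sd %.3f | %d QC-flagged\n",
    role, nrow(sc), ds$median, ds$sd, sum(nzchar(sc$qc_flags))))
}
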