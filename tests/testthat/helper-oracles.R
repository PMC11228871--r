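# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive each quantity by direct enumeration, not by
# calling the package's own code paths.

# Minimal gene-score table around a vector of statistic values.
make_scores <- function(values, statistic = "log2_ngr",
                        gene_id = sprintf("g%03d", seq_along(values)),
                        query_label = "q") {
  tb <- tibble::tibble(gene_id = gene_id, query_label = query_label,
                       qc_flags = "")
  tb[[statistic]] <- values
  tb
}

# Brute-force two-SD outlier selection: center = median, sd = mean-centered
# sample sd, both computed from first principles.
oracle_two_sd <- function(gene_id, values, direction, n_sd = 2) {
  ok <- is.finite(values)
  gene_id <- gene_id[ok]; values <- values[ok]
  n <- length(values)
  ctr <- sort(values)[c(ceiling(n / 2), floor(n / 2) + 1)]
  ctr <- mean(ctr)
  s <- sqrt(sum((values - mean(values))^2) / (n - 1))
  if (direction == "positive") {
    sort(gene_id[values >= ctr + n_sd * s])
  } else {
    sort(gene_id[values <= ctr - n_sd * s])
  }
}

# Brute-force top-quartile selection with the package's documented tie rule,
# implemented by explicit sort-and-slice.
oracle_percentile <- function(gene_id, values, direction, fraction = 0.25,
                              tie_slack_frac = 0.01) {
  ok <- is.finite(values)
  gene_id <- gene_id[ok]; values <- values[ok]
  n <- length(values)
  k <- ceiling(fraction * n)
  df <- data.frame(gene_id, values)
  df <- if (direction == "positive") {
    df[order(-df$values, df$gene_id), ]
  } else {
    df[order(df$values, df$gene_id), ]
  }
  boundary <- df$values[k]
  tied_all <- df[df$values == boundary, ]
  strictly <- if (direction == "positive") df$values > boundary
              else df$values < boundary
  if (sum(strictly) + nrow(tied_all) <= k + ceiling(tie_slack_frac * n)) {
    sort(df$gene_id[strictly | df$values == boundary])
  } else {
    sort(df$gene_id[seq_len(k)])
  }
}

# Exhaustive hypergeometric tail: enumerate every n_hits-subset of an
# N-gene universe and count those containing >= k of the K annotated genes.
oracle_hyper_tail <- function(k, n_hits, K, N) {
  subsets <- utils::combn(N, n_hits)
  ann <- seq_len(K)  # w.l.o.g. the first K genes carry the annotation
  mean(apply(subsets, 2, function(s) sum(s %in% ann) >= k))
}

# A tiny deterministic colony table: one plate, given sizes.
make_plate <- function(sizes, plate_id = "p1", temperature = "30C",
                       replicate = 1L) {
  n <- length(sizes)
  tibble::tibble(plate_id = plate_id, temperature = temperature,
                 replicate = replicate, row = 1L, col = seq_len(n),
                 gene_id = sprintf("g%03d", seq_len(n)), size = sizes)
}

# Raw TSV writer that bypasses the package's validation (for building
# deliberately malformed files).
write_tsv_commented_for_test <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

# Noise-free simulation config for exactness tests.
quiet_config <- function(n_genes = 60, seed = 1, ...) {
  sim_config(n_genes = n_genes, grid_rows = 6, grid_cols = 10,
             baseline_log_size_sd = 0, plate_effect_sd = 0,
             colony_noise_sd = 0, dropout_prob = 0, seed = seed, ...)
}
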