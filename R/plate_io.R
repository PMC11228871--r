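#' @title Plate-data file formats
#' @description
#' All on-disk tables are UTF-8 tab-separated values with a header row and
#' `#` comment lines. Coordinates are 1-based `(row, col)`, following plate
#' robotics convention. Temperatures are opaque condition labels (`"30C"`,
#' `"19C"`); the pipeline never does arithmetic on them.
#'
#' * colony table: `plate_id, temperature, replicate, row, col, gene_id, size`
#'   (an empty `size` field is a missing colony; missing colonies may equally
#'   be absent rows)
#' * layout: `plate_id, row, col, gene_id`, with grid dimensions recorded in
#'   `# grid_rows:` / `# grid_cols:` header comments
#' * annotation (minimal GAF-like): `gene_id, term_id, term_name`
#' @name plate-formats
NULL

stop_io <- function(...) stop(..., call. = FALSE)

read_tsv_commented <- function(path, col_names) {
  if (!file.exists(path)) stop_io("file does not exist: ", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE, quote = "")
  missing_cols <- setdiff(col_names, names(df))
  if (length(missing_cols) > 0) {
    stop_io("missing required column(s) in ", path, ": ",
            paste(missing_cols, collapse = ", "))
  }
  tibble::as_tibble(df)
}

parse_int_col <- function(x, name, path) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) | as.numeric(x) != v)
  if (length(bad) > 0) {
    stop_io("malformed ", name, " at record ", bad[1], " of ", path,
            ": '", x[bad[1]], "' is not an integer")
  }
  v
}

#' Read a colony-size measurement table
#'
#' @param path Path to a colony table TSV (see [plate-formats]).
#' @param layout Optional layout tibble from [read_layout()]; used to resolve
#'   `gene_id` when the table lacks that column. When both the table and the
#'   layout carry a `gene_id` for a position and they disagree, that is an
#'   integrity error (no silent precedence).
#' @return A tibble with columns `plate_id`, `temperature`, `replicate`,
#'   `row`, `col`, `gene_id`, `size` (`NA` size = missing colony).
#' @export
read_colony_table <- function(path, layout = NULL) {
  need <- c("plate_id", "temperature", "replicate", "row", "col", "size")
  df <- read_tsv_commented(path, need)
  out <- tibble::tibble(
    plate_id = df$plate_id,
    temperature = df$temperature,
    replicate = parse_int_col(df$replicate, "replicate", path),
    row = parse_int_col(df$row, "row", path),
    col = parse_int_col(df$col, "col", path),
    gene_id = if ("gene_id" %in% names(df)) df$gene_id else NA_character_
  )
  size_raw <- df$size
  size <- suppressWarnings(as.numeric(size_raw))
  bad <- which(is.na(size) & size_raw != "")
  if (length(bad) > 0) {
    stop_io("malformed size at record ", bad[1], " of ", path,
            ": '", size_raw[bad[1]], "'")
  }
  size[size_raw == ""] <- NA_real_
  if (any(size < 0, na.rm = TRUE)) stop_io("negative colony size in ", path)
  out$size <- size
  validate_colony_table(out, path = path)
  if (!is.null(layout)) out <- resolve_gene_ids(out, layout)
  out
}

validate_colony_table <- function(tbl, path = "<in-memory>") {
  key <- paste(tbl$plate_id, tbl$temperature, tbl$replicate, tbl$row, tbl$col)
  if (anyDuplicated(key) > 0) {
    d <- key[anyDuplicated(key)]
    stop_io("duplicate plate position in ", path, ": ", d)
  }
  if (any(tbl$row < 1) || any(tbl$col < 1)) {
    stop_io("plate coordinates must be 1-based positive integers in ", path)
  }
  invisible(tbl)
}

resolve_gene_ids <- function(tbl, layout) {
  m <- dplyr::left_join(
    tbl, dplyr::select(layout, "plate_id", "row", "col",
                       layout_gene = "gene_id"),
    by = c("plate_id", "row", "col")
  )
  conflict <- !is.na(m$gene_id) & !is.na(m$layout_gene) &
    m$gene_id != m$layout_gene
  if (any(conflict)) {
    i <- which(conflict)[1]
    stop_io("gene_id conflict at plate ", m$plate_id[i], " (", m$row[i], ",",
            m$col[i], "): table says '", m$gene_id[i], "', layout says '",
            m$layout_gene[i], "'")
  }
  m$gene_id <- ifelse(is.na(m$gene_id), m$layout_gene, m$gene_id)
  dplyr::select(m, -"layout_gene")
}

#' Write a colony-size measurement table
#'
#' @param tbl Colony tibble as returned by [read_colony_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_colony_table <- function(tbl, path) {
  validate_colony_table(tbl)
  out <- tbl[, c("plate_id", "temperature", "replicate", "row", "col",
                 "gene_id", "size")]
  out$size <- ifelse(is.na(out$size), "", format_num(out$size))
  write_tsv_commented(out, path,
                      comments = "coordinates are 1-based (row, col)")
}

format_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

#' Write a tibble as a commented TSV
#'
#' The package's house dialect: UTF-8, tab-separated, `#` comment lines
#' before the header, `NA` written as the empty string.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param comments Character vector of comment lines (without the `#`).
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a plate layout
#'
#' @param path Path to a layout TSV mapping `(plate_id, row, col)` to
#'   `gene_id` (see [plate-formats]). Grid dimensions are read from
#'   `# grid_rows:` / `# grid_cols:` header comments when present.
#' @return A tibble with columns `plate_id`, `row`, `col`, `gene_id` and
#'   attributes `grid_rows`, `grid_cols` (possibly `NULL`).
#' @export
read_layout <- function(path) {
  hdr <- readLines(path, n = 20L)
  grid_rows <- parse_grid_comment(hdr, "grid_rows")
  grid_cols <- parse_grid_comment(hdr, "grid_cols")
  df <- read_tsv_commented(path, c("plate_id", "row", "col", "gene_id"))
  out <- tibble::tibble(
    plate_id = df$plate_id,
    row = parse_int_col(df$row, "row", path),
    col = parse_int_col(df$col, "col", path),
    gene_id = df$gene_id
  )
  validate_layout(out, grid_rows, grid_cols, path)
  attr(out, "grid_rows") <- grid_rows
  attr(out, "grid_cols") <- grid_cols
  out
}

parse_grid_comment <- function(lines, key) {
  hit <- grep(paste0("^#\\s*", key, ":"), lines, value = TRUE)
  if (length(hit) == 0) return(NULL)
  as.integer(sub(paste0("^#\\s*", key, ":\\s*"), "", hit[1]))
}

validate_layout <- function(layout, grid_rows = NULL, grid_cols = NULL,
                            path = "<in-memory>") {
  key <- paste(layout$plate_id, layout$row, layout$col)
  if (anyDuplicated(key) > 0) stop_io("duplicate layout position in ", path)
  if (any(layout$row < 1) || any(layout$col < 1)) {
    stop_io("layout coordinates must be positive in ", path)
  }
  if (!is.null(grid_rows) && any(layout$row > grid_rows)) {
    stop_io("layout row exceeds grid_rows=", grid_rows, " in ", path)
  }
  if (!is.null(grid_cols) && any(layout$col > grid_cols)) {
    stop_io("layout col exceeds grid_cols=", grid_cols, " in ", path)
  }
  invisible(layout)
}

#' Write a plate layout
#'
#' @param layout Layout tibble (columns `plate_id`, `row`, `col`, `gene_id`),
#'   optionally carrying `grid_rows`/`grid_cols` attributes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  gr <- attr(layout, "grid_rows")
  gc <- attr(layout, "grid_cols")
  validate_layout(layout, gr, gc)
  comments <- "coordinates are 1-based (row, col)"
  if (!is.null(gr)) comments <- c(comments, paste0("grid_rows: ", gr))
  if (!is.null(gc)) comments <- c(comments, paste0("grid_cols: ", gc))
  write_tsv_commented(
    layout[, c("plate_id", "row", "col", "gene_id")], path, comments)
}

#' Read a gene-to-ontology-term association table
#'
#' A minimal, GAF-like flat dialect: one row per (gene, term) membership,
#' columns `gene_id`, `term_id`, `term_name`. No ontology-graph propagation
#' is performed; the table is assumed pre-slimmed.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble with columns `gene_id`, `term_id`, `term_name`.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_commented(path, c("gene_id", "term_id", "term_name"))
  out <- tibble::tibble(gene_id = df$gene_id, term_id = df$term_id,
                        term_name = df$term_name)
  if (any(!nzchar(out$gene_id)) || any(!nzchar(out$term_id))) {
    stop_io("empty gene_id or term_id in ", path)
  }
  dplyr::distinct(out)
}

#' Write a gene-to-ontology-term association table
#'
#' @param annotation Annotation tibble (columns `gene_id`, `term_id`,
#'   `term_name`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  write_tsv_commented(
    annotation[, c("gene_id", "term_id", "term_name")], path)
}

#' Read a per-gene score table written by the pipeline
#'
#' Inverse of the score TSVs emitted by [run_pipeline()] (or written with
#' the package's TSV writer from a [score_screen()] result).
#'
#' @param path Path to a gene-score TSV.
#' @return A gene-score tibble (see [score_screen()]).
#' @export
read_gene_scores <- function(path) {
  df <- read_tsv_commented(path, c("gene_id", "query_label", "ng_30",
                                   "ng_19", "ngr", "log2_ng_30",
                                   "log2_ng_19", "log2_ngr", "n_rep_30",
                                   "n_rep_19"))
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  tibble::tibble(
    gene_id = df$gene_id, query_label = df$query_label,
    ng_30 = num(df$ng_30), ng_19 = num(df$ng_19), ngr = num(df$ngr),
    log2_ng_30 = num(df$log2_ng_30), log2_ng_19 = num(df$log2_ng_19),
    log2_ngr = num(df$log2_ngr),
    n_rep_30 = parse_int_col(df$n_rep_30, "n_rep_30", path),
    n_rep_19 = parse_int_col(df$n_rep_19, "n_rep_19", path),
    qc_flags = if ("qc_flags" %in% names(df)) df$qc_flags else ""
  )
}

#' Read or write a screen manifest
#'
#' A manifest is a YAML file naming one query screen: its `query_label`,
#' the `reference_temperature` and `cold_temperature` condition labels, and
#' the colony-table and layout file paths.
#'
#' @param path Manifest path.
#' @return For `read_manifest`, a named list with elements `query_label`,
#'   `reference_temperature`, `cold_temperature`, `colony_tables` (character
#'   vector of paths) and `layout` (path or `NULL`).
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  need <- c("query_label", "reference_temperature", "cold_temperature",
            "colony_tables")
  missing_f <- setdiff(need, names(m))
  if (length(missing_f) > 0) {
    stop_io("manifest ", path, " lacks field(s): ",
            paste(missing_f, collapse = ", "))
  }
  m$colony_tables <- unlist(m$colony_tables)
  if (length(m$colony_tables) < 1) stop_io("manifest lists no colony tables")
  m
}

#' @rdname read_manifest
#' @param manifest Manifest list as returned by [read_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}
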