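test_that("colony tables round-trip losslessly, including missing colonies", {
  tb <- make_plate(c(10, 20, NA, 30))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_colony_table(tb, path)
  back <- read_colony_table(path)
  expect_equal(back$size, tb$size)
  expect_identical(back$gene_id, tb$gene_id)
  expect_identical(back$row, tb$row)
  expect_identical(back$col, tb$col)
  # second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_colony_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("layout and annotation tables round-trip with grid metadata", {
  layout <- tibble::tibble(plate_id = "p1", row = c(1L, 2L), col = c(1L, 5L),
                           gene_id = c("geneA", "geneB"))
  attr(layout, "grid_rows") <- 8L
  attr(layout, "grid_cols") <- 12L
  path <- withr::local_tempfile(fileext = ".tsv")
  write_layout(layout, path)
  back <- read_layout(path)
  expect_equal(attr(back, "grid_rows"), 8L)
  expect_equal(attr(back, "grid_cols"), 12L)
  expect_equal(as.data.frame(back), as.data.frame(layout))

  ann <- tibble::tibble(gene_id = c("geneA", "geneA", "geneB"),
                        term_id = c("T1", "T2", "T1"),
                        term_name = c("one", "two", "one"))
  apath <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ann, apath)
  aback <- read_annotation(apath)
  expect_equal(as.data.frame(aback), as.data.frame(ann))
  # a gene annotated to two terms keeps both memberships
  expect_setequal(aback$term_id[aback$gene_id == "geneA"], c("T1", "T2"))
})

test_that("randomized tables survive write-read round trips", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    tb <- tibble::tibble(
      plate_id = sample(c("pA", "pB"), n, replace = TRUE),
      temperature = sample(c("30C", "19C"), n, replace = TRUE),
      replicate = sample(1:3, n, replace = TRUE),
      row = 1L, col = seq_len(n),
      gene_id = sprintf("g%02d", seq_len(n)),
      size = ifelse(runif(n) < 0.1, NA_real_, round(rlnorm(n, 5, 1), 6)))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_colony_table(tb, path)
    expect_equal(as.data.frame(read_colony_table(path)), as.data.frame(tb),
                 tolerance = 1e-12)
  }
})

test_that("integrity violations are rejected with informative errors", {
  tb <- make_plate(c(10, 20))
  dup <- dplyr::bind_rows(tb, tb[1, ])
  path <- withr::local_tempfile(fileext = ".tsv")
  tb2 <- dup; tb2$size <- as.character(tb2$size)
  write_tsv_commented_for_test(tb2, path)
  expect_error(read_colony_table(path), "duplicate")

  bad <- make_plate(c(10, 20)); bad$size <- c("10", "not_a_number")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_commented_for_test(bad, path2)
  expect_error(read_colony_table(path2), "malformed size at record 2")

  # layout disagreement with an explicit gene_id column is never silent
  tb3 <- make_plate(c(5, 6))
  layout <- tibble::tibble(plate_id = "p1", row = 1L, col = 1:2,
                           gene_id = c("g001", "WRONG"))
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_colony_table(tb3, path3)
  expect_error(read_colony_table(path3, layout = layout), "conflict")

  # out-of-bounds layout position
  lpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# grid_rows: 2", "# grid_cols: 2",
               "plate_id\trow\tcol\tgene_id", "p1\t3\t1\tgX"), lpath)
  expect_error(read_layout(lpath), "exceeds grid_rows")
})

test_that("manifests validate required fields and round-trip", {
  m <- list(query_label = "taz1", reference_temperature = "30C",
            cold_temperature = "19C", colony_tables = "colonies.tsv",
            layout = "layout.tsv")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_manifest(m, path)
  back <- read_manifest(path)
  expect_identical(back$query_label, "taz1")
  expect_identical(back$colony_tables, "colonies.tsv")

  bad <- m; bad$cold_temperature <- NULL
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_manifest(bad, path2)
  expect_error(read_manifest(path2), "cold_temperature")
})
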