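test_that("two-SD caller isolates extreme genes and rejects degeneracy", {
  values <- c(rep(0, 98), 5, -5)
  sc <- make_scores(values)
  pos <- call_hits_two_sd(sc, "log2_ngr", "positive")
  neg <- call_hits_two_sd(sc, "log2_ngr", "negative")
  expect_identical(pos$gene_id, sc$gene_id[99])
  expect_identical(neg$gene_id, sc$gene_id[100])
  expect_identical(sort(c(pos$gene_id, neg$gene_id)),
                   oracle_two_sd(sc$gene_id, values, "positive") |>
                     c(oracle_two_sd(sc$gene_id, values, "negative")) |>
                     sort())
  summ <- attr(pos, "distribution_summary")
  expect_true(all(abs(pos$value - summ$median) >= 2 * summ$sd))

  expect_error(call_hits_two_sd(make_scores(rep(1, 50))), "sd = 0")
  expect_error(call_hits_two_sd(make_scores(rnorm(5))), ">= 10")
})

test_that("two-SD tail fraction on a normal sample sits near theory", {
  set.seed(2024)
  values <- rnorm(10000)
  sc <- make_scores(values)
  for (dir in c("positive", "negative")) {
    frac <- nrow(call_hits_two_sd(sc, "log2_ngr", dir)) / 10000
    expect_gte(frac, 0.013)
    expect_lte(frac, 0.033)
  }
})

test_that("percentile caller applies ceil(0.25 n) with the documented ties", {
  # n = 8 distinct values -> exactly 2 genes
  sc8 <- make_scores(c(3, 7, 1, 9, 4, 6, 2, 8))
  expect_equal(nrow(call_hits_percentile(sc8, direction = "positive")), 2)
  # n = 5: ceil(1.25) = 2 -> the genes holding {5, 4}
  sc5 <- make_scores(1:5)
  hp <- call_hits_percentile(sc5, direction = "positive")
  expect_setequal(hp$value, c(4, 5))
  expect_error(call_hits_percentile(make_scores(1:3)), ">= 4")
  # boundary ties beyond the slack are broken by ascending gene_id
  sct <- make_scores(c(9, rep(5, 60), rnorm(139)))
  ht <- call_hits_percentile(sct, direction = "positive")
  expect_equal(nrow(ht), 50)  # ceil(0.25*200), ties not absorbable
  expect_identical(sort(ht$gene_id),
                   oracle_percentile(sct$gene_id, sct$log2_ngr, "positive"))
})

test_that("both callers match brute-force oracles on randomized instances", {
  set.seed(7)
  for (trial in 1:1000) {
    n <- sample(10:200, 1)
    values <- rnorm(n)
    if (trial %% 3 == 0) values <- round(values, 1)   # force ties
    if (trial %% 7 == 0) values[sample(n, 2)] <- values[1]
    gid <- sprintf("g%03d", sample(n))
    sc <- make_scores(values, gene_id = gid)
    dir <- if (trial %% 2 == 0) "positive" else "negative"
    expect_identical(sort(call_hits_percentile(sc, direction = dir)$gene_id),
                     oracle_percentile(gid, values, dir))
    if (sd(values) > 0) {
      expect_identical(sort(call_hits_two_sd(sc, direction = dir)$gene_id),
                       oracle_two_sd(gid, values, dir))
    }
  }
})

test_that("raising a gene's statistic never drops it from a positive call", {
  set.seed(31)
  values <- rnorm(60)
  sc <- make_scores(values)
  base_hits <- call_hits_percentile(sc, direction = "positive")$gene_id
  for (g in base_hits[1:3]) {
    sc2 <- sc
    sc2$log2_ngr[sc2$gene_id == g] <- sc2$log2_ngr[sc2$gene_id == g] + 1
    expect_true(g %in% call_hits_percentile(sc2,
                                            direction = "positive")$gene_id)
  }
})

test_that("QC-voided genes are excluded before calling and reported", {
  sc <- make_scores(c(rnorm(20), NA, Inf))
  sc$qc_flags[21] <- "MISSING_REF"
  h <- call_hits_percentile(sc, direction = "positive")
  excl <- attr(h, "excluded")
  expect_setequal(excl$gene_id, sc$gene_id[21:22])
  expect_match(excl$reason[1], "MISSING_REF")
})

test_that("statistic routing follows the analysis goal", {
  expect_identical(select_statistic("taz1", "permissive_interaction"),
                   "log2_ng_30")
  expect_identical(select_statistic("taz1", "cold_specific"), "log2_ngr")
  expect_identical(select_statistic("taz1rif1", "cold_specific"), "log2_ngr")
  expect_error(select_statistic("taz1", "nonsense"))
})
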