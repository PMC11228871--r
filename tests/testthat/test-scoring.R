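test_that("plate-median normalization matches hand-computed NG values", {
  expect_equal(normalize_plate(make_plate(c(10, 20, 30))), c(0.5, 1, 1.5))
  expect_equal(normalize_plate(make_plate(rep(7.3, 5))), rep(1, 5))
  # even colony count: median is the mean of the two central sizes (8 here)
  expect_equal(normalize_plate(make_plate(c(4, 6, 10, 100))),
               c(0.5, 0.75, 1.25, 12.5))
  expect_equal(unname(quantile(c(4, 6, 10, 100), 0.5, type = 7)), 8)
  # missing colonies get no NG; the rest normalize against the measured median
  expect_equal(normalize_plate(make_plate(c(10, NA, 30))),
               c(0.5, NA, 1.5))
})

test_that("median of NG on a plate is 1, and NG is scale invariant", {
  set.seed(5)
  for (n in c(7, 8, 101, 100)) {
    sizes <- rlnorm(n, 5, 0.6)
    ng <- normalize_plate(make_plate(sizes))
    if (n %% 2 == 1) {
      expect_identical(median(ng), 1)
    } else {
      expect_lt(abs(median(ng) - 1), 1e-9)
    }
    for (k in c(0.01, 3, 1e6)) {
      ng_k <- normalize_plate(make_plate(sizes * k))
      expect_true(all(abs(ng_k - ng) <= 4 * .Machine$double.eps * abs(ng)))
    }
  }
})

test_that("degenerate plates are excluded or rejected", {
  expect_error(normalize_plate(make_plate(c(NA_real_, NA_real_))),
               "all colonies missing")
  expect_error(normalize_plate(make_plate(c(0, 0, 0))), "median size is 0")
  two_plates <- dplyr::bind_rows(make_plate(c(0, 0, 0), plate_id = "dead"),
                                 make_plate(c(10, 20, 30), plate_id = "ok"))
  expect_warning(ng <- normalize_plates(two_plates), "dead")
  expect_setequal(unique(ng$plate_id), "ok")
})

test_that("replicate aggregation is the median with QC flags", {
  tb <- tibble::tibble(gene_id = c("a", "a", "a", "b", "c", "c"),
                       temperature = "30C",
                       replicate = c(1L, 2L, 3L, 1L, 1L, 2L),
                       ng = c(0.8, 1.0, 1.2, 0.7, 0.5, 1.5))
  agg <- aggregate_replicates(tb, min_replicates = 2)
  expect_equal(agg$ng[agg$gene_id == "a"], 1.0)
  expect_equal(agg$ng[agg$gene_id == "b"], 0.7)
  expect_true(agg$low_replicates[agg$gene_id == "b"])
  expect_equal(agg$ng[agg$gene_id == "c"], 1.0)  # even-count median
  expect_false(agg$low_replicates[agg$gene_id == "c"])
})

test_that("NGR and log2 fields are mutually consistent", {
  sc <- tibble::tibble(ng_30 = c(1.0, 0.73, 0.3, 0, NA),
                       ng_19 = c(0.5, 0.73, 1.2, 1, 1))
  out <- compute_ngr(sc)
  expect_equal(out$ngr[1:3], c(0.5, 1, 4))
  expect_equal(out$log2_ngr[1:3], c(-1, 0, 2))
  expect_true(all(is.na(out$ngr[4:5])))  # zero/missing reference
  rel <- abs(out$log2_ngr[1:3] - log2(out$ngr[1:3]))
  expect_true(all(rel <= 1e-12 * pmax(1, abs(log2(out$ngr[1:3])))))
})

test_that("distribution summaries report median and sample SD", {
  s <- summarize_distribution(c(-1, 0, 1), "log2_ngr")
  expect_equal(s$median, 0)
  expect_equal(s$sd, 1)
  s2 <- summarize_distribution(rep(3.7, 4), "log2_ngr")
  expect_equal(s2$median, 3.7)
  expect_equal(s2$sd, 0)
  expect_error(summarize_distribution(c(1), "x"), ">= 2")
  # non-finite values are excluded and counted
  s3 <- summarize_distribution(c(-1, 0, 1, NA, Inf), "log2_ngr")
  expect_equal(s3$n, 3)
  expect_equal(s3$n_nonfinite, 2)
  # Monte-Carlo recovery of the generator's own parameters
  set.seed(99)
  draws <- rnorm(10001, 0, 0.52)
  s4 <- summarize_distribution(draws, "log2_ngr")
  expect_lt(abs(s4$median - 0), 0.02)
  expect_lt(abs(s4$sd - 0.52), 0.02)
})

test_that("score_screen recovers planted effects exactly without noise", {
  pe <- planted_effects(c("g05", "g11"), factor_30 = c(1, 0.25),
                        factor_19 = c(4, 0.25),
                        label = c("cs_suppressor", "synthetic_sick"))
  s <- simulate_screen(quiet_config(planted_effects = pe), "taz1")
  sc <- score_screen(s$colonies, query_label = "taz1")
  expect_equal(sc$ngr[sc$gene_id == "g05"], 4)
  # shared sickness cancels in the ratio
  expect_equal(sc$ngr[sc$gene_id == "g11"], 1)
  expect_equal(sc$ng_30[sc$gene_id == "g11"], 0.25)
  expect_equal(sc$n_rep_30, rep(3L, nrow(sc)))
  expect_true(all(sc$qc_flags == ""))
})

test_that("score_screen flags missing and sparse genes instead of dropping", {
  s <- simulate_screen(quiet_config(), "q")
  col <- s$colonies
  # gene g01: remove all cold-side colonies; gene g02: keep one replicate
  col <- col[!(col$gene_id == "g01" & col$temperature == "19C"), ]
  col <- col[!(col$gene_id == "g02" & col$replicate > 1), ]
  sc <- score_screen(col, query_label = "q")
  expect_match(sc$qc_flags[sc$gene_id == "g01"], "MISSING_COLD")
  expect_true(is.na(sc$ngr[sc$gene_id == "g01"]))
  expect_match(sc$qc_flags[sc$gene_id == "g02"], "LOW_REPLICATES")
  expect_equal(sc$n_rep_19[sc$gene_id == "g02"], 1L)
})

test_that("plate effects are removed by normalization", {
  # same seed, plate effects on vs off: per-gene NG must agree closely
  base <- list(n_genes = 600, grid_rows = 16, grid_cols = 24,
               colony_noise_sd = 0.3, baseline_log_size_sd = 0,
               dropout_prob = 0, seed = 21)
  with_pe <- do.call(sim_config, c(base, plate_effect_sd = 0.5))
  no_pe <- do.call(sim_config, c(base, plate_effect_sd = 0))
  sc_with <- score_screen(simulate_screen(with_pe, "q")$colonies)
  sc_no <- score_screen(simulate_screen(no_pe, "q")$colonies)
  # identical child streams draw identical colony noise, so NG differs only
  # through the plate median's finite-sample response to the plate effect
  expect_equal(sc_with$log2_ngr, sc_no$log2_ngr, tolerance = 1e-9)
  expect_lt(abs(var(sc_with$log2_ngr) / var(sc_no$log2_ngr) - 1), 1e-9)
})
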