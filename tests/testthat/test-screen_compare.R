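make_hits <- function(gene_id, value, statistic = "log2_ng_30",
                      direction = "negative") {
  tibble::tibble(gene_id = gene_id, query_label = "A",
                 statistic_name = statistic, value = value,
                 direction = direction, method = "two_sd",
                 threshold_used = NA_real_)
}

test_that("similar interactions in the comparison screen are filtered out", {
  hits <- make_hits(c("g1", "g2"), c(-2, -2))
  other <- make_scores(c(-1.8, 0.1), statistic = "log2_ng_30",
                       gene_id = c("g1", "g2"))
  out <- filter_query_specific(hits, other)
  expect_identical(out$gene_id, "g2")       # -2 vs +0.1: retained
  excl <- attr(out, "excluded")
  expect_identical(excl$gene_id, "g1")      # -2 vs -1.8: similar, removed
  expect_match(excl$reason, "similar")
  # a same-direction outright hit in the other screen is always similar
  other2 <- make_scores(c(-0.3, -0.3), statistic = "log2_ng_30",
                        gene_id = c("g1", "g2"))
  out2 <- filter_query_specific(hits, other2,
                                hits_other = make_hits("g2", -0.3))
  expect_identical(out2$gene_id, "g1")
  expect_error(filter_query_specific(hits, make_scores(1:4)),
               "statistic mismatch")
})

test_that("the specificity filter matches per-gene brute force", {
  set.seed(13)
  for (trial in 1:50) {
    n <- 80
    va <- rnorm(n); vb <- rnorm(n)
    vb[sample(n, 10)] <- NA
    gid <- sprintf("g%02d", 1:n)
    hit_idx <- sample(n, 25)
    hits <- make_hits(gid[hit_idx], va[hit_idx])
    other <- make_scores(vb, statistic = "log2_ng_30", gene_id = gid)
    out <- filter_query_specific(hits, other, similarity_fraction = 0.5)
    keep_brute <- vapply(seq_along(hit_idx), function(j) {
      b <- vb[hit_idx[j]]; a <- va[hit_idx[j]]
      !(!is.na(b) && sign(b) == sign(a) && abs(b) >= 0.5 * abs(a))
    }, logical(1))
    expect_setequal(out$gene_id, gid[hit_idx][keep_brute])
  }
})

test_that("suppressor classification recovers planted cold-specific rescue", {
  pe <- planted_effects(c("g03", "g07", "g20"),
                        factor_30 = c(1, 1, 0.25),
                        factor_19 = c(4, 4, 0.25),
                        label = c("cs_suppressor", "cs_suppressor",
                                  "synthetic_sick"))
  s <- simulate_screen(quiet_config(planted_effects = pe), "taz1")
  sc <- score_screen(s$colonies, query_label = "taz1")
  sup <- classify_suppressors(sc, method = "percentile25")
  expect_true(all(c("g03", "g07") %in% sup))
  # shared 30C/19C sickness cancels in NGR: not a suppressor
  expect_false("g20" %in% sup)
  # with the 2-SD method only the planted rescues emerge
  sup2 <- classify_suppressors(sc, method = "two_sd")
  expect_setequal(as.character(sup2), c("g03", "g07"))
})

test_that("reverter classification follows the four-screen rule", {
  genes <- sprintf("g%02d", 1:60)
  rev_ <- c("g05", "g06")   # sick in both suppressed screens, quiet singles
  fake <- "g10"             # also sick in a single screen
  only_dbl <- "g15"         # sick in the double screen only
  mk <- function(pe) {
    s <- simulate_screen(quiet_config(planted_effects = pe), "q")
    score_screen(s$colonies, query_label = "q")
  }
  sick <- function(g) planted_effects(g, 1, 0.2, "reverter")
  dbl <- mk(sick(c(rev_, fake, only_dbl)))
  tpl <- mk(sick(c(rev_, fake)))
  s1 <- mk(sick(fake))
  s2 <- mk(NULL)
  cl <- classify_reverters(dbl, tpl, s1, s2, method = "two_sd")
  expect_setequal(attr(cl, "reverters"), rev_)
  expect_match(cl$exclusion_reasons[cl$gene_id == fake],
               "affects single mutant")
  expect_match(cl$exclusion_reasons[cl$gene_id == only_dbl],
               "not a hit in triple screen")
  expect_error(classify_reverters(dbl, tpl, NULL, s2), "missing")
})

test_that("enlarging the single-mutant tolerance never removes a reverter", {
  set.seed(77)
  base <- sim_config(n_genes = 400, grid_rows = 20, grid_cols = 20,
                     colony_noise_sd = 0.3, seed = 77)
  genes <- sprintf("g%03d", 1:400)
  pe <- planted_effects(genes[1:10], 1, 0.15, "reverter")
  scr <- simulate_parallel_screens(
    base, list(dbl = pe, tpl = pe, s1 = NULL, s2 = NULL))
  sc <- lapply(scr, function(s) score_screen(s$colonies,
                                             query_label = s$query_label))
  prev <- character()
  for (tol in c(0.5, 1, 2, 4)) {
    cur <- attr(classify_reverters(sc$dbl, sc$tpl, sc$s1, sc$s2,
                                   single_mutant_tolerance = tol),
                "reverters")
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("classification is invariant to input gene order", {
  set.seed(5)
  values <- rnorm(50); gid <- sprintf("g%02d", 1:50)
  sc <- make_scores(values, gene_id = gid)
  perm <- sample(50)
  sc_perm <- sc[perm, ]
  expect_setequal(classify_suppressors(sc, "percentile25"),
                  classify_suppressors(sc_perm, "percentile25"))
})

test_that("venn partition is an exact disjoint decomposition", {
  v <- venn_partition(list(A = c("a", "b"), B = c("b", "c")))
  expect_identical(v[["A"]], "a")
  expect_identical(v[["A&B"]], "b")
  expect_identical(v[["B"]], "c")
  same <- venn_partition(list(X = c("p", "q"), Y = c("p", "q")))
  expect_identical(names(same), "X&Y")
  expect_setequal(same[["X&Y"]], c("p", "q"))
  expect_error(venn_partition(list(A = "a")), ">= 2")

  set.seed(11)
  sets <- lapply(1:3, function(i) sample(sprintf("g%03d", 1:150), 100))
  names(sets) <- c("A", "B", "C")
  v3 <- venn_partition(sets)
  # disjoint, union-complete, and sizes match brute-force membership counts
  all_genes <- unlist(v3, use.names = FALSE)
  expect_false(any(duplicated(all_genes)))
  expect_setequal(all_genes, unique(unlist(sets)))
  for (region in names(v3)) {
    members <- strsplit(region, "&", fixed = TRUE)[[1]]
    brute <- Reduce(intersect, sets[members])
    for (lab in setdiff(names(sets), members)) {
      brute <- setdiff(brute, sets[[lab]])
    }
    expect_setequal(v3[[region]], brute)
  }
})
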