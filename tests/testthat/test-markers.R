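test_that("log_normalize applies the median-library scaling and pseudocount", {
  counts <- rbind(g1 = c(2, 4), g2 = c(0, 0))
  colnames(counts) <- c("c1", "c2")
  ref <- cell_expression_set(counts,
                             data.frame(cell_type = c("A", "B")))
  out <- log_normalize(ref)
  # libraries are (2, 4), median 3: cell1 scaled by 3/2, cell2 by 3/4
  expect_equal(as.numeric(out$logexpr["g1", ]), c(log2(4), log2(4)))
  expect_equal(as.numeric(out$logexpr["g2", ]), c(0, 0))

  # equal libraries leave counts unscaled
  counts_eq <- rbind(g1 = c(2, 2), g2 = c(0, 0))
  colnames(counts_eq) <- c("c1", "c2")
  ref_eq <- log_normalize(cell_expression_set(
    counts_eq, data.frame(cell_type = c("A", "B"))))
  expect_equal(as.numeric(ref_eq$logexpr[, "c1"]), c(log2(3), 0))

  # all-zero cell is an error
  counts0 <- rbind(g1 = c(1, 0))
  colnames(counts0) <- c("c1", "c2")
  expect_error(
    log_normalize(cell_expression_set(counts0,
                                      data.frame(cell_type = c("A", "B")))),
    "zero library"
  )
})

test_that("doubling counts under equal libraries leaves linear mean ratios unchanged", {
  ref <- random_reference(genes = 20, types = 3, cells_per_type = 5,
                          seed = 11)
  ref2 <- ref
  ref2$counts <- ref$counts * 2
  r1 <- mean_ratio_stats(log_normalize(ref), scale = "linear")
  r2 <- mean_ratio_stats(log_normalize(ref2), scale = "linear")
  expect_equal(r1$mean_ratio, r2$mean_ratio, tolerance = 1e-12)
})

test_that("mean ratio formula, second type, and infinity rule on a toy set", {
  ref <- log_normalize(toy_reference())
  st <- mean_ratio_stats(ref, scale = "linear")
  # per-type linear means of g1 are A=8, B=2, C=1 (equal libraries)
  a <- st[st$gene == "g1" & st$cell_type == "A", ]
  expect_equal(a$mean_ratio, 4)
  expect_equal(a$second_type, "B")
  b <- st[st$gene == "g1" & st$cell_type == "B", ]
  expect_equal(b$mean_ratio, 0.25)   # max non-target is A
  # g4 is zero outside C: infinite ratio ranked first for C
  c4 <- st[st$gene == "g4" & st$cell_type == "C", ]
  expect_true(is.infinite(c4$mean_ratio))
  expect_equal(c4$rank_ratio, 1L)
})

test_that("vectorized mean ratios equal the brute-force triple loop exactly", {
  for (seed in 1:20) {
    genes <- sample(5:50, 1)
    types <- sample(2:5, 1)
    ref <- random_reference(genes, types, cells_per_type = 4, seed = seed)
    ref <- log_normalize(ref)
    fast <- mean_ratio_stats(ref)
    slow <- brute_force_mean_ratio(as.matrix(ref$logexpr),
                                   ref$cell_meta$cell_type)
    merged <- merge(as.data.frame(fast), slow,
                    by = c("gene", "cell_type"),
                    suffixes = c("_fast", "_slow"))
    expect_equal(nrow(merged), genes * types)
    expect_identical(merged$mean_target_fast, merged$mean_target_slow)
    expect_identical(merged$mean_ratio_fast, merged$mean_ratio_slow)
    expect_identical(merged$second_type_fast, merged$second_type_slow)
  }
})

test_that("mean_ratio > 1 iff the target mean exceeds every non-target mean", {
  ref <- log_normalize(random_reference(40, 4, 6, seed = 3))
  st <- mean_ratio_stats(ref)
  expect_equal(st$mean_ratio > 1,
               st$mean_target > st$max_nontarget_mean)
  # ranks are a permutation of 1..G within each type
  for (tt in unique(st$cell_type)) {
    expect_setequal(st$rank_ratio[st$cell_type == tt], 1:40)
  }
})

test_that("one-vs-all Welch statistics match t.test on hand-made groups", {
  # target cells (1,2,3), pooled complement (0,0,1,1)
  counts <- rbind(g1 = c(1, 2, 3, 0, 0, 1, 1), g2 = rep(1, 7))
  colnames(counts) <- paste0("c", 1:7)
  ref <- cell_expression_set(
    counts, data.frame(cell_type = c("T", "T", "T", "N1", "N1", "N2", "N2")))
  # bypass normalization: libraries differ, so feed logexpr directly
  ref$logexpr <- counts
  st <- one_vs_all_stats(ref)
  row <- st[st$gene == "g1" & st$cell_type == "T", ]
  expect_equal(row$logfc, 1.5)

  oracle <- t.test(c(1, 2, 3), c(0, 0, 1, 1))
  expect_equal(row$t_stat, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(row$p_value, oracle$p.value, tolerance = 1e-12)
  expect_equal(row$t_stat, 2.324, tolerance = 1e-3)

  # standardized logfc is logfc over the pooled SD
  v1 <- var(c(1, 2, 3)); v2 <- var(c(0, 0, 1, 1))
  pooled <- sqrt((2 * v1 + 3 * v2) / 5)
  expect_equal(row$std_logfc, 1.5 / pooled, tolerance = 1e-12)
})

test_that("one-vs-all p-values are well calibrated under the null", {
  # identical distributions: type-I error at alpha = 0.05 near nominal
  withr::with_seed(99, {
    n_genes <- 1000
    counts <- matrix(rpois(n_genes * 40, 5), n_genes, 40)
    dimnames(counts) <- list(sprintf("g%04d", 1:n_genes), paste0("c", 1:40))
    ref <- cell_expression_set(
      counts, data.frame(cell_type = rep(c("A", "B"), each = 20)))
    ref$logexpr <- counts   # identity transform keeps the null exact
    st <- one_vs_all_stats(ref)
    rate <- mean(st$p_value[st$cell_type == "A"] < 0.05)
    expect_lt(rate, 0.075)
    expect_gt(mean(st$p_value[st$cell_type == "A"]), 0.4)
  })
})

test_that("top-N selection cuts by rank first, then intersects the universe", {
  ref <- log_normalize(toy_reference())
  st <- mean_ratio_stats(ref, scale = "linear")
  full <- select_top_n(st, n = 4)
  expect_equal(lengths(full$sets), c(A = 4L, B = 4L, C = 4L))

  # universe excluding a top gene shrinks that type's contribution
  top1 <- select_top_n(st, n = 1)
  uni <- setdiff(rownames(ref$counts), top1$sets[["A"]])
  cut <- select_top_n(st, n = 1, universe = uni)
  expect_equal(length(cut$sets[["A"]]), 0L)
  expect_lte(length(cut$union), 3L)

  expect_error(select_top_n(st, n = 0), "at least 1")
  expect_warning(select_top_n(st, n = 2, universe = "absent_gene"),
                 "empty")
})

test_that("threshold rule is strict and monotone in the threshold", {
  st <- tibble::tibble(
    gene = paste0("g", 1:3), cell_type = "A",
    mean_target = 3:1, mean_ratio = c(1.9, 2.0, 2.1),
    rank_ratio = 3:1
  )
  sel <- select_over_threshold(st, threshold = 2)
  expect_equal(sel$sets[["A"]], "g3")   # strictly greater only

  ref <- log_normalize(random_reference(50, 4, 6, seed = 7))
  stats <- mean_ratio_stats(ref)
  s2 <- select_over_threshold(stats, threshold = 2)
  s15 <- select_over_threshold(stats, threshold = 1.5)
  for (tt in names(s2$sets)) {
    expect_true(all(s2$sets[[tt]] %in% s15$sets[[tt]]))
  }

  # infinite ratios always pass
  st_inf <- tibble::tibble(gene = "g9", cell_type = "A",
                           mean_target = 1, mean_ratio = Inf,
                           rank_ratio = 1)
  expect_equal(select_over_threshold(st_inf, 100)$sets[["A"]], "g9")
})

test_that("MAD rule reproduces the hand-computed threshold and edge cases", {
  st <- tibble::tibble(
    gene = paste0("g", 1:6), cell_type = "A",
    mean_target = 6:1,
    mean_ratio = c(0.5, 1.2, 1.5, 2.0, 3.0, 10),
    rank_ratio = 6:1
  )
  # ratios > 1: {1.2, 1.5, 2, 3, 10}; median 2, raw MAD 0.8,
  # threshold 2 + 3 * 1.4826 * 0.8 = 5.55824 -> only the 10 passes
  sel <- select_mad_rule(st, k = 3)
  expect_equal(sel$sets[["A"]], "g6")

  # k = 0 keeps ratios strictly above the median
  sel0 <- select_mad_rule(st, k = 0)
  expect_setequal(sel0$sets[["A"]], c("g5", "g6"))

  # all equal ratios: MAD 0, strict rule selects nothing
  st_eq <- tibble::tibble(gene = paste0("g", 1:3), cell_type = "A",
                          mean_target = 3:1, mean_ratio = rep(2, 3),
                          rank_ratio = 1:3)
  expect_equal(length(select_mad_rule(st_eq, k = 3)$sets[["A"]]), 0L)

  # fewer than 2 finite ratios > 1 warns and contributes nothing finite
  st_few <- tibble::tibble(gene = c("g1", "g2"), cell_type = "A",
                           mean_target = 2:1, mean_ratio = c(1.5, Inf),
                           rank_ratio = c(2L, 1L))
  expect_warning(few <- select_mad_rule(st_few, k = 3), "fewer than 2")
  expect_equal(few$sets[["A"]], "g2")   # the infinite ratio survives
})

test_that("HVG selection nests across prop and recovers planted dispersion", {
  sim <- shared_sim()
  h1 <- select_hvg(sim$reference, prop = 0.1)
  h2 <- select_hvg(sim$reference, prop = 0.2)
  h10 <- select_hvg(sim$reference, prop = 1)
  expect_true(all(h1 %in% h2))
  expect_true(all(h2 %in% h10))
  expect_error(select_hvg(sim$reference, prop = 0), "\\(0, 1]")

  # planted markers vary across types, so they are enriched among HVGs
  planted <- unlist(sim$truth$markers)
  top_decile <- select_hvg(sim$reference, prop = 0.1)
  enrichment <- mean(planted %in% top_decile) /
    (length(top_decile) / nrow(sim$reference$counts))
  expect_gt(enrichment, 2)
})

test_that("marker recovery on the default synthetic reference is near-perfect", {
  sim <- shared_sim()
  st <- mean_ratio_stats(sim$reference)
  top <- select_top_n(st, n = 25)
  for (tt in names(sim$truth$markers)) {
    expect_gte(mean(sim$truth$markers[[tt]] %in% top$sets[[tt]]), 0.9)
  }
})
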