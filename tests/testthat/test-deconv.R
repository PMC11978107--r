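test_that("signature columns are per-type means of normalized counts", {
  ref <- toy_reference()   # equal libraries: normalization is identity
  sig <- build_signature(ref, c("g1", "g2", "g4"))
  expect_equal(unname(sig["g1", ]), c(8, 2, 1))
  expect_equal(unname(sig["g4", ]), c(0, 0, 8))
  expect_equal(attr(sig, "provenance"), "custom")

  # a type with a single cell contributes that cell's values
  one <- cell_expression_set(
    cbind(c1 = c(g1 = 2, g2 = 2), c2 = c(4, 0), c3 = c(0, 4)),
    data.frame(cell_type = c("A", "B", "B"))
  )
  sig1 <- build_signature(one, c("g1", "g2"))
  expect_equal(unname(sig1[, "A"]), c(2, 2))

  expect_error(build_signature(ref, "not_a_gene"), "no marker genes")
})

test_that("exact mixtures are recovered exactly", {
  s <- rbind(g1 = c(1, 0), g2 = c(0, 1), g3 = c(1, 1))
  colnames(s) <- c("A", "B")
  sig <- structure(s, class = c("signature_matrix", "matrix", "array"),
                   provenance = "toy")
  b <- cbind(mix = c(0.3, 0.7, 1.0), pure = s[, 1])
  rownames(b) <- rownames(s)
  props <- nnls_proportions(b, sig)
  m <- prop_matrix(props)
  expect_equal(unname(m["mix", ]), c(0.3, 0.7), tolerance = 1e-9)
  expect_equal(unname(m["pure", ]), c(1, 0), tolerance = 1e-9)
  expect_equal(attr(props, "method"), "baseline-nnls")
})

test_that("noiseless identifiability holds over random simplex draws", {
  withr::with_seed(17, {
    for (i in 1:20) {
      s <- matrix(runif(50 * 4), 50, 4,
                  dimnames = list(sprintf("g%02d", 1:50), LETTERS[1:4]))
      sig <- structure(s, class = c("signature_matrix", "matrix", "array"),
                       provenance = "rand")
      g <- rgamma(4, 1)
      pi_true <- g / sum(g)
      b <- s %*% pi_true
      colnames(b) <- "s1"
      est <- prop_matrix(nnls_proportions(b, sig))[1, ]
      expect_equal(unname(est), unname(pi_true), tolerance = 1e-6)
    }
  })
})

test_that("proportions are invariant to per-sample depth scaling", {
  sim <- simulate_reference(K = 4, G = 200, m = 10, D = 2, n_cells = 20,
                            seed = 5)
  bk <- simulate_bulk(sim$truth, n_samples = 3, poisson = FALSE, seed = 6)
  sig <- signature_from_truth(sim$truth)
  p1 <- prop_matrix(nnls_proportions(bk$bulk$counts, sig))
  p2 <- prop_matrix(nnls_proportions(bk$bulk$counts %*% diag(c(10, 1, 0.1)),
                                     sig))
  expect_equal(unname(p1), unname(p2), tolerance = 1e-9)
})

test_that("noisy mixtures are still recovered accurately", {
  withr::with_seed(31, {
    s <- matrix(runif(50 * 4, 0.2, 2), 50, 4,
                dimnames = list(sprintf("g%02d", 1:50), LETTERS[1:4]))
    sig <- structure(s, class = c("signature_matrix", "matrix", "array"),
                     provenance = "rand")
    g <- matrix(rgamma(4 * 30, 1), 4)
    pi_true <- sweep(g, 2, colSums(g), "/")
    b <- s %*% pi_true
    b <- b * matrix(rlnorm(length(b), 0, 0.1), nrow(b))
    colnames(b) <- sprintf("s%02d", 1:30)
    est <- prop_matrix(nnls_proportions(b, sig))
    per_sample_cor <- vapply(1:30, function(j) cor(est[j, ], pi_true[, j]),
                             0)
    expect_gte(mean(per_sample_cor), 0.95)
  })
})

test_that("cell-size adjustment inverts RNA-content weighting", {
  p <- proportion_table(tibble::tibble(sample = "s1", A = 0.5, B = 0.5))
  adj <- adjust_for_cell_size(p, c(A = 2, B = 1))
  expect_equal(unname(prop_matrix(adj)[1, ]), c(1 / 3, 2 / 3))

  # equal sizes are the identity
  same <- adjust_for_cell_size(p, c(A = 3, B = 3))
  expect_equal(prop_matrix(same), prop_matrix(p))

  # adjusting by s then by 1/s round-trips
  withr::with_seed(2, {
    m <- matrix(rgamma(12, 1), 4, 3,
                dimnames = list(NULL, c("A", "B", "C")))
  })
  m <- m / rowSums(m)
  pt <- proportion_table(dplyr::bind_cols(
    tibble::tibble(sample = paste0("s", 1:4)), tibble::as_tibble(m)))
  s <- c(A = 2, B = 0.5, C = 1.3)
  back <- adjust_for_cell_size(adjust_for_cell_size(pt, s), 1 / s)
  expect_equal(prop_matrix(back), prop_matrix(pt), tolerance = 1e-12)

  expect_error(adjust_for_cell_size(p, c(A = 1)), "no cell size")
  expect_error(adjust_for_cell_size(p, c(A = 1, B = -1)), "positive")
})

test_that("size-aware mixing closure: nnls + size adjustment recovers cell fractions", {
  sim <- simulate_reference(K = 7, G = 500, m = 10, D = 2, n_cells = 20,
                            seed = 9)
  bk <- simulate_bulk(sim$truth, n_samples = 12, poisson = FALSE,
                      use_cell_sizes = TRUE, seed = 10)
  sig <- signature_from_truth(sim$truth)
  rna_fracs <- nnls_proportions(bk$bulk, sig)
  adjusted <- adjust_for_cell_size(rna_fracs, sim$truth$cell_sizes)
  truth <- true_proportions(bk$truth)
  est <- prop_matrix(adjusted)
  tru <- prop_matrix(truth)[rownames(est), colnames(est)]
  expect_lt(max(abs(est - tru)), 1e-3)

  # without the adjustment the estimates are the RNA fractions instead
  w <- sweep(tru, 2, sim$truth$cell_sizes[colnames(tru)], "*")
  w <- w / rowSums(w)
  expect_lt(max(abs(prop_matrix(rna_fracs) - w)), 1e-3)
})

test_that("adapter contract validates and renormalizes external output", {
  ref <- toy_reference(); bulk <- NULL
  good <- function(ref, bulk, markers, ...) {
    tibble::tibble(sample = c("s1", "s2"), A = c(0.4, 0.999999),
                   B = c(0.6, 0.000001))
  }
  out <- external_adapter(good, ref, bulk, c("g1"), "toy-engine")
  expect_s3_class(out, "proportion_table")
  expect_equal(attr(out, "method"), "toy-engine")

  near <- function(ref, bulk, markers, ...) {
    tibble::tibble(sample = "s1", A = 0.4999996, B = 0.4999996)
  }
  out2 <- external_adapter(near, ref, bulk, "g1")
  expect_equal(rowSums(prop_matrix(out2)), c(s1 = 1))

  off <- function(ref, bulk, markers, ...) {
    tibble::tibble(sample = "s1", A = 0.4, B = 0.4)
  }
  expect_error(external_adapter(off, ref, bulk, "g1", "bad"), "sum to 1")

  negative <- function(ref, bulk, markers, ...) {
    tibble::tibble(sample = "s1", A = -0.1, B = 1.1)
  }
  expect_error(external_adapter(negative, ref, bulk, "g1", "neg"),
               "negative")
})

test_that("long-format serialization round-trips through tidy()", {
  p <- proportion_table(tibble::tibble(sample = c("s1", "s2"),
                                       A = c(0.2, 0.5), B = c(0.8, 0.5)),
                        method = "baseline-nnls", gene_set = "toy")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_proportions(p, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 4L)
  expect_setequal(names(back),
                  c("sample", "cell_type", "proportion", "method",
                    "gene_set"))
  expect_equal(sum(back$proportion), 2)
})
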