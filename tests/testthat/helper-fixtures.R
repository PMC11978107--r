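# small in-code fixtures shared across test files

# dense toy reference with explicit per-type means; no randomness
toy_reference <- function() {
  # column sums are all 12, so library normalization is the identity
  counts <- rbind(
    g1 = c(8, 8, 2, 2, 1, 1),   # marker-ish for A
    g2 = c(1, 1, 6, 6, 1, 1),   # marker-ish for B
    g3 = c(2, 2, 2, 2, 2, 2),   # flat
    g4 = c(0, 0, 0, 0, 8, 8),   # perfectly specific for C
    g5 = c(1, 1, 2, 2, 0, 0)    # filler equalizing library sizes
  )
  colnames(counts) <- paste0("c", 1:6)
  meta <- data.frame(
    barcode = colnames(counts),
    cell_type = rep(c("A", "B", "C"), each = 2),
    donor = rep(c("d1", "d2"), 3)
  )
  cell_expression_set(counts, meta)
}

# random dense reference for property-style loops
random_reference <- function(genes, types, cells_per_type, seed) {
  withr::with_seed(seed, {
    n <- types * cells_per_type
    counts <- matrix(rpois(genes * n, lambda = 3), genes, n)
    dimnames(counts) <- list(sprintf("g%03d", seq_len(genes)),
                             sprintf("c%03d", seq_len(n)))
    meta <- data.frame(
      barcode = colnames(counts),
      cell_type = rep(LETTERS[seq_len(types)], each = cells_per_type),
      donor = "d1"
    )
    cell_expression_set(counts, meta)
  })
}

# independent brute-force mean ratio oracle: explicit loop over
# (gene, target, non-target) triples on a dense matrix
brute_force_mean_ratio <- function(expr, types) {
  out <- list()
  for (tt in sort(unique(types))) {
    for (g in rownames(expr)) {
      mt <- mean(expr[g, types == tt])
      best <- -Inf; second <- NA_character_
      for (ot in setdiff(sort(unique(types)), tt)) {
        mo <- mean(expr[g, types == ot])
        if (mo > best) { best <- mo; second <- ot }
      }
      ratio <- if (mt == 0 && best == 0) 0 else mt / best
      out[[length(out) + 1]] <- data.frame(
        gene = g, cell_type = tt, mean_target = mt,
        max_nontarget_mean = best, second_type = second,
        mean_ratio = ratio, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

prop_matrix <- function(props) {
  m <- as.matrix(props[proportion_types(props)])
  rownames(m) <- props$sample
  m
}

# one shared default-scale simulation for the expensive tests
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_reference(seed = 20260928)
      sim$reference <- log_normalize(sim$reference)
      cache <<- sim
    }
    cache
  }
})
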