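#' Simulate a single-nucleus reference with planted marker genes
#'
#' Generates a gene x cell count matrix with the structure the benchmark
#' assumes: `K` cell types, `m` planted marker genes per type whose mean is
#' elevated `marker_fold`-fold in the target type, `D` donors each
#' contributing `n_cells` cells per type, gene-wise multiplicative donor
#' effects, lognormal per-cell library sizes, and negative-binomial counts
#' with variance `mu + dispersion * mu^2`.
#'
#' Baseline gene means are drawn log-uniformly and each type's mean profile
#' is normalized to sum to 1, so a type's profile describes *relative*
#' expression; per-type total RNA content is carried separately as
#' `cell_sizes` and only enters bulk mixing ([simulate_bulk()]). Donor
#' effects are lognormal and renormalized to mean 1 across donors per gene,
#' so the population mean equals the stored truth profile.
#'
#' Defaults mirror a broad-cell-type cortical reference: 7 types, 2000
#' genes, 25 markers per type at 8-fold elevation, 10 donors, 100 cells per
#' type per donor, NB dispersion 0.5.
#'
#' @param K Number of cell types (uses [broad_cell_types] names when
#'   `K <= 7`).
#' @param G Number of genes.
#' @param m Planted markers per type (`m * K <= G`).
#' @param D Number of donors.
#' @param n_cells Cells per type per donor.
#' @param marker_fold Linear fold elevation of a marker in its target type.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param donor_sigma SD of log donor effects.
#' @param lib_sigma SD of log per-cell library size factors.
#' @param base_lib Expected per-cell library size (counts).
#' @param cell_sizes Named per-type relative RNA content; defaults reflect
#'   neurons carrying more RNA than glia.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return List with `reference` (a [cell_expression_set()]) and `truth`
#'   (a `sim_truth` carrying marker lists, the mean-profile matrix `mu`,
#'   donor effects, cell sizes and the seed).
#' @export
simulate_reference <- function(K = 7, G = 2000, m = 25, D = 10,
                               n_cells = 100, marker_fold = 8,
                               dispersion = 0.5, donor_sigma = 0.2,
                               lib_sigma = 0.3, base_lib = 3000,
                               cell_sizes = NULL, seed = 1) {
  stopifnot(K >= 2, G >= 2, m >= 1, D >= 1, n_cells >= 1,
            marker_fold > 0, dispersion > 0, base_lib > 0)
  if (m * K > G) stop("m * K must not exceed G", call. = FALSE)
  types <- if (K <= length(broad_cell_types)) broad_cell_types[seq_len(K)]
           else c(broad_cell_types,
                  paste0("Type", seq_len(K - length(broad_cell_types))))
  if (is.null(cell_sizes)) {
    default_sizes <- c(Astro = 1, EndoMural = 0.8, Micro = 0.6, Oligo = 0.9,
                       OPC = 0.8, Excit = 1.8, Inhib = 1.4)
    cell_sizes <- setNames(rep(1, K), types)
    known <- intersect(types, names(default_sizes))
    cell_sizes[known] <- default_sizes[known]
  }
  stopifnot(all(cell_sizes > 0), all(types %in% names(cell_sizes)))
  cell_sizes <- cell_sizes[types]

  withr::with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(G))
    base <- exp(runif(G, log(0.01), log(10)))
    mu <- matrix(base, G, K, dimnames = list(genes, types))
    marker_idx <- matrix(sample.int(G, m * K), nrow = m)
    markers <- lapply(seq_len(K), function(k) genes[marker_idx[, k]])
    names(markers) <- types
    for (k in seq_len(K)) {
      mu[marker_idx[, k], k] <- mu[marker_idx[, k], k] * marker_fold
    }
    mu <- sweep(mu, 2, colSums(mu), "/")   # relative expression profiles

    donor_ids <- sprintf("D%02d", seq_len(D))
    donor_eff <- matrix(rlnorm(G * D, 0, donor_sigma), G, D,
                        dimnames = list(genes, donor_ids))
    donor_eff <- donor_eff / rowMeans(donor_eff)   # mean 1 across donors

    n_total <- K * D * n_cells
    dense <- matrix(0L, G, n_total)
    meta <- vector("list", K * D)
    i <- 0L
    for (k in seq_len(K)) {
      for (d in seq_len(D)) {
        i <- i + 1L
        lib <- base_lib * rlnorm(n_cells, -lib_sigma^2 / 2, lib_sigma)
        mu_gd <- mu[, k] * donor_eff[, d]
        mu_mat <- outer(mu_gd, lib)
        cols <- (i - 1L) * n_cells + seq_len(n_cells)
        dense[, cols] <- rnbinom(G * n_cells, mu = mu_mat,
                                 size = 1 / dispersion)
        meta[[i]] <- tibble(
          cell_type = rep(types[k], n_cells), donor = donor_ids[d],
          sample = paste0(donor_ids[d], "_s1")
        )
      }
    }
    counts <- methods::as(dense, "CsparseMatrix")
    dimnames(counts) <- list(genes, sprintf("C%06d", seq_len(n_total)))
    cell_meta <- bind_rows(meta)
    cell_meta$barcode <- colnames(counts)

    truth <- structure(
      list(markers = markers, mu = mu, cell_sizes = cell_sizes,
           donor_effects = donor_eff, types = types,
           dispersion = dispersion, seed = seed),
      class = "sim_truth"
    )
    list(reference = cell_expression_set(counts, cell_meta), truth = truth)
  })
}

#' @exportS3Method base::print
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", length(x$types), " types, ", nrow(x$mu), " genes, ",
      length(x$markers[[1]]), " planted markers/type\n", sep = "")
  invisible(x)
}

#' Simulate bulk samples as linear mixtures of the reference profiles
#'
#' Expected expression of sample `j` is `e_g = sum_k pi_jk * s_k * mu_gk`
#' (with `s` identically 1 when `use_cell_sizes = FALSE`): the RNA pool of a
#' bulk sample is the cell-count-weighted, RNA-content-weighted mixture of
#' the per-type relative profiles. The expectation is multiplied by
#' gene-wise lognormal noise of SD `noise_sd`, rescaled so the sample's
#' expected depth is `depth`, and Poisson-sampled.
#'
#' True proportions are drawn per *tissue block* from a Dirichlet prior (all
#' samples of a block share one composition, mimicking repeated library
#' preparations of the same tissue), and the six library-type x
#' RNA-extraction combinations are assigned cyclically within each block so
#' grouped evaluation is exercised.
#'
#' @param truth A `sim_truth` from [simulate_reference()].
#' @param n_samples Number of bulk samples (default 24, i.e. 4 blocks x 6
#'   protocol combinations).
#' @param pi Either `"dirichlet"` (default) or a fixed probability vector /
#'   matrix (blocks x types) of true proportions.
#' @param alpha Dirichlet concentration parameters; default is a
#'   cortex-like base composition times concentration 50.
#' @param depth Expected total counts per sample.
#' @param noise_sd SD of gene-wise log-normal noise (0 = noiseless mixing;
#'   Poisson sampling still applies unless `poisson = FALSE`).
#' @param use_cell_sizes Weight the mixture by per-type RNA content
#'   (`truth$cell_sizes`).
#' @param poisson If `FALSE`, return the exact expected profiles instead of
#'   Poisson draws (noiseless closure experiments).
#' @param seed Integer seed.
#' @return List with `bulk` (a [bulk_expression_set()]) and `truth`
#'   (the input truth extended with the per-sample `pi` proportion table).
#' @export
simulate_bulk <- function(truth, n_samples = 24, pi = "dirichlet",
                          alpha = NULL, depth = 1e6, noise_sd = 0,
                          use_cell_sizes = FALSE, poisson = TRUE,
                          seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (depth <= 0) stop("`depth` must be positive", call. = FALSE)
  K <- length(truth$types)
  n_blocks <- ceiling(n_samples / 6)
  combos <- tidyr::expand_grid(library_type = .library_types,
                               rna_extraction = .rna_extractions)

  withr::with_seed(seed, {
    if (identical(pi, "dirichlet")) {
      if (is.null(alpha)) {
        base_comp <- c(Astro = 0.15, EndoMural = 0.05, Micro = 0.05,
                       Oligo = 0.25, OPC = 0.05, Excit = 0.35, Inhib = 0.10)
        p0 <- if (all(truth$types %in% names(base_comp))) {
          base_comp[truth$types]
        } else {
          rep(1 / K, K)
        }
        alpha <- 50 * p0 / sum(p0)
      }
      g <- matrix(rgamma(n_blocks * K, shape = alpha), n_blocks, K,
                  byrow = TRUE)
      pi_block <- g / rowSums(g)
    } else {
      pi_block <- matrix(pi, ncol = K, byrow = is.null(dim(pi)))
      pi_block <- pi_block / rowSums(pi_block)
      pi_block <- pi_block[rep_len(seq_len(nrow(pi_block)), n_blocks), ,
                           drop = FALSE]
    }
    colnames(pi_block) <- truth$types

    s <- if (use_cell_sizes) truth$cell_sizes else
      setNames(rep(1, K), truth$types)
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    block_of <- rep(seq_len(n_blocks), each = 6)[seq_len(n_samples)]
    meta <- tibble(
      sample_id = sample_ids,
      tissue_block = sprintf("Br%02d", block_of),
      donor = sprintf("Br%02d", block_of),
      library_type = combos$library_type[rep_len(seq_len(6), n_samples)],
      rna_extraction = combos$rna_extraction[rep_len(seq_len(6), n_samples)]
    )

    pi_sample <- pi_block[block_of, , drop = FALSE]
    rownames(pi_sample) <- sample_ids
    weights <- sweep(pi_sample, 2, s, "*")            # sample x type
    expected <- truth$mu %*% t(weights)               # gene x sample
    if (noise_sd > 0) {
      expected <- expected *
        matrix(rlnorm(length(expected), -noise_sd^2 / 2, noise_sd),
               nrow(expected))
    }
    expected <- sweep(expected, 2, colSums(expected), "/") * depth
    counts <- if (poisson) {
      matrix(rpois(length(expected), expected), nrow(expected))
    } else {
      expected
    }
    dimnames(counts) <- list(rownames(truth$mu), sample_ids)

    truth$pi <- proportion_table(
      as_tibble(pi_sample, rownames = "sample"),
      method = "truth", gene_set = "truth"
    )
    truth$bulk_meta <- meta
    list(bulk = bulk_expression_set(counts, meta), truth = truth)
  })
}

#' Simulate an imaging-style segmentation table
#'
#' Emulates per-cell exports from multiplexed in-situ imaging: per section,
#' phenotype labels are drawn from a composition with an unphenotyped
#' `"Other"` mass; nuclear areas are lognormal per type, and total-RNA
#' marker (TREG) copy counts are negative binomial with a per-type mean
#' proportional to the type's RNA content. Sections alternate between the
#' two probe combinations, and -- as in real multiplexed assays that probe
#' only three of the six broad classes per combination -- cells of types not
#' probed in a section's combination are masked to `"Other"`.
#'
#' @param truth A `sim_truth` (provides type names and cell sizes).
#' @param n_sections Number of tissue sections (alternating Star/Circle).
#' @param cells_per_section Nuclei per section.
#' @param proportions Optional named composition used for every section;
#'   default draws per-section compositions from a Dirichlet around a
#'   cortex-like base (matching [simulate_bulk()]).
#' @param other_fraction Mass of intrinsically unphenotyped cells, in
#'   \[0, 1).
#' @param area_medians Named per-type median nuclear areas (square microns).
#' @param area_sdlog SD of log nuclear area.
#' @param copies_mean_scale TREG copies mean = scale x cell size.
#' @param copies_dispersion NB dispersion of TREG copies.
#' @param seed Integer seed.
#' @return List with `cells` (a [cell_table()]) and `truth` extended with
#'   `section_pi`, the per-section pre-masking compositions.
#' @export
simulate_cell_table <- function(truth, n_sections = 8,
                                cells_per_section = 2000,
                                proportions = NULL, other_fraction = 0.2,
                                area_medians = NULL, area_sdlog = 0.25,
                                copies_mean_scale = 8,
                                copies_dispersion = 0.3, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (other_fraction < 0 || other_fraction >= 1) {
    stop("`other_fraction` must be in [0, 1)", call. = FALSE)
  }
  types <- truth$types
  K <- length(types)
  if (is.null(area_medians)) {
    defaults <- c(Astro = 35, EndoMural = 28, Micro = 22, Oligo = 30,
                  OPC = 28, Excit = 50, Inhib = 45)
    area_medians <- setNames(rep(30, K), types)
    known <- intersect(types, names(defaults))
    area_medians[known] <- defaults[known]
  }
  area_medians <- c(area_medians[types], Other = 30)
  stopifnot(all(area_medians > 0))
  copy_mu <- c(copies_mean_scale * truth$cell_sizes[types],
               Other = copies_mean_scale)

  withr::with_seed(seed, {
    base_comp <- c(Astro = 0.15, EndoMural = 0.05, Micro = 0.05,
                   Oligo = 0.25, OPC = 0.05, Excit = 0.35, Inhib = 0.10)
    p0 <- if (all(types %in% names(base_comp))) base_comp[types]
          else rep(1 / K, K)
    p0 <- p0 / sum(p0)
    rows <- vector("list", n_sections)
    section_pi <- matrix(NA_real_, n_sections, K,
                         dimnames = list(NULL, types))
    for (sct in seq_len(n_sections)) {
      combo <- if (sct %% 2 == 1) "Star" else "Circle"
      p <- if (is.null(proportions)) {
        g <- rgamma(K, shape = 50 * p0)
        setNames(g / sum(g), types)
      } else {
        setNames(proportions[types] / sum(proportions[types]), types)
      }
      section_pi[sct, ] <- p
      probs <- c(p * (1 - other_fraction), Other = other_fraction)
      labels <- sample(names(probs), cells_per_section, replace = TRUE,
                       prob = probs)
      pheno <- ifelse(labels %in% probe_combinations[[combo]] |
                        labels == "Other", labels, "Other")
      area <- rlnorm(cells_per_section, log(area_medians[labels]),
                     area_sdlog)
      copies <- rnbinom(cells_per_section, mu = copy_mu[labels],
                        size = 1 / copies_dispersion)
      rows[[sct]] <- tibble(
        section_id = sprintf("Sec%02d", sct),
        combination = combo,
        phenotype = pheno,
        true_phenotype = labels,
        nuclear_area = area,
        treg_copies = copies
      )
    }
    rownames(section_pi) <- sprintf("Sec%02d", seq_len(n_sections))
    truth$section_pi <- section_pi
    list(cells = cell_table(bind_rows(rows)), truth = truth)
  })
}

#' True proportions of simulated bulk samples as a reference table
#'
#' Convenience accessor: returns the `sim_truth` per-sample compositions as
#' a [proportion_table()] suitable as the `ref` argument of
#' [evaluate_against_reference()].
#'
#' @param truth A `sim_truth` that has passed through [simulate_bulk()].
#' @return A [proportion_table()] of the true per-sample proportions.
#' @export
true_proportions <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(truth$pi)) {
    stop("truth carries no bulk proportions; run simulate_bulk() first",
         call. = FALSE)
  }
  truth$pi
}

#' Exact signature matrix from simulation ground truth
#'
#' Returns the true per-type mean-profile matrix (optionally restricted to
#' a marker set) as a `signature_matrix`. Useful for separating estimation
#' error in the signature from error in the solver: with the true signature
#' and noiseless bulk, deconvolution is exact up to numerical tolerance.
#'
#' @param truth A `sim_truth`.
#' @param markers Optional [marker_set()] or gene id vector to restrict to.
#' @return A `signature_matrix`.
#' @export
signature_from_truth <- function(truth, markers = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  sig <- truth$mu
  if (!is.null(markers)) {
    genes <- if (inherits(markers, "marker_set")) markers$union else markers
    sig <- sig[rownames(sig) %in% genes, , drop = FALSE]
    if (nrow(sig) == 0) stop("no marker genes in truth", call. = FALSE)
  }
  structure(sig, class = c("signature_matrix", "matrix", "array"),
            provenance = "truth")
}

#' Write a complete paired synthetic fixture to disk
#'
#' Emits the reference (MTX + TSVs), bulk (TSVs), segmentation table (CSV)
#' and a JSON file of the ground truth under `dir`, in exactly the formats
#' the readers consume.
#'
#' @param dir Output directory.
#' @param seed Integer seed driving all three generators.
#' @param ... Passed to [simulate_reference()].
#' @return `dir`, invisibly.
#' @export
simulate_fixture <- function(dir, seed = 1, ...) {
  sim <- simulate_reference(seed = seed, ...)
  bk <- simulate_bulk(sim$truth, seed = seed + 1)
  ct <- simulate_cell_table(bk$truth, seed = seed + 2)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cell_expression(sim$reference, file.path(dir, "reference"))
  write_bulk_expression(bk$bulk, file.path(dir, "bulk_counts.tsv"),
                        file.path(dir, "bulk_meta.tsv"))
  readr::write_csv(as_tibble(ct$cells), file.path(dir, "cell_table.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- ct$truth
    jsonlite::write_json(
      list(markers = truth$markers,
           cell_sizes = as.list(truth$cell_sizes),
           pi = as.data.frame(truth$pi),
           seed = seed),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
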