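#' Downsample a reference to equal cell-type proportions
#'
#' Draws exactly `n_per_type` cells from each cell type uniformly at random
#' without replacement (per-cell data is kept exactly; counts are never
#' resampled). `"min"` uses the size of the rarest type, mirroring the
#' balanced-composition sensitivity experiment in which the reference is
#' downsampled to the rarest type before deconvolution. Deterministic given
#' the seed.
#'
#' @param ref A [cell_expression_set()].
#' @param n_per_type Integer, or `"min"` for the rarest type's count.
#' @param seed Integer seed.
#' @return A [cell_expression_set()] with `n_per_type` cells per type.
#' @export
equal_proportion_downsample <- function(ref, n_per_type = "min", seed = 1) {
  stopifnot(inherits(ref, "cell_expr_set"))
  tab <- table(ref$cell_meta$cell_type)
  if (identical(n_per_type, "min")) n_per_type <- min(tab)
  n_per_type <- as.integer(n_per_type)
  too_small <- names(tab)[tab < n_per_type]
  if (length(too_small) > 0) {
    stop("type(s) with fewer than ", n_per_type, " cells: ",
         paste(too_small, collapse = ", "), call. = FALSE)
  }
  withr::with_seed(seed, {
    idx <- unlist(lapply(split(seq_len(ncol(ref$counts)),
                               ref$cell_meta$cell_type),
                         function(i) sort(sample(i, n_per_type))),
                  use.names = FALSE)
  })
  idx <- sort(idx)
  out <- ref
  out$counts <- ref$counts[, idx, drop = FALSE]
  out$logexpr <- if (!is.null(ref$logexpr)) {
    ref$logexpr[, idx, drop = FALSE]
  }
  out$cell_meta <- ref$cell_meta[idx, ]
  out
}

# default engine: signature from the (sub)reference + the NNLS baseline
nnls_engine <- function(ref, bulk, markers, ...) {
  sig <- build_signature(ref, markers)
  nnls_proportions(bulk, sig)
}

#' Replicated equal-proportion downsampling + deconvolution
#'
#' Runs the balanced-reference sensitivity experiment: for replicate `r`
#' the reference is downsampled to `n_per_type` cells per type with seed
#' `base_seed + r`, the engine deconvolves the bulk with the (fixed) marker
#' set, and the per-replicate proportion tables are summarised by their
#' mean and SD per sample x type. Seeds are derived additively from
#' `base_seed`, and the full seed ledger is stored so any replicate can be
#' re-executed bit-identically.
#'
#' @param ref A [cell_expression_set()].
#' @param bulk A [bulk_expression_set()].
#' @param markers A [marker_set()] (held fixed across replicates).
#' @param engine Function `(ref, bulk, markers, ...)` returning a
#'   [proportion_table()]; default builds a signature and runs
#'   [nnls_proportions()].
#' @param n_per_type Cells per type per replicate (or `"min"`).
#' @param n_reps Number of replicates.
#' @param base_seed Replicate `r` uses seed `base_seed + r`.
#' @param ref_comp Optional reference composition; when given, the mean
#'   proportion table is evaluated with [evaluate_against_reference()].
#' @param ... Passed to the engine.
#' @return A `replicate_result`: list with `mean` and `sd` proportion
#'   tibbles, `replicates` (long tibble of every replicate), `seeds`, and
#'   optionally `metrics`.
#' @export
replicate_downsample_deconv <- function(ref, bulk, markers,
                                        engine = nnls_engine,
                                        n_per_type = "min", n_reps = 10,
                                        base_seed = 1, ref_comp = NULL,
                                        ...) {
  stopifnot(n_reps >= 1)
  seeds <- base_seed + seq_len(n_reps)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sub <- equal_proportion_downsample(ref, n_per_type, seed = seeds[r])
    reps[[r]] <- tryCatch(
      engine(sub, bulk, markers, ...),
      error = function(e) {
        stop("engine failed on replicate ", r, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  long <- imap(reps, function(p, r) {
    tidy(p) %>% mutate(replicate = r, seed = seeds[r])
  }) %>% bind_rows()
  summ <- long %>%
    group_by(.data$sample, .data$cell_type) %>%
    summarise(mean = mean(.data$proportion),
              sd = if (dplyr::n() > 1) sd(.data$proportion) else NA_real_,
              .groups = "drop")
  mean_tab <- summ %>%
    select("sample", "cell_type", "mean") %>%
    tidyr::pivot_wider(names_from = "cell_type", values_from = "mean")
  mean_tab <- proportion_table(
    renormalize_rows(mean_tab),
    method = paste0(attr(reps[[1]], "method"), "+downsample_mean"),
    gene_set = attr(reps[[1]], "gene_set")
  )
  metrics <- if (!is.null(ref_comp)) {
    evaluate_against_reference(mean_tab, ref_comp, merge_map = NULL)
  }
  structure(
    list(mean = mean_tab, sd = summ, replicates = long,
         seeds = tibble(replicate = seq_len(n_reps), seed = seeds),
         base_seed = base_seed, n_per_type = n_per_type,
         metrics = metrics),
    class = "replicate_result"
  )
}

renormalize_rows <- function(df) {
  types <- setdiff(names(df), "sample")
  m <- as.matrix(df[types])
  df[types] <- m / rowSums(m)
  df
}

#' @exportS3Method base::print
print.replicate_result <- function(x, ...) {
  cat("<replicate_result> ", nrow(x$seeds), " replicates, base seed ",
      x$base_seed, "\n", sep = "")
  invisible(x)
}

#' Donor subsampling sensitivity experiment
#'
#' Measures how deconvolution accuracy depends on the number of reference
#' donors. For each requested donor count and iteration, a random donor
#' subset is drawn (seed derived additively from `base_seed`), the
#' reference is restricted to those donors, Mean Ratio markers are
#' *recomputed on the subset* -- keeping per type the top `n_markers` genes
#' whose recomputed ratio strictly exceeds 1, so a type may contribute
#' fewer than `n_markers` -- and the engine's predictions are scored
#' against `ref_comp`. Marker recomputation per subset is the default
#' because marker quality itself degrades with fewer donors; set
#' `recompute_markers = FALSE` to ablate with a fixed marker set.
#'
#' @param ref A log-normalized [cell_expression_set()].
#' @param donor_counts Integer vector of donor subset sizes.
#' @param n_iter Iterations (random donor combinations) per count.
#' @param engine As in [replicate_downsample_deconv()].
#' @param bulk A [bulk_expression_set()].
#' @param ref_comp Reference composition ([proportion_table()] or
#'   [composition_table()]).
#' @param n_markers Markers per type before the ratio > 1 filter.
#' @param fixed_markers A [marker_set()] used for every subset when
#'   `recompute_markers = FALSE`.
#' @param recompute_markers Recompute markers on each donor subset.
#' @param base_seed Iteration seeds are `base_seed + 1000 * count_index +
#'   iteration`.
#' @param ... Passed to the engine.
#' @return Long tibble: one row per (donor count, iteration) with `cor`,
#'   `rmse`, the seed, and the realised marker-union size.
#' @export
donor_subsample_experiment <- function(ref, bulk, ref_comp,
                                       donor_counts, n_iter = 10,
                                       engine = nnls_engine, n_markers = 25,
                                       fixed_markers = NULL,
                                       recompute_markers = TRUE,
                                       base_seed = 1, ...) {
  stopifnot(inherits(ref, "cell_expr_set"))
  donors <- unique(ref$cell_meta$donor)
  if (any(donor_counts > length(donors))) {
    stop("requested donor count exceeds the ", length(donors),
         " available donors", call. = FALSE)
  }
  out <- list()
  for (ci in seq_along(donor_counts)) {
    nd <- donor_counts[ci]
    for (it in seq_len(n_iter)) {
      seed <- base_seed + 1000L * ci + it
      withr::with_seed(seed, {
        chosen <- sample(donors, nd)
      })
      keep <- ref$cell_meta$donor %in% chosen
      sub <- subset_cells(ref, keep)
      markers <- if (recompute_markers) {
        stats <- mean_ratio_stats(sub)
        picked <- stats %>%
          filter(.data$rank_ratio <= n_markers, .data$mean_ratio > 1) %>%
          arrange(.data$cell_type, .data$rank_ratio)
        marker_set(split(picked$gene, picked$cell_type),
                   paste0("MeanRatio_top", n_markers, "_ratio_gt1"))
      } else {
        if (is.null(fixed_markers)) {
          stop("`fixed_markers` required when recompute_markers = FALSE",
               call. = FALSE)
        }
        fixed_markers
      }
      props <- engine(sub, bulk, markers, ...)
      met <- evaluate_against_reference(props, ref_comp, merge_map = NULL)
      out[[length(out) + 1L]] <- met %>%
        mutate(n_donors = nd, iteration = it, seed = seed,
               n_marker_genes = length(markers$union), .before = 1)
    }
  }
  bind_rows(out)
}

subset_cells <- function(ref, keep) {
  out <- ref
  out$counts <- ref$counts[, keep, drop = FALSE]
  out$logexpr <- if (!is.null(ref$logexpr)) {
    ref$logexpr[, keep, drop = FALSE]
  }
  out$cell_meta <- ref$cell_meta[keep, ]
  out
}

#' Sweep deconvolution accuracy over marker gene sets
#'
#' Runs the engine once per marker set and scores each result against the
#' reference composition, producing the long table behind marker-set
#' comparison figures. Duplicate set labels are suffixed deterministically.
#'
#' @param ref A [cell_expression_set()].
#' @param bulk A [bulk_expression_set()].
#' @param sets List of [marker_set()]s (or character vectors of gene ids).
#' @param ref_comp Reference composition.
#' @param engine As in [replicate_downsample_deconv()].
#' @param group_by,sample_meta Passed to [evaluate_against_reference()].
#' @param ... Passed to the engine.
#' @return Long tibble of metric records keyed by `gene_set`.
#' @export
gene_set_sweep <- function(ref, bulk, sets, ref_comp, engine = nnls_engine,
                           group_by = NULL, sample_meta = NULL, ...) {
  stopifnot(length(sets) >= 1)
  labels <- vapply(sets, function(s) {
    if (inherits(s, "marker_set")) s$method else "custom"
  }, "")
  labels <- make.unique(labels, sep = "_")
  out <- purrr::map2(sets, labels, function(s, lab) {
    props <- engine(ref, bulk, s, ...)
    evaluate_against_reference(props, ref_comp, merge_map = NULL,
                               group_by = group_by,
                               sample_meta = sample_meta) %>%
      mutate(gene_set = lab,
             n_genes = if (inherits(s, "marker_set")) length(s$union)
                       else length(s),
             .before = 1)
  })
  bind_rows(out)
}
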