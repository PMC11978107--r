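#' Accuracy metrics for a pair of proportion vectors
#'
#' Computes the four benchmark metrics over paired predicted and reference
#' values: Pearson correlation (`cor`), Spearman correlation (`scor`), root
#' mean squared error (`rmse`), and the relative rmse
#' (`rrmse = rmse / mean(ref)`), which expresses the error on the scale of
#' the reference proportions. NA pairs are excluded pairwise; a
#' zero-variance vector yields `NA` correlations and a zero-mean reference
#' yields `NA` rrmse.
#'
#' @param pred,ref Equal-length numeric vectors, pairs formed by
#'   (sample, cell type).
#' @return A one-row tibble: `cor`, `scor`, `rmse`, `rrmse`, `n_pairs`.
#' @export
#' @examples
#' metric_suite(c(0, 1), c(1, 1))  # rmse = sqrt(0.5), cor NA (ref constant)
metric_suite <- function(pred, ref) {
  if (length(pred) != length(ref)) {
    stop("`pred` and `ref` must have equal length", call. = FALSE)
  }
  ok <- complete.cases(pred, ref)
  if (sum(!ok) > 0) {
    message(sum(!ok), " NA pair(s) excluded")
  }
  pred <- pred[ok]; ref <- ref[ok]
  if (length(pred) < 2) {
    stop("need at least 2 complete pairs", call. = FALSE)
  }
  pearson <- if (sd(pred) == 0 || sd(ref) == 0) NA_real_ else cor(pred, ref)
  spearman <- if (sd(pred) == 0 || sd(ref) == 0) NA_real_ else
    cor(pred, ref, method = "spearman")
  rmse <- sqrt(mean((pred - ref)^2))
  rrmse <- if (mean(ref) == 0) NA_real_ else rmse / mean(ref)
  tibble(cor = pearson, scor = spearman, rmse = rmse, rrmse = rrmse,
         n_pairs = length(pred))
}

#' Evaluate predicted proportions against a measured reference composition
#'
#' Joins a table of predicted proportions with orthogonally measured
#' compositions and computes [metric_suite()] overall and within requested
#' sample groupings (e.g. library type x RNA extraction). Before matching,
#' a merge map (default Oligo + OPC -> OligoOPC) collapses predicted types
#' to the vocabulary the measurement assay can resolve. Pairs are formed per
#' (matched sample, shared cell type); reference types never predicted
#' raise an error listing the vocabulary difference, and unmatched samples
#' are dropped with a message.
#'
#' @param pred A [proportion_table()].
#' @param ref A [composition_table()] (long, keyed by `section_id`) or a
#'   `proportion_table`/wide data frame keyed by `sample`.
#' @param merge_map Named list passed to [merge_types()], or `NULL` to skip.
#' @param group_by Character vector of `sample_meta` columns to group
#'   metrics by (each grouping is emitted in addition to `"overall"`).
#' @param sample_meta Tibble keyed by `sample_id` carrying the grouping
#'   columns and, when matching against sections, a `tissue_block` column.
#' @param match_by `"sample"` joins pred samples to ref samples/sections by
#'   id; `"tissue_block"` joins via the block column in `sample_meta` (ref
#'   sections must then carry a `tissue_block` column, or their
#'   `section_id` is taken as the block).
#' @param ignore_types Reference types excluded from pairing (default
#'   `"Other"`, which deconvolution never predicts).
#' @return A tibble of metric records, one row per group plus `"overall"`,
#'   with a `group` label column and the grouping columns.
#' @export
evaluate_against_reference <- function(pred, ref, merge_map = list(OligoOPC = c("Oligo", "OPC")),
                                       group_by = NULL, sample_meta = NULL,
                                       match_by = c("sample", "tissue_block"),
                                       ignore_types = "Other") {
  match_by <- match.arg(match_by)
  stopifnot(inherits(pred, "proportion_table"))
  if (!is.null(merge_map)) {
    have <- proportion_types(pred)
    applicable <- purrr::keep(merge_map,
                              ~ length(intersect(.x, have)) > 0)
    if (length(applicable) > 0) pred <- merge_types(pred, applicable)
  }
  pred_long <- tidy(pred) %>%
    select("sample", "cell_type", pred = "proportion")

  ref_long <- reference_long(ref) %>%
    filter(!.data$cell_type %in% ignore_types)

  # attach the matching key to predictions
  if (match_by == "tissue_block") {
    if (is.null(sample_meta)) {
      stop("matching by tissue_block requires `sample_meta`", call. = FALSE)
    }
    pred_long <- pred_long %>%
      left_join(select(sample_meta, sample = "sample_id", "tissue_block"),
                by = "sample")
    key <- "tissue_block"
  } else {
    ref_long <- rename(ref_long, sample = "ref_key")
    key <- "sample"
  }
  if (match_by == "tissue_block") {
    if (!"tissue_block" %in% names(ref_long)) {
      ref_long <- rename(ref_long, tissue_block = "ref_key")
    } else {
      ref_long$ref_key <- NULL
    }
  }

  missing_types <- setdiff(unique(ref_long$cell_type),
                           unique(pred_long$cell_type))
  if (length(missing_types) > 0) {
    stop("reference type(s) never predicted: ",
         paste(missing_types, collapse = ", "),
         "; predicted types: ",
         paste(sort(unique(pred_long$cell_type)), collapse = ", "),
         call. = FALSE)
  }

  paired <- inner_join(pred_long, ref_long, by = c(key, "cell_type"),
                       relationship = "many-to-many")
  n_unmatched <- length(setdiff(unique(pred_long$sample),
                                unique(paired$sample)))
  if (n_unmatched > 0) {
    message(n_unmatched, " predicted sample(s) had no matching reference ",
            "and were dropped")
  }
  if (nrow(paired) == 0) stop("zero matched samples", call. = FALSE)

  if (!is.null(group_by)) {
    if (is.null(sample_meta)) {
      stop("`group_by` requires `sample_meta`", call. = FALSE)
    }
    paired <- paired %>%
      left_join(select(sample_meta, sample = "sample_id",
                       all_of(setdiff(group_by, names(paired)))),
                by = "sample")
  }

  overall <- metric_suite(paired$pred, paired$ref) %>%
    mutate(group = "overall", .before = 1)
  if (is.null(group_by)) return(overall)

  grouped <- paired %>%
    group_by(across(all_of(group_by))) %>%
    group_modify(~ metric_suite(.x$pred, .x$ref)) %>%
    ungroup() %>%
    mutate(group = paste(group_by, collapse = "x"), .before = 1)
  bind_rows(overall, grouped)
}

# normalize any supported reference representation to
# (ref_key, cell_type, ref [, tissue_block])
reference_long <- function(ref) {
  if (inherits(ref, "composition_table")) {
    out <- ref %>%
      as_tibble() %>%
      select(ref_key = "section_id", "cell_type", ref = "proportion",
             any_of("tissue_block"))
    return(out)
  }
  if (inherits(ref, "proportion_table") ||
      (is.data.frame(ref) && "sample" %in% names(ref))) {
    ref %>%
      as_tibble() %>%
      tidyr::pivot_longer(-any_of(c("sample", "tissue_block")),
                          names_to = "cell_type", values_to = "ref") %>%
      rename(ref_key = "sample")
  } else {
    stop("unsupported reference type", call. = FALSE)
  }
}

#' Pairwise concordance between deconvolution results
#'
#' Pearson correlation between every pair of proportion tables over their
#' shared (sample x cell type) grid, flattened. High off-diagonal values
#' mean two methods predict similar compositions even if neither is
#' accurate.
#'
#' @param tables Named list of [proportion_table()]s (names label the
#'   matrix; unnamed lists use the tables' method attributes).
#' @return Symmetric correlation matrix with unit diagonal, of class
#'   `concordance_matrix`.
#' @export
pairwise_concordance <- function(tables) {
  if (length(tables) < 2) {
    stop("need at least 2 proportion tables", call. = FALSE)
  }
  labels <- names(tables)
  if (is.null(labels) || any(labels == "")) {
    labels <- make.unique(vapply(tables, function(x)
      attr(x, "method") %||% "method", ""))
  }
  common_samples <- Reduce(intersect, lapply(tables, function(x) x$sample))
  common_types <- Reduce(intersect, lapply(tables, proportion_types))
  if (length(common_samples) == 0 || length(common_types) == 0) {
    stop("tables share no (sample, type) grid", call. = FALSE)
  }
  flat <- vapply(tables, function(x) {
    m <- as.matrix(x[match(common_samples, x$sample), common_types])
    as.numeric(m)
  }, numeric(length(common_samples) * length(common_types)))
  colnames(flat) <- labels
  out <- cor(flat)
  diag(out) <- 1
  class(out) <- c("concordance_matrix", class(out))
  out
}

#' Within-block consistency of the neuronal fraction (RSD)
#'
#' Samples prepared from the same tissue block should agree on composition
#' regardless of library preparation or RNA extraction. For each block this
#' computes the summed neuronal proportion (default excitatory + inhibitory)
#' per sample and reports its relative standard deviation
#' `RSD = sd / mean` (coefficient of variation, n - 1 denominator) across
#' the block's samples. Blocks with a single sample yield `NA`.
#'
#' @param pred A [proportion_table()].
#' @param sample_meta Tibble keyed by `sample_id` with a block column.
#' @param neuron_types Types summed into the neuronal fraction.
#' @param block_key Name of the block column in `sample_meta`.
#' @return Tibble: one row per block with `n_samples`, `mean_neuronal`,
#'   `sd_neuronal`, `rsd`.
#' @export
#' @examples
#' # neuronal proportions 0.4, 0.5, 0.6 in one block -> RSD = 0.1/0.5 = 0.2
neuronal_rsd <- function(pred, sample_meta,
                         neuron_types = c("Excit", "Inhib"),
                         block_key = "tissue_block") {
  stopifnot(inherits(pred, "proportion_table"))
  present <- intersect(neuron_types, proportion_types(pred))
  if (length(present) == 0) {
    stop("none of the neuron types are present in `pred`", call. = FALSE)
  }
  df <- pred %>%
    as_tibble() %>%
    mutate(neuronal = rowSums(as.matrix(pred[present]))) %>%
    select("sample", "neuronal") %>%
    left_join(select(sample_meta, sample = "sample_id",
                     block = all_of(block_key)),
              by = "sample")
  df %>%
    group_by(.data$block) %>%
    summarise(
      n_samples = dplyr::n(),
      mean_neuronal = mean(.data$neuronal),
      sd_neuronal = if (dplyr::n() > 1) sd(.data$neuronal) else NA_real_,
      .groups = "drop"
    ) %>%
    mutate(rsd = .data$sd_neuronal / .data$mean_neuronal)
}

#' Write a metrics table to TSV and a JSON summary
#'
#' @param metrics Tibble of metric records.
#' @param tsv_path Output TSV path.
#' @param json_path Optional JSON path (requires the jsonlite package).
#' @return `tsv_path`, invisibly.
#' @export
write_metrics <- function(metrics, tsv_path, json_path = NULL) {
  readr::write_tsv(metrics, tsv_path)
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("jsonlite is required for JSON output", call. = FALSE)
    }
    jsonlite::write_json(metrics, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(tsv_path)
}
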