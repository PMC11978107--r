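#' Tidy a proportion table into long format
#'
#' @param x A [proportion_table()].
#' @param ... Unused.
#' @return Tibble with `sample`, `cell_type`, `proportion`, `method`,
#'   `gene_set`.
#' @export
tidy.proportion_table <- function(x, ...) {
  x %>%
    as_tibble() %>%
    tidyr::pivot_longer(-"sample", names_to = "cell_type",
                        values_to = "proportion") %>%
    mutate(method = attr(x, "method") %||% "unknown",
           gene_set = attr(x, "gene_set") %||% "unknown")
}

#' One-row summary of a proportion table
#'
#' @param x A [proportion_table()].
#' @param ... Unused.
#' @return Tibble with `method`, `gene_set`, `n_samples`, `n_types`, and
#'   the mean proportion of the most abundant type.
#' @export
glance.proportion_table <- function(x, ...) {
  types <- proportion_types(x)
  means <- colMeans(as.matrix(x[types]))
  tibble(
    method = attr(x, "method") %||% "unknown",
    gene_set = attr(x, "gene_set") %||% "unknown",
    n_samples = nrow(x),
    n_types = length(types),
    top_type = names(which.max(means)),
    top_type_mean = max(means)
  )
}

#' Tidy a marker set into long format
#'
#' @param x A [marker_set()].
#' @param ... Unused.
#' @return Tibble with `method`, `cell_type`, `rank`, `gene`.
#' @export
tidy.marker_set <- function(x, ...) {
  imap(x$sets, function(genes, tt) {
    tibble(method = x$method, cell_type = tt,
           rank = seq_along(genes), gene = genes)
  }) %>% list_rbind()
}

#' One-row summary of a marker set
#'
#' @param x A [marker_set()].
#' @param ... Unused.
#' @return Tibble with `method`, `n_types`, `n_union`, and min/max per-type
#'   set sizes.
#' @export
glance.marker_set <- function(x, ...) {
  sizes <- vapply(x$sets, length, 1L)
  tibble(method = x$method, n_types = length(sizes),
         n_union = length(x$union),
         min_per_type = min(sizes), max_per_type = max(sizes))
}

#' Tidy a replicated-downsampling result
#'
#' @param x A `replicate_result` from [replicate_downsample_deconv()].
#' @param ... Unused.
#' @return Long tibble of per-replicate proportions with `replicate` and
#'   `seed` columns.
#' @export
tidy.replicate_result <- function(x, ...) x$replicates

#' One-row summary of a replicated-downsampling result
#'
#' @param x A `replicate_result`.
#' @param ... Unused.
#' @return Tibble with replicate count, cells per type, base seed, and the
#'   median across samples of the per-sample x type SD.
#' @export
glance.replicate_result <- function(x, ...) {
  tibble(
    n_reps = nrow(x$seeds),
    n_per_type = x$n_per_type,
    base_seed = x$base_seed,
    median_sd = median(x$sd$sd, na.rm = TRUE)
  )
}

#' @export
tidy.concordance_matrix <- function(x, ...) {
  m <- unclass(x)
  as_tibble(m, rownames = "method_a") %>%
    tidyr::pivot_longer(-"method_a", names_to = "method_b",
                        values_to = "cor")
}
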