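#' Build a marker-gene signature matrix from a reference
#'
#' The signature holds, for every marker gene and cell type, the
#' linear-scale mean of library-size-normalized counts over that type's
#' cells. Because every cell is first rescaled to the median library size,
#' each type's full-transcriptome profile carries the same total mass, and
#' column magnitudes restricted to the marker genes reflect how much of each
#' type's RNA the markers capture.
#'
#' @param ref A [cell_expression_set()].
#' @param markers A [marker_set()] (its union is used), or a character
#'   vector of gene ids.
#' @return A `signature_matrix`: numeric gene x type matrix with a
#'   `provenance` attribute naming the marker set.
#' @export
build_signature <- function(ref, markers) {
  stopifnot(inherits(ref, "cell_expr_set"))
  genes <- if (inherits(markers, "marker_set")) markers$union else markers
  label <- if (inherits(markers, "marker_set")) markers$method else "custom"
  hit <- strip_gene_version(rownames(ref$counts)) %in%
    strip_gene_version(genes)
  if (!any(hit)) {
    stop("no marker genes found in the reference", call. = FALSE)
  }
  lib <- Matrix::colSums(ref$counts)
  norm <- scale_columns(ref$counts[hit, , drop = FALSE], median(lib) / lib)
  sig <- group_means(norm, ref$cell_meta$cell_type)
  zero <- colSums(sig) == 0
  if (any(zero)) {
    stop("all-zero signature column(s) for type(s): ",
         paste(colnames(sig)[zero], collapse = ", "), call. = FALSE)
  }
  structure(sig, class = c("signature_matrix", "matrix", "array"),
            provenance = label)
}

#' Estimate cell-type proportions by non-negative least squares
#'
#' The package's self-contained baseline engine, labelled `"baseline-nnls"`
#' in all outputs. For each bulk sample `b` it solves
#' `min || S w - b ||_2` subject to `w >= 0` (Lawson-Hanson NNLS) over the
#' signature genes, then normalizes `w` to proportions. Bulk columns are
#' scaled to unit total mass per sample, which removes sequencing-depth
#' differences without affecting the normalized solution; the signature is
#' scaled by a single global factor so relative column magnitudes -- which
#' carry the types' relative RNA content -- are preserved. Consequently the
#' returned proportions are *RNA fractions*; convert to cell fractions with
#' [adjust_for_cell_size()] when per-type sizes are known.
#'
#' @param bulk A [bulk_expression_set()], or a gene x sample matrix.
#' @param sig A [build_signature()] matrix.
#' @return A [proportion_table()] (samples x types), with `method` and
#'   `gene_set` attributes.
#' @export
nnls_proportions <- function(bulk, sig) {
  counts <- if (inherits(bulk, "bulk_expr_set")) bulk$counts else
    as.matrix(bulk)
  idx <- match(strip_gene_version(rownames(sig)),
               strip_gene_version(rownames(counts)))
  if (anyNA(idx)) {
    missing <- rownames(sig)[is.na(idx)]
    stop(length(missing), " signature gene(s) absent from bulk, e.g. ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  }
  if (nrow(sig) < ncol(sig)) {
    stop("need at least as many marker genes as cell types", call. = FALSE)
  }
  b <- counts[idx, , drop = FALSE]
  b <- sweep(b, 2, pmax(colSums(b), .Machine$double.eps), "/")
  s <- as.matrix(sig) / mean(colSums(sig))
  if (qr(s)$rank < ncol(s)) {
    warning("signature matrix is rank-deficient; solution may be unstable",
            call. = FALSE)
  }
  w <- apply(b, 2, function(col) pracma::lsqnonneg(s, col)$x)
  w <- matrix(w, nrow = ncol(s),
              dimnames = list(colnames(s), colnames(counts)))
  tot <- colSums(w)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " sample(s) yielded an all-zero solution; ",
            "uniform proportions returned", call. = FALSE)
    w[, tot == 0] <- 1 / nrow(w)
    tot[tot == 0] <- 1
  }
  props <- t(sweep(w, 2, tot, "/"))
  proportion_table(
    as_tibble(as.matrix(props), rownames = "sample"),
    method = "baseline-nnls",
    gene_set = attr(sig, "provenance") %||% "custom"
  )
}

#' Proportion-table container
#'
#' Wide tibble of estimated (or true) cell-type proportions: one row per
#' sample, one column per cell type plus a `sample` id column. Entries lie
#' in \[0, 1\] and rows sum to 1 within 1e-9.
#'
#' @param df Data frame with a `sample` column and numeric type columns.
#' @param method,gene_set Labels stored as attributes.
#' @return A `proportion_table` tibble.
#' @export
proportion_table <- function(df, method = "unknown", gene_set = "unknown") {
  df <- as_tibble(df)
  if (!"sample" %in% names(df)) {
    stop("proportion table needs a `sample` column", call. = FALSE)
  }
  types <- setdiff(names(df), "sample")
  m <- as.matrix(df[types])
  if (any(m < -1e-12 | m > 1 + 1e-12)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("proportion rows must sum to 1 (worst deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  class(df) <- c("proportion_table", class(tibble()))
  attr(df, "method") <- method
  attr(df, "gene_set") <- gene_set
  df
}

#' Cell types of a proportion table
#' @param props A [proportion_table()].
#' @return Character vector of type column names.
#' @export
proportion_types <- function(props) setdiff(names(props), "sample")

#' Convert RNA fractions to cell fractions using per-type cell sizes
#'
#' Linear deconvolution of RNA abundances estimates the fraction of RNA
#' contributed by each cell type, not the fraction of cells: a type whose
#' cells carry more RNA (larger size `s_k`) is over-represented in
#' proportion to `s_k`. Given sizes, the cell-count fraction is
#' `p'_k = (p_k / s_k) / sum_j (p_j / s_j)`.
#'
#' Any of the three metrics from [cell_size_metrics()] (median nuclear
#' area, median total-RNA-marker copies, or their per-cell product) can
#' serve as `sizes`; only relative magnitudes matter.
#'
#' @param props A [proportion_table()].
#' @param sizes Named positive numeric vector covering every type column.
#' @return A [proportion_table()] of adjusted proportions.
#' @export
#' @examples
#' p <- proportion_table(tibble::tibble(sample = "s1", A = 0.5, B = 0.5))
#' adjust_for_cell_size(p, c(A = 2, B = 1))  # -> 1/3, 2/3
adjust_for_cell_size <- function(props, sizes) {
  stopifnot(inherits(props, "proportion_table"))
  types <- proportion_types(props)
  miss <- setdiff(types, names(sizes))
  if (length(miss) > 0) {
    stop("no cell size for type(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  s <- sizes[types]
  if (any(!is.finite(s) | s <= 0)) {
    stop("cell sizes must be positive and finite", call. = FALSE)
  }
  m <- sweep(as.matrix(props[types]), 2, s, "/")
  m <- m / rowSums(m)
  out <- bind_cols(props["sample"], as_tibble(m))
  proportion_table(out,
                   method = paste0(attr(props, "method"), "+size_adj"),
                   gene_set = attr(props, "gene_set"))
}

#' Run an external deconvolution engine through the adapter contract
#'
#' External engines plug in as a function
#' `run(reference, bulk, markers, ...)` returning a data frame with a
#' `sample` column and one numeric column per cell type. The output is
#' validated against the proportion-table invariants: all expected types
#' present, no negative entries, and rows summing to 1 (renormalized when
#' within `1e-6` of 1, rejected otherwise).
#'
#' @param run The engine callable.
#' @param ref,bulk,markers Passed through to `run`.
#' @param method_label Label recorded on the output.
#' @param ... Engine options passed through.
#' @return A validated [proportion_table()].
#' @export
external_adapter <- function(run, ref, bulk, markers,
                             method_label = "external", ...) {
  raw <- run(ref, bulk, markers, ...)
  raw <- as_tibble(raw)
  if (!"sample" %in% names(raw)) {
    stop("adapter output for '", method_label,
         "' lacks a `sample` column", call. = FALSE)
  }
  types <- setdiff(names(raw), "sample")
  m <- as.matrix(raw[types])
  if (any(m < 0)) {
    stop("adapter '", method_label, "' returned negative proportions",
         call. = FALSE)
  }
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("adapter '", method_label,
         "' rows do not sum to 1 within 1e-6 (worst deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  m <- m / rs
  gs <- if (inherits(markers, "marker_set")) markers$method else "custom"
  proportion_table(bind_cols(raw["sample"], as_tibble(m)),
                   method = method_label, gene_set = gs)
}

#' Write a proportion table as long-format TSV
#'
#' Columns: `sample`, `cell_type`, `proportion`, `method`, `gene_set`.
#'
#' @param props A [proportion_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(props, path) {
  readr::write_tsv(tidy(props), path)
  invisible(path)
}
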