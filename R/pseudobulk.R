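#' Sum single-cell counts into pseudobulk profiles
#'
#' Aggregates the reference by summing raw counts over cells within each
#' observed combination of the grouping annotations (typically
#' `c("cell_type", "sample")`). Summation is lossless: the total count of
#' the pseudobulk equals the total of the input, and no minimum-cell filter
#' is applied unless requested.
#'
#' @param set A [cell_expression_set()].
#' @param group_keys Character vector of `cell_meta` column names.
#' @param min_cells Drop groups with fewer cells than this (default 0, i.e.
#'   keep everything); dropped groups are reported in a message.
#' @return A `pseudobulk_set`: list with `counts` (gene x group matrix) and
#'   `group_meta` (tibble with the keys and `n_cells`).
#' @export
pseudobulk_sum <- function(set, group_keys = c("cell_type", "sample"),
                           min_cells = 0) {
  stopifnot(inherits(set, "cell_expr_set"))
  unknown <- setdiff(group_keys, names(set$cell_meta))
  if (length(unknown) > 0) {
    stop("unknown grouping key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keys <- set$cell_meta[group_keys]
  id <- do.call(paste, c(as.list(keys), sep = "."))
  lev <- unique(id)
  ind <- sparseMatrix(i = seq_along(id), j = match(id, lev), x = 1,
                      dims = c(length(id), length(lev)))
  counts <- as.matrix(set$counts %*% ind)
  colnames(counts) <- lev
  meta <- keys %>%
    mutate(group = id) %>%
    count(across(all_of(c(group_keys, "group"))), name = "n_cells") %>%
    arrange(match(.data$group, lev))
  if (min_cells > 0) {
    keep <- meta$n_cells >= min_cells
    if (any(!keep)) {
      message(sum(!keep), " group(s) below min_cells = ", min_cells,
              " dropped")
    }
    counts <- counts[, keep, drop = FALSE]
    meta <- meta[keep, ]
  }
  structure(list(counts = counts, group_meta = meta),
            class = "pseudobulk_set")
}

#' @exportS3Method base::print
print.pseudobulk_set <- function(x, ...) {
  cat("<pseudobulk_set> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " groups\n", sep = "")
  invisible(x)
}

#' Log counts-per-million of a pseudobulk (or any count) matrix
#'
#' `log2(count * 1e6 / column sum + pseudocount)`.
#'
#' @param pb A `pseudobulk_set` or a plain gene x group count matrix.
#' @param pseudocount Added inside the log; default 1.
#' @return A dense numeric matrix of the same shape.
#' @export
logcpm <- function(pb, pseudocount = 1) {
  m <- if (inherits(pb, "pseudobulk_set")) pb$counts else as.matrix(pb)
  cs <- colSums(m)
  if (any(cs == 0)) {
    stop("zero-sum column(s): ",
         paste(colnames(m)[cs == 0], collapse = ", "), call. = FALSE)
  }
  log2(sweep(m, 2, cs, "/") * 1e6 + pseudocount)
}

#' Z-score a matrix by gene (row)
#'
#' Centers and scales each row to zero mean and unit sample standard
#' deviation (n - 1 denominator). Constant rows, whose SD is zero, map to
#' all-zero rows rather than NaN, matching the convention used for
#' marker-gene heatmaps.
#'
#' @param m Numeric matrix with at least two columns.
#' @return Matrix of the same shape.
#' @export
zscore_by_gene <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 columns to z-score", call. = FALSE)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  out <- sweep(m, 1, mu, "-")
  nz <- s > 0
  out[nz, ] <- out[nz, , drop = FALSE] / s[nz]
  out[!nz, ] <- 0
  out
}

#' Write a pseudobulk set to TSV (counts + sidecar metadata)
#'
#' @param pb A `pseudobulk_set`.
#' @param counts_tsv,meta_tsv Output paths.
#' @return `counts_tsv`, invisibly.
#' @export
write_pseudobulk <- function(pb, counts_tsv, meta_tsv) {
  readr::write_tsv(as_tibble(pb$counts, rownames = "gene"), counts_tsv)
  readr::write_tsv(pb$group_meta, meta_tsv)
  invisible(counts_tsv)
}
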